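# Canonical feature column names: seq_0..seq_1279 then str_0..str_511.
feature_colnames <- function()
  c(paste0("seq_", seq_len(SEQ_EMBED_WIDTH) - 1L),
    paste0("str_", seq_len(STRUCT_EMBED_WIDTH) - 1L))

#' Mean-pool an embedding matrix over residues
#'
#' Entry j of the result is the arithmetic mean of column j over all L
#' rows — the pooling that condenses per-residue embeddings into one
#' fixed-width vector per complex. Pooling is linear and length-weighted
#' across both partner chains jointly.
#'
#' @param m An `embedding_matrix` (or plain numeric matrix), L >= 1.
#' @return Numeric vector of the matrix width.
#' @export
mean_pool <- function(m) {
  if (is.null(dim(m)) || nrow(m) < 1L) stop("cannot pool an empty matrix")
  colMeans(unclass(m))
}

#' Difference of pooled embeddings (mutant minus wild type)
#'
#' @param pooled_mut,pooled_wt Equal-width numeric vectors.
#' @return Elementwise `pooled_mut - pooled_wt`.
#' @export
sequence_delta <- function(pooled_mut, pooled_wt) {
  if (length(pooled_mut) != length(pooled_wt))
    stop("width mismatch: ", length(pooled_mut), " vs ", length(pooled_wt))
  pooled_mut - pooled_wt
}

# Apply all of a record's mutations to the complex's chains; both
# substitutions of a double mutant go into one mutant sequence set.
mutant_chains <- function(record, structure) {
  chains <- complex_chains(structure)
  ids <- vapply(chains, `[[`, "", "chain_id")
  for (spec in record$mutations) {
    i <- match(spec$chain_id, ids)
    if (is.na(i))
      stop("record targets chain ", spec$chain_id, " absent from ",
           structure$pdb_id)
    chains[[i]] <- apply_mutation(chains[[i]], spec)
  }
  chains
}

#' Assemble the 1792-entry feature vector for one mutation record
#'
#' The feature is the concatenation, in fixed block order, of
#' * `seq_0..seq_1279`: pooled mutant sequence embedding minus pooled
#'   wild-type sequence embedding (one forward pass each; both
#'   substitutions of a double mutant applied together), and
#' * `str_0..str_511`: the pooled wild-type structural embedding.
#'
#' Structural embeddings of wild type and mutant are nearly identical
#' (they see backbone geometry only), so only the wild-type structural
#' embedding is used; it is therefore constant across all mutations of
#' one complex.
#'
#' @param record A [mutation_record()] validated against the structure.
#' @param structure The [complex_structure()] for `record$pdb_id`.
#' @param seq_provider,struct_provider Providers (see [providers]).
#' @param cache_dir Optional on-disk cache directory for embedding calls.
#' @return Named numeric vector of length 1792 with attribute `blocks`.
#' @export
assemble_features <- function(record, structure, seq_provider, struct_provider,
                              cache_dir = NULL) {
  wt_chains <- complex_chains(structure)
  mut_chains <- mutant_chains(record, structure)

  embed_seq <- function(chains) {
    if (is.null(cache_dir)) return(embed_sequence(chains, seq_provider))
    cache_get_or_compute(seq_provider, embedding_input_digest(chains),
                         function() embed_sequence(chains, seq_provider),
                         cache_dir)
  }
  pooled_wt <- mean_pool(embed_seq(wt_chains))
  pooled_mut <- mean_pool(embed_seq(mut_chains))

  struct_m <- if (is.null(cache_dir)) embed_structure(structure, struct_provider)
  else cache_get_or_compute(struct_provider, embedding_input_digest(structure),
                            function() embed_structure(structure, struct_provider),
                            cache_dir)
  fv <- c(sequence_delta(pooled_mut, pooled_wt), mean_pool(struct_m))
  names(fv) <- feature_colnames()
  attr(fv, "blocks") <- c(seq_delta = SEQ_EMBED_WIDTH, struct_wt = STRUCT_EMBED_WIDTH)
  fv
}

#' Featurize a dataset of mutation records
#'
#' Builds the n x 1792 design matrix, one row per record in input order,
#' plus the aligned experimental ddG target vector. Wild-type pooled
#' sequence embeddings and pooled structural embeddings are computed once
#' per complex and reused. Records that fail assembly (e.g. wild-type
#' mismatch against the structure) are skipped and logged; the final
#' count is reported.
#'
#' @param records List of [mutation_record()]s.
#' @param structures Named list mapping pdb_id to [complex_structure()].
#' @param seq_provider,struct_provider Providers (see [providers]).
#' @param cache_dir Optional embedding cache directory.
#' @param quiet Suppress progress/skip messages.
#' @return List with `features` (n x 1792 matrix), `targets` (numeric n),
#'   `records` (the kept records), `n_skipped`, `skip_reasons`.
#' @export
featurize_dataset <- function(records, structures, seq_provider, struct_provider,
                              cache_dir = NULL, quiet = FALSE) {
  if (!length(records)) stop("no records to featurize (empty design matrix)")
  missing_pdbs <- setdiff(unique(record_pdb_ids(records)), names(structures))
  if (length(missing_pdbs))
    stop("no structure for complex(es): ", paste(missing_pdbs, collapse = ", "))

  # per-complex memoization of the WT blocks
  wt_pool <- new.env(parent = emptyenv())
  str_pool <- new.env(parent = emptyenv())
  get_wt <- function(pdb) {
    if (is.null(wt_pool[[pdb]])) {
      chains <- complex_chains(structures[[pdb]])
      m <- if (is.null(cache_dir)) embed_sequence(chains, seq_provider)
      else cache_get_or_compute(seq_provider, embedding_input_digest(chains),
                                function() embed_sequence(chains, seq_provider),
                                cache_dir)
      wt_pool[[pdb]] <- mean_pool(m)
    }
    wt_pool[[pdb]]
  }
  get_struct <- function(pdb) {
    if (is.null(str_pool[[pdb]])) {
      s <- structures[[pdb]]
      m <- if (is.null(cache_dir)) embed_structure(s, struct_provider)
      else cache_get_or_compute(struct_provider, embedding_input_digest(s),
                                function() embed_structure(s, struct_provider),
                                cache_dir)
      str_pool[[pdb]] <- mean_pool(m)
    }
    str_pool[[pdb]]
  }

  n <- length(records)
  features <- matrix(NA_real_, n, SEQ_EMBED_WIDTH + STRUCT_EMBED_WIDTH,
                     dimnames = list(NULL, feature_colnames()))
  ok <- logical(n)
  skip_reasons <- character(0)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    row <- tryCatch({
      pooled_mut <- mean_pool(embed_sequence(mutant_chains(rec, structures[[rec$pdb_id]]),
                                             seq_provider))
      c(sequence_delta(pooled_mut, get_wt(rec$pdb_id)), get_struct(rec$pdb_id))
    }, error = function(e) conditionMessage(e))
    if (is.character(row)) {
      skip_reasons <- c(skip_reasons, paste0("record ", i, " (", format(rec), "): ", row))
      if (!quiet) message("skipped record ", i, ": ", row)
    } else {
      features[i, ] <- row
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("all records failed featurization (empty design matrix)")
  if (!quiet && length(skip_reasons))
    message(sum(!ok), " of ", n, " records skipped; ", sum(ok), " featurized")
  list(features = features[ok, , drop = FALSE],
       targets = record_ddg(records)[ok],
       records = records[ok],
       n_skipped = sum(!ok),
       skip_reasons = skip_reasons)
}

#' Write / read a feature table with sidecar metadata
#'
#' The table is CSV with the canonical block header (`seq_0..seq_1279`,
#' `str_0..str_511`) plus a leading `ddg_exp` column; the sidecar JSON
#' records provider checkpoints, block layout and a dataset digest.
#'
#' @param featurized Result of [featurize_dataset()].
#' @param path Output CSV path (sidecar written to `<path>.meta.json`).
#' @param seq_provider,struct_provider Providers used (recorded in sidecar).
#' @return `write_feature_table()`: `path` invisibly.
#'   `read_feature_table()`: list with `features`, `targets`, `meta`.
#' @export
write_feature_table <- function(featurized, path, seq_provider = NULL,
                                struct_provider = NULL) {
  df <- data.frame(ddg_exp = featurized$targets, featurized$features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(version = "probass-features-1",
               blocks = list(seq_delta = SEQ_EMBED_WIDTH, struct_wt = STRUCT_EMBED_WIDTH),
               n = nrow(featurized$features),
               n_skipped = featurized$n_skipped,
               sequence_checkpoint = if (!is.null(seq_provider)) seq_provider$checkpoint_id else NA,
               structure_checkpoint = if (!is.null(struct_provider)) struct_provider$checkpoint_id else NA,
               dataset_digest = digest::digest(featurized$features))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  features <- as.matrix(df[, setdiff(names(df), "ddg_exp"), drop = FALSE])
  if (ncol(features) != SEQ_EMBED_WIDTH + STRUCT_EMBED_WIDTH)
    stop("feature table has ", ncol(features), " columns, expected ",
         SEQ_EMBED_WIDTH + STRUCT_EMBED_WIDTH)
  list(features = features, targets = df$ddg_exp, meta = meta)
}
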