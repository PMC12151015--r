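# Embedding widths pinned by the pipeline: 1280 per-residue sequence
# features, 512 per-residue structural (inverse-folding encoder) features.
SEQ_EMBED_WIDTH <- 1280L
STRUCT_EMBED_WIDTH <- 512L

#' Embedding providers
#'
#' A provider describes a per-residue embedding producer. Two real
#' backends are declared — a transformer protein language model for
#' sequences (1280-wide per-token representations, final layer) and an
#' inverse-folding encoder for backbone structures (512-wide) — plus
#' deterministic mock providers of the same widths for fully offline work.
#' Mock providers are pure functions of (residue letter, chain, position,
#' seed): reproducible, position-local (a point mutation perturbs exactly
#' one row), and network-free. Real transformer embeddings are not local;
#' nothing downstream may assume locality except for the mock path.
#'
#' @param checkpoint_id Checkpoint identifier recorded in outputs.
#' @param seed Integer seed fixing the mock provider's output.
#' @return A `provider_info` object with fields `name`, `kind`, `width`,
#'   `checkpoint_id` and (mocks only) `seed`.
#' @name providers
NULL

new_provider <- function(name, kind, width, checkpoint_id = "", seed = NULL) {
  kind <- match.arg(kind, c("sequence", "structure", "mock_sequence", "mock_structure"))
  width <- as.integer(width)
  if (width <= 0L) stop("provider width must be positive")
  if (kind %in% c("sequence", "mock_sequence") && width != SEQ_EMBED_WIDTH)
    stop("sequence providers must be ", SEQ_EMBED_WIDTH, "-wide, got ", width)
  if (kind %in% c("structure", "mock_structure") && width != STRUCT_EMBED_WIDTH)
    stop("structure providers must be ", STRUCT_EMBED_WIDTH, "-wide, got ", width)
  structure(list(name = name, kind = kind, width = width,
                 checkpoint_id = checkpoint_id, seed = seed),
            class = "provider_info")
}

#' @rdname providers
#' @export
sequence_provider <- function(checkpoint_id = "esm2_t33_650M_UR50D")
  new_provider("esm2", "sequence", SEQ_EMBED_WIDTH, checkpoint_id)

#' @rdname providers
#' @export
structure_provider <- function(checkpoint_id = "esm_if1_gvp4_t16_142M_UR50")
  new_provider("esm_if1", "structure", STRUCT_EMBED_WIDTH, checkpoint_id)

#' @rdname providers
#' @export
mock_sequence_provider <- function(seed = 1L)
  new_provider("mock_seq", "mock_sequence", SEQ_EMBED_WIDTH, "mock", as.integer(seed))

#' @rdname providers
#' @export
mock_structure_provider <- function(seed = 1L)
  new_provider("mock_struct", "mock_structure", STRUCT_EMBED_WIDTH, "mock", as.integer(seed))

#' @export
print.provider_info <- function(x, ...) {
  cat("<provider_info>", x$name, paste0("[", x$kind, "]"), "width", x$width,
      if (nzchar(x$checkpoint_id)) paste0("ckpt=", x$checkpoint_id) else "", "\n")
  invisible(x)
}

# Construct an embedding_matrix: numeric matrix (L x width) carrying its
# residue index and provider.
new_embedding_matrix <- function(rows, residue_index, provider) {
  if (!is.matrix(rows) || nrow(rows) < 1L)
    stop("embedding matrix needs at least one row")
  if (nrow(rows) != nrow(residue_index))
    stop("rows (", nrow(rows), ") and residue_index (", nrow(residue_index),
         ") disagree")
  structure(rows,
            residue_index = residue_index[, c("chain_id", "position"), drop = FALSE],
            provider = provider[c("name", "kind", "width", "checkpoint_id")],
            class = c("embedding_matrix", "matrix", "array"))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  p <- attr(x, "provider")
  cat("<embedding_matrix>", nrow(x), "residues x", ncol(x), "dims from",
      p$name, "\n")
  invisible(x)
}

# Deterministic 31-bit string hash; pure, platform-independent.
.token_hash <- function(s, seed) {
  v <- utf8ToInt(s)
  h <- (as.double(seed) %% 2147483647) + 17
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr with the global RNG state untouched.
.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Deterministic mock per-residue embeddings
#'
#' Row i is a pure function of (residue letter, chain, position, seed)
#' with entries in \[-1, 1\]: identical arguments give bitwise-identical
#' output, and changing one residue letter changes exactly that row. This
#' locality is a property of the mock only; it gives sharp unit tests for
#' pooling and feature assembly without any pre-trained checkpoint.
#'
#' @param tokens data.frame with columns `chain_id`, `position`, `letter`.
#' @param width Embedding width (> 0).
#' @param seed Integer seed.
#' @param salt Extra string mixed into the hash so that providers of
#'   different kinds disagree even at equal width and seed.
#' @return An `embedding_matrix` of dim `nrow(tokens)` x `width`.
#' @export
mock_embed <- function(tokens, width, seed, salt = "mock") {
  width <- as.integer(width)
  if (width <= 0L) stop("width must be positive")
  if (!nrow(tokens)) stop("no tokens to embed")
  rows <- matrix(0, nrow(tokens), width)
  .with_preserved_rng({
    for (i in seq_len(nrow(tokens))) {
      h <- .token_hash(paste(salt, tokens$letter[i], tokens$chain_id[i],
                             tokens$position[i], sep = "|"), seed)
      set.seed(h)
      rows[i, ] <- stats::runif(width, -1, 1)
    }
  })
  new_embedding_matrix(rows, tokens,
                       list(name = paste0("mock-", salt), kind = "mock",
                            width = width, checkpoint_id = "mock"))
}

.check_alphabet <- function(sequence, where) {
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, AA_ALPHABET)
  if (length(bad))
    stop("sequence for ", where, " contains letter(s) outside the standard ",
         "alphabet: ", paste(unique(bad), collapse = ", "))
}

.real_backend_error <- function(which) {
  stop(which, " backend is not available in this installation. ",
       "Pre-compute per-residue embeddings with the corresponding Python ",
       "model (fair-esm: ", which, "), export them, and register them via ",
       "the embedding cache, or use the mock provider for offline work.",
       call. = FALSE)
}

#' Embed chain sequences with a sequence provider
#'
#' Returns one row per residue across all chains, in the given chain
#' order. Backend special/boundary tokens are never part of the returned
#' rows. The mock provider is deterministic per seed.
#'
#' @param chains List of [chain_sequence()] objects (non-empty sequences).
#' @param provider A sequence-kind provider from [sequence_provider()] or
#'   [mock_sequence_provider()].
#' @return An `embedding_matrix` (total length x 1280).
#' @export
embed_sequence <- function(chains, provider) {
  if (!provider$kind %in% c("sequence", "mock_sequence"))
    stop("provider kind '", provider$kind, "' cannot embed sequences")
  if (inherits(chains, "chain_sequence")) chains <- list(chains)
  tokens <- do.call(rbind, lapply(chains, function(cs) {
    if (!nchar(cs$sequence)) stop("empty sequence for chain ", cs$chain_id)
    .check_alphabet(cs$sequence, paste0("chain ", cs$chain_id))
    data.frame(chain_id = cs$chain_id, position = cs$numbering,
               letter = strsplit(cs$sequence, "")[[1]],
               stringsAsFactors = FALSE)
  }))
  if (provider$kind == "mock_sequence")
    return(mock_embed(tokens, provider$width, provider$seed, salt = "seq"))
  .real_backend_error("ESM-2 sequence")
}

#' Embed a complex structure with a structural provider
#'
#' One row per residue of both binding partners, aligned to the loaded
#' complex's residue order (the alignment contract downstream pooling
#' relies on). The real backend is an inverse-folding encoder consuming
#' backbone coordinates; the mock provider derives rows from the residue
#' identity deterministically.
#'
#' @param structure A [complex_structure()].
#' @param provider A structure-kind provider.
#' @return An `embedding_matrix` (L x 512).
#' @export
embed_structure <- function(structure, provider) {
  if (!provider$kind %in% c("structure", "mock_structure"))
    stop("provider kind '", provider$kind, "' cannot embed structures")
  ridx <- complex_residue_index(structure)
  ca <- structure$backbone[structure$backbone$atom == "CA", , drop = FALSE]
  have_ca <- paste(ridx$chain_id, ridx$position) %in% paste(ca$chain_id, ca$position)
  if (!all(have_ca))
    stop("residue count mismatch: ", sum(!have_ca),
         " sequence position(s) lack backbone coordinates")
  if (provider$kind == "mock_structure")
    return(mock_embed(ridx, provider$width, provider$seed, salt = "struct"))
  .real_backend_error("ESM-IF1 inverse-folding")
}

#' On-disk embedding cache
#'
#' Memoizes embedding calls keyed by (provider, input digest). The first
#' call computes and stores; later calls with the same key return a
#' bitwise-equal matrix without invoking the backend. A corrupt cache
#' entry is recomputed and overwritten with a warning.
#'
#' @param provider A `provider_info`.
#' @param input_digest Character digest of the embedding input (see
#'   [embedding_input_digest()]).
#' @param compute Zero-argument function producing the `embedding_matrix`.
#' @param cache_dir Writable cache directory; created if absent.
#' @return The embedding matrix, with attribute `"cache_hit"` TRUE/FALSE.
#' @export
cache_get_or_compute <- function(provider, input_digest, compute, cache_dir) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  key <- paste0(provider$name, "-", provider$width, "-",
                substr(digest::digest(list(provider$checkpoint_id, provider$seed,
                                           input_digest)), 1, 16), ".rds")
  path <- file.path(cache_dir, key)
  if (file.exists(path)) {
    entry <- tryCatch(readRDS(path), error = function(e) NULL)
    if (!is.null(entry) && identical(entry$version, "probass-cache-1") &&
        inherits(entry$matrix, "embedding_matrix")) {
      attr(entry$matrix, "cache_hit") <- TRUE
      return(entry$matrix)
    }
    warning("corrupt cache entry ", key, "; recomputing")
  }
  m <- compute()
  saveRDS(list(version = "probass-cache-1", provider = provider, matrix = m),
          path)
  attr(m, "cache_hit") <- FALSE
  m
}

#' Digest of an embedding input
#'
#' Canonical digest for cache keys: chains are digested by (chain id,
#' sequence, numbering); structures additionally by their backbone table.
#'
#' @param x A list of [chain_sequence()]s or a [complex_structure()].
#' @return Character digest.
#' @export
embedding_input_digest <- function(x) {
  if (inherits(x, "complex_structure"))
    return(digest::digest(list(lapply(complex_chains(x), unclass), x$backbone)))
  if (inherits(x, "chain_sequence")) x <- list(x)
  digest::digest(lapply(x, unclass))
}
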