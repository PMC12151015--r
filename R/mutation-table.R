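# The 20-letter standard amino-acid alphabet used throughout.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a single point-substitution specification
#'
#' A `mutation_spec` identifies one substitution: the chain, the
#' author-assigned residue position (kept as a character string so that
#' insertion codes such as `"100A"` pass through untouched), the wild-type
#' residue and the mutant residue, both as one-letter codes.
#'
#' @param chain_id Single-character chain identifier.
#' @param position Author residue number, possibly with an insertion-code
#'   suffix. Coerced to character; no arithmetic is ever performed on it.
#' @param wt_aa,mut_aa One-letter amino-acid codes; must differ and must
#'   belong to the 20-letter standard alphabet.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(chain_id, position, wt_aa, mut_aa) {
  chain_id <- as.character(chain_id)
  position <- as.character(position)
  if (nchar(chain_id) != 1L)
    stop("chain_id must be a single character, got '", chain_id, "'")
  if (!wt_aa %in% AA_ALPHABET)
    stop("unknown wild-type amino-acid letter '", wt_aa, "'")
  if (!mut_aa %in% AA_ALPHABET)
    stop("unknown mutant amino-acid letter '", mut_aa, "'")
  if (wt_aa == mut_aa)
    stop("wild-type and mutant residue are identical (", wt_aa, position, mut_aa, ")")
  structure(list(chain_id = chain_id, position = position,
                 wt_aa = wt_aa, mut_aa = mut_aa),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) {
  paste0(x$chain_id, ":", x$wt_aa, x$position, x$mut_aa)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec>", format(x), "\n")
  invisible(x)
}

#' Construct one experimental measurement record
#'
#' Bundles a complex identifier, one or two point substitutions, the
#' measured change in binding free energy and its optional error.
#'
#' @param pdb_id Complex identifier (typically a 4-character PDB code).
#' @param mutations List of 1 or 2 [mutation_spec()] objects; two specs may
#'   not share a (chain, position) site.
#' @param ddg_exp Experimental ddG_bind in kcal/mol (finite, signed;
#'   positive = destabilizing). May be `NA` for prediction-only records.
#' @param ddg_error Optional standard deviation of the measurement, kcal/mol.
#' @param source One of `"inhouse"` or `"skempi"`.
#' @param partner_chains Optional string naming the two partner chain
#'   groups, e.g. `"E_I"`; carried through to the normalized table.
#' @return An object of class `mutation_record`.
#' @export
mutation_record <- function(pdb_id, mutations, ddg_exp, ddg_error = NA_real_,
                            source = c("inhouse", "skempi"),
                            partner_chains = NA_character_) {
  source <- match.arg(source)
  if (inherits(mutations, "mutation_spec")) mutations <- list(mutations)
  if (length(mutations) < 1L || length(mutations) > 2L)
    stop("a record must carry 1 or 2 mutations, got ", length(mutations))
  sites <- vapply(mutations, function(m) paste0(m$chain_id, ":", m$position), "")
  if (anyDuplicated(sites))
    stop("mutations in one record may not share a site: ", sites[1L])
  ddg_exp <- as.numeric(ddg_exp)
  if (!is.na(ddg_exp) && !is.finite(ddg_exp))
    stop("ddg_exp must be finite")
  structure(list(pdb_id = as.character(pdb_id), mutations = mutations,
                 ddg_exp = ddg_exp, ddg_error = as.numeric(ddg_error),
                 source = source, partner_chains = as.character(partner_chains)),
            class = "mutation_record")
}

#' @export
format.mutation_record <- function(x, ...) {
  paste0(x$pdb_id, " ", paste(vapply(x$mutations, format, ""), collapse = ","),
         " ddG=", signif(x$ddg_exp, 4), " [", x$source, "]")
}

#' @export
print.mutation_record <- function(x, ...) {
  cat("<mutation_record>", format(x), "\n")
  invisible(x)
}

# Canonical duplicate key: complex plus the multiset of substitutions.
record_key <- function(record) {
  muts <- sort(vapply(record$mutations, format, ""))
  paste0(record$pdb_id, "|", paste(muts, collapse = ","))
}

#' Extract per-record fields from a list of records
#'
#' @param records List of [mutation_record()] objects.
#' @return `record_pdb_ids()`: character vector of complex ids;
#'   `record_ddg()`: numeric vector of experimental ddG values;
#'   `record_errors()`: numeric vector of measurement errors;
#'   `record_n_mutations()`: integer vector (1 or 2).
#' @export
record_pdb_ids <- function(records) vapply(records, function(r) r$pdb_id, "")

#' @rdname record_pdb_ids
#' @export
record_ddg <- function(records) vapply(records, function(r) r$ddg_exp, 0)

#' @rdname record_pdb_ids
#' @export
record_errors <- function(records) vapply(records, function(r) r$ddg_error, 0)

#' @rdname record_pdb_ids
#' @export
record_n_mutations <- function(records)
  vapply(records, function(r) length(r$mutations), 0L)

# Parse one mutation code. skempi codes embed the chain ("KI15A"); inhouse
# codes ("K15A") take the chain from the table's chain column. The position
# may carry a one-letter insertion code ("K100AL" = pos "100A", mut L).
parse_mutation_code <- function(code, chain = NULL) {
  code <- trimws(code)
  if (is.null(chain)) {
    m <- regmatches(code, regexec("^([A-Za-z])([A-Za-z0-9])([0-9]+[A-Za-z]?)([A-Za-z])$", code))[[1]]
    if (length(m) == 0L) stop("cannot parse mutation code '", code, "'")
    mutation_spec(chain_id = m[3L], position = m[4L],
                  wt_aa = toupper(m[2L]), mut_aa = toupper(m[5L]))
  } else {
    m <- regmatches(code, regexec("^([A-Za-z])([0-9]+[A-Za-z]?)([A-Za-z])$", code))[[1]]
    if (length(m) == 0L) stop("cannot parse mutation code '", code, "'")
    mutation_spec(chain_id = chain, position = m[3L],
                  wt_aa = toupper(m[2L]), mut_aa = toupper(m[4L]))
  }
}

#' Parse a mutation table in a declared dialect
#'
#' Reads a tabular file of mutation measurements. Two dialects are
#' supported and must be declared explicitly (never sniffed):
#'
#' * `"inhouse_like"`: CSV with columns `pdb_id`, `chain`, `mutation`,
#'   `ddg` and optionally `ddg_error`. The mutation field holds codes such
#'   as `"K15A"`; a comma-separated pair (`"K15A,R17D"`) yields a
#'   two-mutation record.
#' * `"skempi_like"`: CSV/TSV with columns `pdb` (e.g. `"3OTJ_E_I"`, the
#'   complex id plus the two partner chain groups), `mutations`
#'   (semicolon-separated codes with embedded chain letters, e.g.
#'   `"KI15A"`), `ddg` and optionally `ddg_error`.
#'
#' Malformed rows (unparsable codes, letters outside the standard
#' alphabet, wild type equal to mutant, non-finite ddG, more than two
#' substitutions) are rejected row by row; each rejection is logged with
#' its line number and reason, and the full rejection table is attached to
#' the result as attribute `"rejections"`.
#'
#' @param path Path to the table.
#' @param dialect `"skempi_like"` or `"inhouse_like"`.
#' @param source Source tag stored in each record; defaults to `"skempi"`
#'   for the skempi dialect and `"inhouse"` otherwise.
#' @param quiet Suppress per-row rejection messages.
#' @return List of [mutation_record()]s with attribute `rejections`
#'   (data.frame: line, reason).
#' @export
parse_mutation_table <- function(path, dialect = c("skempi_like", "inhouse_like"),
                                 source = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mutation table not found: ", path)
  if (is.null(source)) source <- if (dialect == "skempi_like") "skempi" else "inhouse"
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  records <- vector("list", nrow(tab))
  rej_line <- integer(0); rej_reason <- character(0)
  for (i in seq_len(nrow(tab))) {
    rec <- tryCatch({
      if (dialect == "inhouse_like") {
        codes <- strsplit(as.character(tab$mutation[i]), ",")[[1]]
        specs <- lapply(codes, parse_mutation_code, chain = as.character(tab$chain[i]))
        mutation_record(tab$pdb_id[i], specs, tab$ddg[i],
                        ddg_error = if ("ddg_error" %in% names(tab)) tab$ddg_error[i] else NA_real_,
                        source = source)
      } else {
        pdb_field <- strsplit(as.character(tab$pdb[i]), "_")[[1]]
        codes <- strsplit(as.character(tab$mutations[i]), ";")[[1]]
        specs <- lapply(codes, parse_mutation_code)
        mutation_record(pdb_field[1L], specs, tab$ddg[i],
                        ddg_error = if ("ddg_error" %in% names(tab)) tab$ddg_error[i] else NA_real_,
                        source = source,
                        partner_chains = if (length(pdb_field) > 1L)
                          paste(pdb_field[-1L], collapse = "_") else NA_character_)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      rej_line <- c(rej_line, i)
      rej_reason <- c(rej_reason, rec)
      if (!quiet) message("rejected ", basename(path), " row ", i, ": ", rec)
      records[i] <- list(NULL)
    } else records[[i]] <- rec
  }
  kept <- records[!vapply(records, is.null, TRUE)]
  if (!quiet && length(rej_line))
    message(length(rej_line), " of ", nrow(tab), " rows rejected in ", basename(path))
  structure(kept, rejections = data.frame(line = rej_line, reason = rej_reason,
                                          stringsAsFactors = FALSE))
}

#' Merge two mutation sources, preferring in-house measurements
#'
#' When the same (complex, mutation set) appears in both sources, only the
#' in-house record survives. Within one source, exact duplicates collapse
#' to a single record whose ddG is the arithmetic mean of the duplicates
#' (and whose error is the mean of the reported errors, when any).
#'
#' The operation is a pure merge and is idempotent: applying it to its own
#' output (with an empty second argument) changes nothing.
#'
#' @param inhouse,skempi Lists of [mutation_record()]s.
#' @return Merged list of records.
#' @export
resolve_duplicates <- function(inhouse, skempi = list()) {
  collapse <- function(records) {
    if (!length(records)) return(list())
    keys <- vapply(records, record_key, "")
    lapply(split(seq_along(records), keys)[unique(keys)], function(idx) {
      rec <- records[[idx[1L]]]
      if (length(idx) > 1L) {
        rec$ddg_exp <- mean(vapply(records[idx], function(r) r$ddg_exp, 0))
        errs <- vapply(records[idx], function(r) r$ddg_error, 0)
        rec$ddg_error <- if (all(is.na(errs))) NA_real_ else mean(errs, na.rm = TRUE)
      }
      rec
    })
  }
  inh <- collapse(inhouse)
  ske <- collapse(skempi)
  inh_keys <- vapply(inh, record_key, character(1L))
  ske <- ske[!vapply(ske, record_key, "") %in% inh_keys]
  unname(c(inh, ske))
}

#' Write and re-read the normalized mutation table
#'
#' The normalized CSV has columns `pdb_id`, `partner_chains`, `mutations`
#' (comma-joined `chain:wtPOSmut` codes), `ddg_exp`, `ddg_error`, `source`.
#' `read_mutation_table()` inverts `write_mutation_table()` exactly, so a
#' write/read round trip reproduces the records.
#'
#' @param records List of [mutation_record()]s.
#' @param path Output CSV path.
#' @return `write_mutation_table()` returns `path` invisibly;
#'   `read_mutation_table()` returns a list of records.
#' @export
write_mutation_table <- function(records, path) {
  df <- data.frame(
    pdb_id = record_pdb_ids(records),
    partner_chains = vapply(records, function(r) r$partner_chains, ""),
    mutations = vapply(records, function(r)
      paste(vapply(r$mutations, format, ""), collapse = ","), ""),
    ddg_exp = record_ddg(records),
    ddg_error = record_errors(records),
    source = vapply(records, function(r) r$source, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pdb_id = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    specs <- lapply(strsplit(df$mutations[i], ",")[[1]], function(code) {
      m <- regmatches(code, regexec("^(.):([A-Z])([0-9]+[A-Za-z]?)([A-Z])$", code))[[1]]
      mutation_spec(m[2L], m[4L], m[3L], m[5L])
    })
    mutation_record(df$pdb_id[i], specs, df$ddg_exp[i], df$ddg_error[i],
                    source = df$source[i], partner_chains = df$partner_chains[i])
  })
}
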