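# Three-letter -> one-letter residue codes, standard 20 plus parent
# mappings for common modified residues seen in PDB entries.
RES3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "C", HYP = "P", SEP = "S", TPO = "T",
             PTR = "Y", CSO = "C", MLY = "K")

#' Construct a chain sequence with author numbering
#'
#' @param chain_id Single-character chain identifier.
#' @param sequence One-letter amino-acid string.
#' @param numbering Character vector of author residue numbers (possibly
#'   with insertion codes), one per sequence position, unique within the
#'   chain.
#' @return An object of class `chain_sequence`.
#' @export
chain_sequence <- function(chain_id, sequence, numbering) {
  numbering <- as.character(numbering)
  if (nchar(sequence) != length(numbering))
    stop("sequence length (", nchar(sequence), ") != numbering length (",
         length(numbering), ") for chain ", chain_id)
  if (anyDuplicated(numbering))
    stop("duplicate residue numbers in chain ", chain_id)
  structure(list(chain_id = as.character(chain_id), sequence = sequence,
                 numbering = numbering),
            class = "chain_sequence")
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat("<chain_sequence>", x$chain_id, paste0("(", nchar(x$sequence), " aa)"),
      substr(x$sequence, 1, 40), "\n")
  invisible(x)
}

#' Load a two-partner protein complex from a PDB file
#'
#' Parses coordinate records (via bio3d), derives each chain's sequence
#' from residues with a resolved C-alpha atom, and groups the chains into
#' the two binding partners named by `partner_spec`. Non-standard residues
#' with a known parent (e.g. selenomethionine) are mapped to the parent's
#' one-letter code; unknown residues are skipped with a warning. HETATM
#' and water records are ignored. Residues without a C-alpha are excluded
#' from both the sequence and the backbone table (keeping sequence and
#' structural embeddings index-aligned), with a logged count.
#'
#' @param pdb_path Path to a PDB-format file.
#' @param partner_spec List of two character vectors of chain IDs, e.g.
#'   `list(a = "A", b = c("H", "L"))`. Both groups must be non-empty,
#'   disjoint and present in the file.
#' @param pdb_id Complex identifier; defaults to the file stem.
#' @param quiet Suppress skipped-residue messages.
#' @return An object of class `complex_structure` with fields `pdb_id`,
#'   `partner_a`, `partner_b` (lists of [chain_sequence()]), and
#'   `backbone`: a data.frame of N/CA/C coordinates (`chain_id`,
#'   `position`, `atom`, `x`, `y`, `z`, Angstrom).
#' @export
load_complex <- function(pdb_path, partner_spec, pdb_id = NULL, quiet = FALSE) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  if (length(partner_spec) != 2L ||
      !length(partner_spec[[1L]]) || !length(partner_spec[[2L]]))
    stop("partner_spec must name two non-empty chain groups")
  chains_a <- as.character(partner_spec[[1L]])
  chains_b <- as.character(partner_spec[[2L]])
  if (length(intersect(chains_a, chains_b)))
    stop("partner groups must be disjoint chain-ID sets")
  if (is.null(pdb_id)) pdb_id <- sub("\\.(pdb|ent)$", "", basename(pdb_path))

  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM" & !is.na(pdb$atom$chain), , drop = FALSE]
  atoms <- atoms[atoms$resid != "HOH", , drop = FALSE]

  build_chain <- function(ch) {
    ca <- atoms[atoms$chain == ch & atoms$elety == "CA", , drop = FALSE]
    if (!nrow(ca)) stop("chain ", ch, " has no resolved residues in ", pdb_path)
    pos <- paste0(ca$resno, ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert))
    keep <- !duplicated(pos)          # drop altloc duplicates
    ca <- ca[keep, , drop = FALSE]; pos <- pos[keep]
    letters1 <- RES3TO1[ca$resid]
    unknown <- is.na(letters1)
    if (any(unknown) && !quiet)
      message("chain ", ch, ": skipped ", sum(unknown),
              " residue(s) with unknown type (",
              paste(unique(ca$resid[unknown]), collapse = ","), ")")
    ca <- ca[!unknown, , drop = FALSE]; pos <- pos[!unknown]
    letters1 <- letters1[!unknown]
    if (!nrow(ca)) stop("chain ", ch, " has zero usable residues")
    chain_sequence(ch, paste(letters1, collapse = ""), pos)
  }

  missing_chains <- setdiff(c(chains_a, chains_b), unique(atoms$chain))
  if (length(missing_chains))
    stop("chain(s) absent from ", pdb_path, ": ",
         paste(missing_chains, collapse = ", "))

  partner_a <- lapply(chains_a, build_chain)
  partner_b <- lapply(chains_b, build_chain)

  # Backbone table restricted to residues retained in the sequences.
  kept <- do.call(rbind, lapply(c(partner_a, partner_b), function(cs)
    data.frame(chain_id = cs$chain_id, position = cs$numbering,
               stringsAsFactors = FALSE)))
  bb <- atoms[atoms$elety %in% c("N", "CA", "C") &
                atoms$chain %in% c(chains_a, chains_b), , drop = FALSE]
  bbpos <- paste0(bb$resno, ifelse(is.na(bb$insert) | bb$insert == "", "", bb$insert))
  sel <- paste(bb$chain, bbpos) %in% paste(kept$chain_id, kept$position)
  bb <- bb[sel, , drop = FALSE]; bbpos <- bbpos[sel]
  keep <- !duplicated(paste(bb$chain, bbpos, bb$elety))
  backbone <- data.frame(chain_id = bb$chain[keep], position = bbpos[keep],
                         atom = bb$elety[keep], x = bb$x[keep], y = bb$y[keep],
                         z = bb$z[keep], stringsAsFactors = FALSE)

  structure(list(pdb_id = pdb_id, partner_a = partner_a, partner_b = partner_b,
                 backbone = backbone),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  na <- vapply(x$partner_a, function(c) nchar(c$sequence), 0L)
  nb <- vapply(x$partner_b, function(c) nchar(c$sequence), 0L)
  cat("<complex_structure>", x$pdb_id,
      "partner A:", paste(vapply(x$partner_a, `[[`, "", "chain_id"), collapse = ","),
      paste0("(", sum(na), " aa)"),
      "| partner B:", paste(vapply(x$partner_b, `[[`, "", "chain_id"), collapse = ","),
      paste0("(", sum(nb), " aa)\n"))
  invisible(x)
}

# All chains of a complex in partner order (A chains then B chains).
complex_chains <- function(structure)
  c(structure$partner_a, structure$partner_b)

# Residue index of a complex: one (chain_id, position) row per residue,
# in partner/chain order. This is the alignment contract embeddings obey.
complex_residue_index <- function(structure) {
  do.call(rbind, lapply(complex_chains(structure), function(cs)
    data.frame(chain_id = cs$chain_id, position = cs$numbering,
               letter = strsplit(cs$sequence, "")[[1]],
               stringsAsFactors = FALSE)))
}

#' Apply a point substitution to a chain sequence
#'
#' Replaces the residue at the spec's author position. The chain must
#' match, the position must exist, and the current residue must equal the
#' spec's wild-type letter; otherwise a WT-mismatch error is raised (such
#' records are rejected upstream, with a logged count).
#'
#' @param chain A [chain_sequence()].
#' @param spec A [mutation_spec()] on the same chain.
#' @return A new `chain_sequence` differing at exactly one position.
#' @export
apply_mutation <- function(chain, spec) {
  if (spec$chain_id != chain$chain_id)
    stop("mutation targets chain ", spec$chain_id, " but sequence is chain ",
         chain$chain_id)
  idx <- match(spec$position, chain$numbering)
  if (is.na(idx))
    stop("position ", spec$position, " absent from chain ", chain$chain_id)
  have <- substr(chain$sequence, idx, idx)
  if (have != spec$wt_aa)
    stop("WT mismatch at ", chain$chain_id, ":", spec$position,
         ": sequence has ", have, ", record says ", spec$wt_aa)
  seq <- chain$sequence
  substr(seq, idx, idx) <- spec$mut_aa
  chain_sequence(chain$chain_id, seq, chain$numbering)
}

#' Identify interface positions of a two-partner complex
#'
#' A residue is at the interface when its C-alpha atom lies within
#' `cutoff` Angstrom (inclusive) of any C-alpha of the opposite partner.
#' Positions from both partners are returned. The default 4 Angstrom
#' C-alpha--C-alpha cutoff is deliberately strict; it is a parameter so
#' users can relax it.
#'
#' @param structure A [complex_structure()].
#' @param cutoff Distance cutoff in Angstrom (inclusive), default 4.0.
#' @return data.frame with columns `chain_id`, `position`, one row per
#'   interface residue, in partner/chain order.
#' @export
interface_positions <- function(structure, cutoff = 4.0) {
  ca <- structure$backbone[structure$backbone$atom == "CA", , drop = FALSE]
  ids_a <- vapply(structure$partner_a, `[[`, "", "chain_id")
  ids_b <- vapply(structure$partner_b, `[[`, "", "chain_id")
  ca_a <- ca[ca$chain_id %in% ids_a, , drop = FALSE]
  ca_b <- ca[ca$chain_id %in% ids_b, , drop = FALSE]
  if (!nrow(ca_a) || !nrow(ca_b))
    stop("a binding partner has no C-alpha coordinates")
  xa <- as.matrix(ca_a[, c("x", "y", "z")])
  xb <- as.matrix(ca_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  close <- d2 <= cutoff^2 + 1e-9     # inclusive boundary
  hit_a <- which(rowSums(close) > 0)
  hit_b <- which(colSums(close) > 0)
  out <- rbind(ca_a[hit_a, c("chain_id", "position"), drop = FALSE],
               ca_b[hit_b, c("chain_id", "position"), drop = FALSE])
  rownames(out) <- NULL
  out
}
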