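#' Fixture configuration for offline end-to-end testing
#'
#' Captures the study conditions the synthetic pipeline emulates: a
#' two-chain toy complex with a real interface, single and double point
#' mutations with ddG values generated as a known sparse-linear function
#' of the assembled features plus Gaussian noise.
#'
#' @param n_res_a,n_res_b Residues per binding partner (>= 3 each).
#' @param n_single,n_double Mutation counts.
#' @param informative_dims Number of feature columns carrying signal.
#' @param noise_sd Measurement noise SD in kcal/mol (>= 0).
#' @param seed Integer seed driving every random choice.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_res_a = 60L, n_res_b = 50L, n_single = 200L,
                           n_double = 0L, informative_dims = 20L,
                           noise_sd = 0, seed = 1L) {
  stopifnot(n_res_a >= 3L, n_res_b >= 3L, n_single + n_double > 0L,
            informative_dims > 0L, noise_sd >= 0)
  structure(list(n_res_a = as.integer(n_res_a), n_res_b = as.integer(n_res_b),
                 n_single = as.integer(n_single), n_double = as.integer(n_double),
                 informative_dims = as.integer(informative_dims),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_config")
}

# One PDB ATOM record. Fixed-width columns per the PDB 3.3 format.
.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z, elem) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, 1.0, 0.0, elem)
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Generate a loadable two-chain toy complex
#'
#' Writes PDB-format text for two chains with idealized backbone
#' geometry: each chain is a straight C-alpha trace at 3.8 Angstrom
#' spacing, the second chain offset so that the closest cross-partner
#' C-alpha pairs lie just inside 4 Angstrom (so interface detection at
#' the default cutoff is non-empty by construction). Sequences are drawn
#' uniformly from the 20-letter alphabet; output is byte-identical per
#' seed.
#'
#' @param n_res_a,n_res_b Residues per chain (>= 3).
#' @param seed Integer seed.
#' @param pdb_id Complex identifier written into the header.
#' @param chain_ids Two chain letters (default A, B).
#' @return List with `pdb_text` (character vector of lines), `pdb_id`,
#'   `partner_spec` (list of the two chain-id groups), and the two
#'   sequences.
#' @export
make_toy_complex <- function(n_res_a = 60L, n_res_b = 50L, seed = 1L,
                             pdb_id = "TOYC", chain_ids = c("A", "B")) {
  stopifnot(n_res_a >= 3L, n_res_b >= 3L)
  seqs <- .with_seed(seed, list(
    a = paste(sample(AA_ALPHABET, n_res_a, replace = TRUE), collapse = ""),
    b = paste(sample(AA_ALPHABET, n_res_b, replace = TRUE), collapse = "")))
  lines <- c(sprintf("HEADER    SYNTHETIC TOY COMPLEX                   %s", pdb_id))
  serial <- 0L
  emit_chain <- function(seqstr, chain, y_off, x_off) {
    letters1 <- strsplit(seqstr, "")[[1]]
    out <- character(0)
    for (i in seq_along(letters1)) {
      ca <- c(3.8 * (i - 1L) + x_off, y_off, 0)
      res3 <- AA1TO3[[letters1[i]]]
      for (atom in list(c(" N  ", -1.20, 0.85, "N"), c(" CA ", 0, 0, "C"),
                        c(" C  ", 1.20, 0.85, "C"))) {
        serial <<- serial + 1L
        out <- c(out, .pdb_atom_line(serial, atom[1L], res3, chain, i,
                                     ca[1L] + as.numeric(atom[2L]),
                                     ca[2L] + as.numeric(atom[3L]),
                                     ca[3L], atom[4L]))
      }
    }
    out
  }
  # chain B midpoints sit between chain A CA positions: nearest
  # cross-partner CA distance is sqrt(1.9^2 + 3.5^2) ~ 3.98 A < 4 A.
  lines <- c(lines, emit_chain(seqs$a, chain_ids[1L], 0, 0),
             "TER",
             emit_chain(seqs$b, chain_ids[2L], 3.5, 1.9),
             "TER", "END")
  list(pdb_text = lines, pdb_id = pdb_id,
       partner_spec = list(a = chain_ids[1L], b = chain_ids[2L]),
       sequence_a = seqs$a, sequence_b = seqs$b)
}

#' Write a toy complex to a PDB file and load it back
#'
#' @param toy Result of [make_toy_complex()].
#' @param path Output path; a temporary file by default.
#' @return `write_toy_complex()`: the path; `load_toy_complex()`: the
#'   [complex_structure()] obtained by round-tripping through the PDB
#'   loader.
#' @export
write_toy_complex <- function(toy, path = tempfile(fileext = ".pdb")) {
  writeLines(toy$pdb_text, path)
  path
}

#' @rdname write_toy_complex
#' @export
load_toy_complex <- function(toy, path = tempfile(fileext = ".pdb")) {
  load_complex(write_toy_complex(toy, path), toy$partner_spec,
               pdb_id = toy$pdb_id, quiet = TRUE)
}

#' Generate a unique mutation set over a complex
#'
#' Samples `n_single` single substitutions and `n_double` double
#' substitutions (two distinct sites) uniformly without replacement from
#' all possibilities consistent with the complex's sequences. Every
#' returned record passes [apply_mutation()] by construction; ddG is
#' left unset (`NA`) for [make_synthetic_ddg()] to fill.
#'
#' @param structure A [complex_structure()].
#' @param n_single,n_double Counts (must be feasible for the sequence
#'   lengths; 19 mutants per site).
#' @param seed Integer seed.
#' @return List of [mutation_record()]s.
#' @export
make_mutation_set <- function(structure, n_single, n_double = 0L, seed = 1L) {
  ridx <- complex_residue_index(structure)
  all_single <- do.call(rbind, lapply(seq_len(nrow(ridx)), function(i) {
    muts <- setdiff(AA_ALPHABET, ridx$letter[i])
    data.frame(chain_id = ridx$chain_id[i], position = ridx$position[i],
               wt_aa = ridx$letter[i], mut_aa = muts, stringsAsFactors = FALSE)
  }))
  if (n_single > nrow(all_single))
    stop("requested ", n_single, " unique single mutations but only ",
         nrow(all_single), " are possible")
  .with_seed(seed, {
    singles <- all_single[sample(nrow(all_single), n_single), , drop = FALSE]
    recs <- lapply(seq_len(nrow(singles)), function(i)
      mutation_record(structure$pdb_id,
                      list(mutation_spec(singles$chain_id[i], singles$position[i],
                                         singles$wt_aa[i], singles$mut_aa[i])),
                      NA_real_, source = "inhouse"))
    if (n_double > 0L) {
      # site pairs within one chain (the in-house dialect names one chain
      # per row, mirroring inhibitor-side double-mutant scans)
      pair_list <- do.call(rbind, lapply(split(seq_len(nrow(ridx)), ridx$chain_id),
                                         function(idx) {
        if (length(idx) < 2L) return(NULL)
        t(utils::combn(idx, 2L))
      }))
      if (n_double > nrow(pair_list))
        stop("requested more double mutations than same-chain site pairs available")
      chosen <- pair_list[sample(nrow(pair_list), n_double), , drop = FALSE]
      doubles <- lapply(seq_len(nrow(chosen)), function(r) {
        specs <- lapply(chosen[r, ], function(i)
          mutation_spec(ridx$chain_id[i], ridx$position[i], ridx$letter[i],
                        sample(setdiff(AA_ALPHABET, ridx$letter[i]), 1L)))
        mutation_record(structure$pdb_id, specs, NA_real_, source = "inhouse")
      })
      recs <- c(recs, doubles)
    }
    recs
  })
}

#' Generate synthetic ddG targets with known ground truth
#'
#' Draws a sparse weight vector `w` with `informative_dims` nonzero
#' entries over the feature columns (restricted to columns with nonzero
#' empirical variance, since e.g. the structural block is constant within
#' a single complex) and sets `target_i = w . x_i + eps_i`,
#' `eps ~ Normal(0, noise_sd^2)`. Weights are rescaled so the noise-free
#' signal has SD `signal_sd` kcal/mol (default 3, giving a realistic
#' roughly -12..+12 kcal/mol range).
#'
#' @param features n x 1792 feature matrix from [featurize_dataset()].
#' @param informative_dims Number of signal-carrying columns (k <= 1792).
#' @param noise_sd Gaussian noise SD, kcal/mol. May also be given as
#'   `noise_ratio` times the realized signal SD via the `noise_ratio`
#'   argument (exactly one of the two).
#' @param seed Integer seed.
#' @param signal_sd Target SD of the noise-free signal, kcal/mol.
#' @param noise_ratio Optional; noise SD as a fraction of signal SD.
#' @return List with `targets`, `weights` (full-width vector),
#'   `informative_idx`, `signal_sd` (realized), `noise_sd`, `seed`.
#' @export
make_synthetic_ddg <- function(features, informative_dims = 20L, noise_sd = 0,
                               seed = 1L, signal_sd = 3.0, noise_ratio = NULL) {
  p <- ncol(features)
  if (informative_dims > p)
    stop("informative_dims (", informative_dims, ") exceeds feature width (", p, ")")
  col_sd <- apply(features, 2L, stats::sd)
  candidates <- which(col_sd > 0)
  if (length(candidates) < informative_dims)
    stop("zero signal variance: only ", length(candidates),
         " feature columns vary")
  .with_seed(seed, {
    idx <- sort(sample(candidates, informative_dims))
    w <- numeric(p)
    w[idx] <- stats::rnorm(informative_dims)
    signal <- as.numeric(features %*% w)
    realized <- stats::sd(signal)
    if (realized == 0) stop("zero signal variance with the drawn weights")
    scale <- signal_sd / realized
    w <- w * scale
    signal <- signal * scale
    if (!is.null(noise_ratio)) noise_sd <- noise_ratio * stats::sd(signal)
    targets <- signal + stats::rnorm(length(signal), 0, noise_sd)
    list(targets = targets, weights = w, informative_idx = idx,
         signal_sd = stats::sd(signal), noise_sd = noise_sd, seed = seed)
  })
}

#' Emit a complete on-disk fixture
#'
#' Writes `complex.pdb`, `mutations.csv` (in-house dialect) and
#' `truth.json` (weights, noise, seed) under `dir`, running the full
#' generator chain: toy complex, mutation set, mock embeddings, feature
#' assembly, synthetic ddG.
#'
#' @param dir Output directory.
#' @param config A [fixture_config()].
#' @return List with paths, the loaded structure, records (ddG filled
#'   in), the featurized set and the ground truth.
#' @export
write_fixture <- function(dir, config = fixture_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_complex(config$n_res_a, config$n_res_b, seed = config$seed)
  pdb_path <- write_toy_complex(toy, file.path(dir, "complex.pdb"))
  structure <- load_complex(pdb_path, toy$partner_spec, pdb_id = toy$pdb_id,
                            quiet = TRUE)
  records <- make_mutation_set(structure, config$n_single, config$n_double,
                               seed = config$seed + 1L)
  featurized <- featurize_dataset(
    records, stats::setNames(list(structure), toy$pdb_id),
    mock_sequence_provider(seed = config$seed),
    mock_structure_provider(seed = config$seed), quiet = TRUE)
  truth <- make_synthetic_ddg(featurized$features, config$informative_dims,
                              noise_sd = config$noise_sd,
                              seed = config$seed + 2L)
  for (i in seq_along(featurized$records))
    featurized$records[[i]]$ddg_exp <- truth$targets[i]
  featurized$targets <- truth$targets

  mut_path <- file.path(dir, "mutations.csv")
  df <- data.frame(
    pdb_id = record_pdb_ids(featurized$records),
    chain = vapply(featurized$records, function(r) r$mutations[[1L]]$chain_id, ""),
    mutation = vapply(featurized$records, function(r)
      paste(vapply(r$mutations, function(m)
        paste0(m$wt_aa, m$position, m$mut_aa), ""), collapse = ","), ""),
    ddg = record_ddg(featurized$records),
    stringsAsFactors = FALSE)
  utils::write.csv(df, mut_path, row.names = FALSE, quote = TRUE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(weights = truth$weights,
                            informative_idx = truth$informative_idx,
                            signal_sd = truth$signal_sd,
                            noise_sd = truth$noise_sd, seed = truth$seed,
                            config = unclass(config)),
                       truth_path, auto_unbox = TRUE, digits = NA)
  list(pdb_path = pdb_path, mutations_path = mut_path, truth_path = truth_path,
       structure = structure, records = featurized$records,
       featurized = featurized, truth = truth)
}
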