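#' Root-mean-square error
#'
#' `sqrt(mean((exp - pred)^2))`, in kcal/mol when the inputs are ddG
#' values.
#'
#' @param pred,exp Equal-length numeric vectors (n >= 1).
#' @return Non-negative scalar.
#' @export
rmse <- function(pred, exp) {
  if (length(pred) != length(exp))
    stop("length mismatch: ", length(pred), " vs ", length(exp))
  if (!length(pred)) stop("empty input")
  sqrt(mean((exp - pred)^2))
}

#' Correlation between predictions and experiment
#'
#' Standard product-moment (`pearson`) and rank (`spearman`) correlation
#' coefficients. Undefined for fewer than 3 points or zero variance in
#' either argument (an error, not NA).
#'
#' @param pred,exp Equal-length numeric vectors.
#' @return Scalar in \[-1, 1\].
#' @export
pearson <- function(pred, exp) .cor_checked(pred, exp, "pearson")

#' @rdname pearson
#' @export
spearman <- function(pred, exp) .cor_checked(pred, exp, "spearman")

.cor_checked <- function(pred, exp, method) {
  if (length(pred) != length(exp))
    stop("length mismatch: ", length(pred), " vs ", length(exp))
  if (length(pred) < 3L) stop("correlation needs at least 3 points")
  if (stats::sd(pred) == 0 || stats::sd(exp) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(pred, exp, method = method)
}

# Run expr under a fixed seed with the global RNG state restored after.
.with_seed <- function(seed, expr) {
  .with_preserved_rng({
    set.seed(seed)
    expr
  })
}

new_split_spec <- function(mode, train_idx, test_idx, seed = NA_integer_,
                           params = list()) {
  if (length(intersect(train_idx, test_idx)))
    stop("train and test sets overlap")
  if (!length(test_idx)) stop("test set is empty")
  structure(list(mode = mode, train_idx = sort(train_idx),
                 test_idx = sort(test_idx), seed = seed, params = params),
            class = "split_spec")
}

#' Random within-dataset train/test split
#'
#' Uniform random assignment of records to an 80/20 (by default)
#' train/test partition, deterministic for a given seed.
#'
#' @param n Number of records (>= 5), or a list of records.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A `split_spec` with disjoint `train_idx` / `test_idx`;
#'   `length(test_idx) == round((1 - train_fraction) * n)`.
#' @export
random_within_split <- function(n, train_fraction = 0.8, seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (n < 5L) stop("need at least 5 records to split, got ", n)
  n_test <- round((1 - train_fraction) * n)
  if (n_test < 1L || n_test >= n) stop("degenerate split at train_fraction = ",
                                       train_fraction)
  test_idx <- .with_seed(seed, sample(n, n_test))
  new_split_spec("random_within", setdiff(seq_len(n), test_idx), test_idx,
                 seed, list(train_fraction = train_fraction))
}

#' Leave-one-complex-out split
#'
#' All mutations of the held-out complex form the test set; every other
#' record trains. Zero leakage is asserted on every call, never assumed.
#'
#' @param pdb_ids Character vector of per-record complex ids, or a list
#'   of records.
#' @param held_out Complex id to hold out (>= 1 record).
#' @return A `split_spec`.
#' @export
leave_one_pdb_out_split <- function(pdb_ids, held_out) {
  if (is.list(pdb_ids)) pdb_ids <- record_pdb_ids(pdb_ids)
  test_idx <- which(pdb_ids == held_out)
  if (!length(test_idx))
    stop("complex '", held_out, "' has no records")
  train_idx <- which(pdb_ids != held_out)
  stopifnot(length(intersect(pdb_ids[train_idx], held_out)) == 0L)
  new_split_spec("leave_one_pdb_out", train_idx, test_idx,
                 params = list(held_out = held_out))
}

new_eval_report <- function(per_repeat, n_test, mode, params = list()) {
  rep <- as.data.frame(per_repeat)
  structure(list(pearson_r = mean(rep$pearson), spearman_r = mean(rep$spearman),
                 rmse = mean(rep$rmse), n_test = n_test, per_repeat = rep,
                 mean_r = mean(rep$pearson), sd_r = stats::sd(rep$pearson),
                 mode = mode, params = params),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$mode, "| n_test", x$n_test, "| Pearson r",
      sprintf("%.3f", x$mean_r),
      if (!is.na(x$sd_r)) sprintf("+/- %.3f", x$sd_r) else "",
      "| Spearman", sprintf("%.3f", x$spearman_r),
      "| RMSE", sprintf("%.3f", x$rmse), "kcal/mol\n")
  invisible(x)
}

# One train + predict + score cycle on a fixed split.
.score_split <- function(features, targets, split, hyperparameters, learner_seed) {
  model <- train_ddg_model(features[split$train_idx, , drop = FALSE],
                           targets[split$train_idx],
                           hyperparameters, seed = learner_seed)
  pred <- predict_ddg(model, features[split$test_idx, , drop = FALSE])
  exp <- targets[split$test_idx]
  list(pred = pred, exp = exp, test_idx = split$test_idx,
       pearson = pearson(pred, exp), spearman = spearman(pred, exp),
       rmse = rmse(pred, exp))
}

#' Run an evaluation protocol
#'
#' Executes one of the pipeline's evaluation protocols, repeating the
#' train/predict/score cycle with the published seed list and reporting
#' the mean and SD of the correlation across repeats:
#'
#' * `random_within` — random 80/20 split of the supplied records; each
#'   repeat resamples both the split and the learner seed. Used both
#'   within a single complex and on the whole dataset (3 and 5 repeats
#'   respectively, by convention).
#' * `leave_one_pdb_out` — all records of `held_out` form the test set;
#'   repeats vary the learner seed only. Train/test complex disjointness
#'   is asserted on every run.
#' * `cross_pdb` — train on every record of `source_pdb`, test on every
#'   record of `target_pdb`.
#'
#' @param features n x 1792 design matrix aligned to `targets`.
#' @param targets Experimental ddG vector.
#' @param mode Protocol name (above).
#' @param pdb_ids Per-record complex ids (required for the complex-aware
#'   modes).
#' @param repeats Number of repeats; defaults to 3 (single-complex
#'   convention) unless `seeds` is given.
#' @param seeds Integer vector of repeat seeds; default `101, 102, ...`.
#' @param train_fraction Training fraction for `random_within`.
#' @param held_out,source_pdb,target_pdb Complex ids for the
#'   complex-aware modes.
#' @param hyperparameters Learner settings, see [default_hyperparameters()].
#' @return An `eval_report`; attribute `"predictions"` holds the last
#'   repeat's per-record (index, exp, pred) table.
#' @export
run_protocol <- function(features, targets,
                         mode = c("random_within", "leave_one_pdb_out", "cross_pdb"),
                         pdb_ids = NULL, repeats = NULL, seeds = NULL,
                         train_fraction = 0.8, held_out = NULL,
                         source_pdb = NULL, target_pdb = NULL,
                         hyperparameters = default_hyperparameters()) {
  mode <- match.arg(mode)
  if (nrow(features) != length(targets))
    stop("features and targets are not aligned")
  if (is.null(repeats)) repeats <- if (is.null(seeds)) 3L else length(seeds)
  if (is.null(seeds)) seeds <- 100L + seq_len(repeats)
  if (length(seeds) != repeats) stop("need one seed per repeat")

  per <- vector("list", repeats)
  last <- NULL
  for (k in seq_len(repeats)) {
    res <- tryCatch({
      split <- switch(mode,
        random_within = random_within_split(length(targets), train_fraction,
                                            seed = seeds[k]),
        leave_one_pdb_out = {
          if (is.null(pdb_ids) || is.null(held_out))
            stop("leave_one_pdb_out needs pdb_ids and held_out")
          leave_one_pdb_out_split(pdb_ids, held_out)
        },
        cross_pdb = {
          if (is.null(pdb_ids) || is.null(source_pdb) || is.null(target_pdb))
            stop("cross_pdb needs pdb_ids, source_pdb and target_pdb")
          tr <- which(pdb_ids == source_pdb)
          te <- which(pdb_ids == target_pdb)
          if (!length(tr)) stop("source complex '", source_pdb, "' has no records")
          new_split_spec("cross_pdb", tr, te,
                         params = list(source_pdb = source_pdb,
                                       target_pdb = target_pdb))
        })
      .score_split(features, targets, split, hyperparameters,
                   learner_seed = seeds[k])
    }, error = function(e)
      stop("repeat ", k, " (seed ", seeds[k], ") failed: ",
           conditionMessage(e), call. = FALSE))
    per[[k]] <- data.frame(seed = seeds[k], pearson = res$pearson,
                           spearman = res$spearman, rmse = res$rmse)
    last <- res
  }
  report <- new_eval_report(do.call(rbind, per), n_test = length(last$test_idx),
                            mode = mode,
                            params = list(train_fraction = train_fraction,
                                          held_out = held_out,
                                          source_pdb = source_pdb,
                                          target_pdb = target_pdb,
                                          seeds = seeds))
  attr(report, "predictions") <- data.frame(index = last$test_idx,
                                            exp = last$exp, pred = last$pred)
  report
}

#' Learning curve with a fixed test half and nested training subsets
#'
#' The records are split once into two equal halves: a training pool and
#' a fixed test half. The training set then grows in `fraction_step`
#' increments of the full dataset up to `max_fraction`, each subset
#' extending the previous one (nested), with the test half identical
#' across all points.
#'
#' @param features,targets Aligned design matrix and ddG vector.
#' @param fraction_step Increment (default 0.05).
#' @param max_fraction Largest training fraction (default 0.5).
#' @param seed Seed fixing the half split and the nesting order.
#' @param hyperparameters Learner settings.
#' @return List of `list(train_fraction, report)` per point (e.g. 10
#'   points for 0.05..0.50), with attribute `"test_idx"`.
#' @export
learning_curve <- function(features, targets, fraction_step = 0.05,
                           max_fraction = 0.5, seed = 1L,
                           hyperparameters = default_hyperparameters()) {
  n <- length(targets)
  fractions <- seq(fraction_step, max_fraction, by = fraction_step)
  if (round(fractions[1L] * n) < 10L)
    stop("too few records (", n, ") for the smallest training fraction ",
         fractions[1L])
  perm <- .with_seed(seed, sample(n))
  pool <- perm[seq_len(floor(n / 2))]
  test_idx <- perm[(floor(n / 2) + 1L):n]
  out <- lapply(fractions, function(f) {
    n_train <- min(round(f * n), length(pool))
    split <- new_split_spec("learning_curve", pool[seq_len(n_train)], test_idx,
                            seed, list(train_fraction = f))
    res <- .score_split(features, targets, split, hyperparameters,
                        learner_seed = seed)
    list(train_fraction = f,
         report = new_eval_report(
           data.frame(seed = seed, pearson = res$pearson,
                      spearman = res$spearman, rmse = res$rmse),
           n_test = length(test_idx), mode = "learning_curve",
           params = list(train_fraction = f)))
  })
  attr(out, "test_idx") <- sort(test_idx)
  out
}

#' Experimental-noise correlation ceiling
#'
#' Estimates the maximum achievable prediction-experiment correlation
#' given per-measurement experimental error: each simulation adds
#' independent Gaussian noise (mean 0, per-point SD from `errors`) to the
#' measured values and records the correlation of the noisy replicate
#' with the original. With homoscedastic noise of SD `s_n` on a signal of
#' SD `s_s` the mean ceiling approaches the attenuation factor
#' `s_s / sqrt(s_s^2 + s_n^2)`.
#'
#' @param values Measured ddG vector.
#' @param errors Per-measurement SDs (same length, all >= 0).
#' @param n_sim Number of simulations (default 1000).
#' @param seed Integer seed.
#' @return List with `r` (length `n_sim` vector of correlations),
#'   `mean_r`, `sd_r`.
#' @export
noise_ceiling <- function(values, errors, n_sim = 1000L, seed = 1L) {
  if (length(values) != length(errors))
    stop("values and errors must be the same length")
  if (any(errors < 0)) stop("negative measurement error")
  n <- length(values)
  r <- .with_seed(seed, vapply(seq_len(n_sim), function(i) {
    noisy <- values + stats::rnorm(n, 0, errors)
    stats::cor(noisy, values)
  }, 0))
  list(r = r, mean_r = mean(r), sd_r = stats::sd(r))
}

# Residue classes discussed in the outlier analysis.
DEFAULT_RESIDUE_CLASSES <- list(
  hydrophobic = c("F", "I", "L", "Y", "M", "V"),
  polar = c("D", "E", "K", "N", "Q", "R"),
  structure_disrupting = c("P", "G", "N"))

#' Residual-outlier residue-class enrichment
#'
#' Fits an ordinary least-squares line of predicted on experimental ddG
#' and flags records whose residual exceeds `threshold_sd` residual
#' standard deviations. Positive residuals (prediction above the line)
#' are over-destabilizing, negative over-stabilizing, under the
#' convention positive ddG = destabilizing. For each residue class and
#' each outlier direction, an exact binomial tail p-value is computed
#' against the class's frequency among the substituted-in residues of
#' all evaluated single mutations (the dataset composition null, not a
#' uniform null). P-values are reported raw; `holm = TRUE` applies a
#' Holm adjustment.
#'
#' @param pred,exp Aligned prediction and experimental vectors (n >= 10).
#' @param records The evaluated [mutation_record()]s (same order). Only
#'   single-mutation records enter the residue-class tests.
#' @param threshold_sd Outlier threshold in residual SDs (default 1.0).
#' @param classes Named list of one-letter residue classes.
#' @param holm Apply Holm multiple-testing adjustment (default FALSE).
#' @return An `enrichment_report`: `outlier_indices`, `direction`,
#'   `class_tests` (data.frame: direction, class, k, n, background_p,
#'   p_value, status), plus the fitted line and residual SD.
#' @export
outlier_enrichment <- function(pred, exp, records, threshold_sd = 1.0,
                               classes = DEFAULT_RESIDUE_CLASSES,
                               holm = FALSE) {
  if (length(pred) < 10L) stop("need at least 10 points")
  if (length(pred) != length(exp) || length(pred) != length(records))
    stop("pred, exp and records must be aligned")
  if (stats::sd(exp) == 0 || stats::sd(pred) == 0)
    stop("degenerate regression: zero variance")
  fit <- stats::lm(pred ~ exp)
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  out_idx <- unname(which(abs(res) > threshold_sd * s))
  direction <- unname(ifelse(res[out_idx] > 0,
                             "over_destabilizing", "over_stabilizing"))

  single <- record_n_mutations(records) == 1L
  mut_letter <- rep(NA_character_, length(records))
  mut_letter[single] <- vapply(records[single],
                               function(r) r$mutations[[1L]]$mut_aa, "")
  background <- mut_letter[single]

  tests <- list()
  for (dir in c("over_destabilizing", "over_stabilizing")) {
    idx <- out_idx[direction == dir]
    letters_out <- mut_letter[idx]
    letters_out <- letters_out[!is.na(letters_out)]
    n_out <- length(letters_out)
    if (!n_out) next
    for (cl in names(classes)) {
      p0 <- mean(background %in% classes[[cl]])
      if (p0 == 0 || p0 == 1) next
      k <- sum(letters_out %in% classes[[cl]])
      enriched <- k / n_out >= p0
      pv <- if (enriched) stats::pbinom(k - 1L, n_out, p0, lower.tail = FALSE)
      else stats::pbinom(k, n_out, p0)
      tests[[length(tests) + 1L]] <-
        data.frame(direction = dir, class = cl, k = k, n = n_out,
                   background_p = p0, p_value = pv,
                   status = if (enriched) "enriched" else "depleted",
                   stringsAsFactors = FALSE)
    }
  }
  class_tests <- if (length(tests)) do.call(rbind, tests)
  else data.frame(direction = character(0), class = character(0),
                  k = integer(0), n = integer(0), background_p = numeric(0),
                  p_value = numeric(0), status = character(0))
  if (holm && nrow(class_tests))
    class_tests$p_adjusted <- stats::p.adjust(class_tests$p_value, "holm")
  structure(list(outlier_indices = out_idx, direction = direction,
                 class_tests = class_tests, residual_sd = s,
                 fit_coefficients = stats::coef(fit),
                 threshold_sd = threshold_sd),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>", length(x$outlier_indices), "outliers beyond",
      x$threshold_sd, "residual SD (",
      sum(x$direction == "over_destabilizing"), "over-destabilizing,",
      sum(x$direction == "over_stabilizing"), "over-stabilizing )\n")
  if (nrow(x$class_tests)) print(x$class_tests, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits the report as JSON plus a flat CSV of per-record experimental
#' value, prediction, residual and outlier flag (scatter-plot ready).
#'
#' @param report An `eval_report` (with `"predictions"` attribute).
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Invisible character vector of the paths written.
#' @export
write_eval_report <- function(report, dir, name = report$mode) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(name, ".json"))
  body <- list(mode = report$mode, pearson_r = report$pearson_r,
               spearman_r = report$spearman_r, rmse = report$rmse,
               n_test = report$n_test, mean_r = report$mean_r,
               sd_r = report$sd_r, per_repeat = report$per_repeat,
               params = report$params[!vapply(report$params, is.null, TRUE)])
  jsonlite::write_json(body, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- json_path
  predictions <- attr(report, "predictions")
  if (!is.null(predictions)) {
    predictions$residual <- predictions$pred - predictions$exp
    csv_path <- file.path(dir, paste0(name, "_predictions.csv"))
    utils::write.csv(predictions, csv_path, row.names = FALSE)
    paths <- c(paths, csv_path)
  }
  invisible(paths)
}
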