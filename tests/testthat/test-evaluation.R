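test_that("rmse matches hand values and the direct-formula oracle", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmse(2, 5), 3)
  expect_error(rmse(1:3, 1:4), "length")
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(rmse(a, b), rmse_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("correlations match oracles and handle degenerate input", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 3), 1)
  expect_equal(spearman(x, exp(x)), 1)          # monotone transform
  expect_equal(pearson(x, -3 * x + 1), -1)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(pearson(a, b), pearson_oracle(a, b), tolerance = 1e-12)
    expect_equal(spearman(a, b), spearman_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("correlations are invariant under increasing affine maps", {
  set.seed(12)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(2.5 * a + 1, b), pearson(a, b))
  expect_equal(spearman(a, 10 * b - 4), spearman(a, b))
  expect_equal(spearman(a, b^3), spearman(a, b))  # monotone, non-affine
})

test_that("random splits have the stated sizes and are seed-deterministic", {
  s100 <- random_within_split(100, 0.8, seed = 5)
  expect_length(s100$test_idx, 20L)
  expect_length(s100$train_idx, 80L)
  expect_length(intersect(s100$train_idx, s100$test_idx), 0L)
  expect_identical(random_within_split(100, 0.8, seed = 5), s100)
  expect_false(identical(random_within_split(100, 0.8, seed = 6)$test_idx,
                         s100$test_idx))
  s10 <- random_within_split(10, 0.8, seed = 1)
  expect_length(s10$test_idx, 2L)
  expect_error(random_within_split(4, 0.8, 1), "at least 5")
})

test_that("leave-one-complex-out splits have zero leakage", {
  pdbs <- rep(c("AAAA", "BBBB", "CCCC"), c(5, 6, 7))
  sp <- leave_one_pdb_out_split(pdbs, "CCCC")
  expect_length(sp$train_idx, 11L)
  expect_length(sp$test_idx, 7L)
  expect_length(intersect(pdbs[sp$train_idx], pdbs[sp$test_idx]), 0L)
  expect_error(leave_one_pdb_out_split(pdbs, "DDDD"), "no records")
})

test_that("run_protocol repeats, reports and reproduces", {
  fz <- multi_complex_featurized()
  rep3 <- run_protocol(fz$features, fz$targets, mode = "random_within",
                       repeats = 3, hyperparameters = fast_hp())
  expect_equal(nrow(rep3$per_repeat), 3L)
  expect_equal(rep3$per_repeat$seed, c(101L, 102L, 103L))
  expect_equal(rep3$mean_r, mean(rep3$per_repeat$pearson))
  rep3b <- run_protocol(fz$features, fz$targets, mode = "random_within",
                        repeats = 3, hyperparameters = fast_hp())
  expect_identical(rep3$per_repeat, rep3b$per_repeat)

  pdbs <- record_pdb_ids(fz$records)
  loo <- run_protocol(fz$features, fz$targets, mode = "leave_one_pdb_out",
                      pdb_ids = pdbs, held_out = "TOY2", repeats = 2,
                      hyperparameters = fast_hp())
  expect_equal(loo$n_test, sum(pdbs == "TOY2"))
  preds <- attr(loo, "predictions")
  expect_setequal(preds$index, which(pdbs == "TOY2"))

  cross <- run_protocol(fz$features, fz$targets, mode = "cross_pdb",
                        pdb_ids = pdbs, source_pdb = "TOY3",
                        target_pdb = "TOY1", repeats = 1,
                        hyperparameters = fast_hp())
  expect_equal(cross$n_test, sum(pdbs == "TOY1"))
})

test_that("learning curve keeps the test half fixed and nests training sets", {
  fz <- recovery_fixture()
  idx <- seq_len(400)                      # structural check at modest size
  curve <- learning_curve(fz$features[idx, ], fz$targets[idx],
                          fraction_step = 0.05, max_fraction = 0.5,
                          seed = 9, hyperparameters = fast_hp())
  expect_length(curve, 10L)
  fracs <- vapply(curve, `[[`, 0, "train_fraction")
  expect_equal(fracs, seq(0.05, 0.5, 0.05))
  expect_true(all(diff(fracs) > 0))
  expect_equal(length(attr(curve, "test_idx")), 200L)
  expect_error(learning_curve(fz$features[1:50, ], fz$targets[1:50],
                              seed = 1, hyperparameters = fast_hp()),
               "too few")
})

test_that("noise ceiling reduces to known limits", {
  set.seed(13)
  vals <- rnorm(200, 0, 2)
  # zero error: every replicate correlates perfectly
  nc0 <- noise_ceiling(vals, rep(0, 200), n_sim = 50, seed = 1)
  expect_equal(nc0$r, rep(1, 50))
  expect_error(noise_ceiling(vals, rep(-1, 200), 10, 1), "negative")
  expect_error(noise_ceiling(vals, rep(0, 10), 10, 1), "length")
  # determinism
  nc1 <- noise_ceiling(vals, rep(1, 200), n_sim = 100, seed = 2)
  nc2 <- noise_ceiling(vals, rep(1, 200), n_sim = 100, seed = 2)
  expect_identical(nc1$r, nc2$r)
  # ceiling shrinks (in expectation) as errors scale up
  m1 <- noise_ceiling(vals, rep(1, 200), n_sim = 500, seed = 3)$mean_r
  m2 <- noise_ceiling(vals, rep(2, 200), n_sim = 500, seed = 3)$mean_r
  m4 <- noise_ceiling(vals, rep(4, 200), n_sim = 500, seed = 3)$mean_r
  expect_true(m1 > m2 && m2 > m4)
})

test_that("an extreme residual is the only flagged outlier", {
  set.seed(14)
  n <- 60
  exp <- seq(-3, 3, length.out = n)
  pred <- exp + rnorm(n, 0, 0.1)
  pred[30] <- exp[30] + 5 * sd(pred - exp)    # one gross over-prediction
  recs <- lapply(seq_len(n), function(i)
    mutation_record("XXXX", mutation_spec("A", as.character(i), "K", "A"),
                    exp[i]))
  enr <- outlier_enrichment(pred, exp, recs, threshold_sd = 3)
  expect_equal(enr$outlier_indices, 30L)
  expect_equal(enr$direction, "over_destabilizing")
  # huge threshold: no outliers, no tests
  none <- outlier_enrichment(pred, exp, recs, threshold_sd = 50)
  expect_length(none$outlier_indices, 0L)
  expect_equal(nrow(none$class_tests), 0L)
  expect_error(outlier_enrichment(rep(1, n), exp, recs), "zero variance")
})

test_that("class enrichment reproduces the exact binomial tail", {
  # 100 single mutations; 30 substituted-in residues are hydrophobic
  # (background 0.3); 10 clean over-destabilizing outliers, 8 hydrophobic.
  n <- 100
  mut_aa <- c(rep("L", 8),  rep("S", 2),   # the 10 outliers-to-be
              rep("V", 22), rep("T", 68))  # 22 + 8 hydrophobic = 30 total
  exp <- seq(-4, 4, length.out = n)
  pred <- exp
  out_rows <- seq(5, 95, by = 10)          # spread across the range
  stopifnot(length(out_rows) == 10L)
  reorder <- c(out_rows, setdiff(seq_len(n), out_rows))
  letters_by_row <- character(n)
  letters_by_row[reorder] <- mut_aa
  pred[out_rows] <- pred[out_rows] + 3     # big positive residuals
  recs <- lapply(seq_len(n), function(i)
    mutation_record("XXXX", mutation_spec("A", as.character(i), "K",
                                          letters_by_row[i]), exp[i]))
  enr <- outlier_enrichment(pred, exp, recs, threshold_sd = 1)
  expect_setequal(enr$outlier_indices, out_rows)
  expect_true(all(enr$direction == "over_destabilizing"))
  hydro <- subset(enr$class_tests,
                  direction == "over_destabilizing" & class == "hydrophobic")
  expect_equal(hydro$k, 8L)
  expect_equal(hydro$n, 10L)
  expect_equal(hydro$background_p, 0.3)
  expect_equal(hydro$status, "enriched")
  # independent oracle: explicit tail sum P(K >= 8), K ~ Binom(10, 0.3)
  tail_sum <- sum(choose(10, 8:10) * 0.3^(8:10) * 0.7^(10 - (8:10)))
  expect_equal(hydro$p_value, tail_sum, tolerance = 1e-12)
})
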