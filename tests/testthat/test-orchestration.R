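# Build a complete on-disk run: fixture data + YAML config.
make_run_dir <- function(n_single = 30, protocol = list(mode = "random_within",
                                                        repeats = 2)) {
  dir <- tempfile("run")
  dir.create(file.path(dir, "structures"), recursive = TRUE)
  tabs <- list()
  partner_specs <- list()
  for (i in 1:2) {
    pdb_id <- paste0("FIX", i)
    toy <- make_toy_complex(10, 8, seed = 40 + i, pdb_id = pdb_id)
    write_toy_complex(toy, file.path(dir, "structures", paste0(pdb_id, ".pdb")))
    s <- load_complex(file.path(dir, "structures", paste0(pdb_id, ".pdb")),
                      toy$partner_spec, pdb_id = pdb_id, quiet = TRUE)
    recs <- make_mutation_set(s, n_single, seed = 50 + i)
    fz <- featurize_dataset(recs, stats::setNames(list(s), pdb_id),
                            mock_sequence_provider(1), mock_structure_provider(1),
                            quiet = TRUE)
    truth <- make_synthetic_ddg(fz$features, 8, noise_sd = 0.3, seed = 60 + i)
    df <- data.frame(
      pdb_id = pdb_id,
      chain = vapply(recs, function(r) r$mutations[[1]]$chain_id, ""),
      mutation = vapply(recs, function(r)
        paste0(r$mutations[[1]]$wt_aa, r$mutations[[1]]$position,
               r$mutations[[1]]$mut_aa), ""),
      ddg = truth$targets, stringsAsFactors = FALSE)
    tab <- file.path(dir, paste0("muts", i, ".csv"))
    utils::write.csv(df, tab, row.names = FALSE)
    tabs[[i]] <- list(path = tab, dialect = "inhouse_like")
    partner_specs[[pdb_id]] <- list("A", "B")
  }
  cfg <- list(
    data = list(mutation_tables = tabs,
                structure_dir = file.path(dir, "structures"),
                partner_specs = partner_specs),
    providers = list(mock = TRUE, mock_seed = 1,
                     cache_dir = file.path(dir, "cache")),
    regressor = list(iterations = 25),
    protocol = protocol,
    output_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(dir = dir, cfg_path = cfg_path)
}

test_that("configs validate paths and protocol modes", {
  run <- make_run_dir()
  cfg <- read_run_config(run$cfg_path)
  expect_s3_class(cfg, "run_config")
  expect_true(nzchar(cfg$digest))
  expect_error(read_run_config(file.path(run$dir, "nope.yaml")), "not found")
  expect_error(read_run_config(run$cfg_path,
                               overrides = list(protocol = list(mode = "bogus"))),
               "unknown protocol mode")
})

test_that("featurize -> train -> evaluate pipeline runs and reproduces", {
  run <- make_run_dir()
  cfg <- read_run_config(run$cfg_path)
  cmd_featurize(cfg, quiet = TRUE)
  feats <- file.path(cfg$output_dir, "features.csv")
  expect_true(file.exists(feats))
  header <- strsplit(readLines(feats, n = 1), ",")[[1]]
  expect_length(header, 1793L)          # ddg_exp + 1792 features
  expect_true(file.exists(paste0(feats, ".meta.json")))

  cmd_train(cfg, quiet = TRUE)
  model <- load_ddg_model(file.path(cfg$output_dir, "model.rds"))
  expect_equal(model$feature_schema$width, 1792L)
  expect_equal(model$hyperparameters$iterations, 25L)

  rep1 <- cmd_evaluate(cfg, quiet = TRUE)
  expect_s3_class(rep1, "eval_report")
  report_path <- file.path(cfg$output_dir, "random_within.json")
  expect_true(file.exists(report_path))
  bytes1 <- readLines(report_path)
  rep2 <- cmd_evaluate(cfg, quiet = TRUE)
  expect_identical(readLines(report_path), bytes1)   # deterministic re-run
  expect_equal(rep2$per_repeat, rep1$per_repeat)

  # warm-cache featurize rerun is byte-identical
  before <- readLines(feats)
  cmd_featurize(cfg, quiet = TRUE)
  expect_identical(readLines(feats), before)
})

test_that("complex-aware evaluation modes run without leakage at cmd level", {
  run <- make_run_dir(protocol = list(mode = "leave_one_pdb_out",
                                      held_out = "FIX2", repeats = 1))
  cfg <- read_run_config(run$cfg_path)
  cmd_featurize(cfg, quiet = TRUE)
  loo <- cmd_evaluate(cfg, quiet = TRUE)
  expect_equal(loo$n_test, 30L)
  records <- read_mutation_table(file.path(cfg$output_dir, "records.csv"))
  pdbs <- record_pdb_ids(records)
  preds <- attr(loo, "predictions")
  expect_true(all(pdbs[preds$index] == "FIX2"))

  curve_cfg <- read_run_config(run$cfg_path,
                               overrides = list(protocol = list(mode = "learning_curve",
                                                                fraction_step = 0.2,
                                                                max_fraction = 0.4)))
  curve <- cmd_evaluate(curve_cfg, quiet = TRUE)
  expect_length(curve, 2L)
  expect_true(file.exists(file.path(cfg$output_dir, "learning_curve.json")))
})

test_that("prediction on unknown complexes is refused", {
  run <- make_run_dir()
  cfg <- read_run_config(run$cfg_path)
  cmd_featurize(cfg, quiet = TRUE)
  cmd_train(cfg, quiet = TRUE)
  unknown <- write_inhouse_csv(data.frame(pdb_id = "ZZZZ", chain = "A",
                                          mutation = "K1A", ddg = NA,
                                          stringsAsFactors = FALSE))
  expect_error(cmd_predict(cfg, file.path(cfg$output_dir, "model.rds"),
                           unknown, quiet = TRUE), "ZZZZ")
})

test_that("the CLI entry point featurizes via the installed package", {
  cli <- system.file("cli", "probass.R", package = "probass")
  expect_true(nzchar(cli))
  run <- make_run_dir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(cli, "featurize", "--config", run$cfg_path, "--quiet"),
            stdout = TRUE, stderr = TRUE, env = env))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  expect_true(file.exists(file.path(run$dir, "out", "features.csv")))
})
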