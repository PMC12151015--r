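#' Read and validate a run configuration
#'
#' The configuration is a YAML file with sections:
#' * `data`: `mutation_tables` (list of `path` + `dialect`),
#'   `structure_dir`, `partner_specs` (map pdb_id -> two chain groups)
#' * `providers`: `sequence_checkpoint`, `structure_checkpoint`,
#'   `cache_dir`, `mock` (logical), `mock_seed`
#' * `regressor`: any of the [default_hyperparameters()] names
#' * `protocol`: `mode`, `repeats`, `seeds`, `train_fraction`,
#'   `held_out`, `source_pdb`, `target_pdb`, `fraction_step`,
#'   `max_fraction`
#' * `output_dir`
#'
#' All randomness in a run flows from seeds named here. Referenced paths
#' are checked at validation time.
#'
#' @param path YAML file path.
#' @param overrides Named list merged over the file contents (CLI
#'   overrides).
#' @return A validated `run_config` list with a `digest` field.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  validate_run_config(cfg, base_dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg Configuration list (as from [yaml::read_yaml()]).
#' @param base_dir Directory against which relative paths resolve.
#' @export
validate_run_config <- function(cfg, base_dir = ".") {
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(base_dir, p)
  if (is.null(cfg$data)) stop("config is missing the 'data' section")
  for (i in seq_along(cfg$data$mutation_tables)) {
    tab <- cfg$data$mutation_tables[[i]]
    if (is.null(tab$path) || is.null(tab$dialect))
      stop("mutation_tables[", i, "] needs 'path' and 'dialect'")
    cfg$data$mutation_tables[[i]]$path <- resolve(tab$path)
    if (!file.exists(cfg$data$mutation_tables[[i]]$path))
      stop("mutation table not found: ", tab$path)
  }
  if (!is.null(cfg$data$structure_dir)) {
    cfg$data$structure_dir <- resolve(cfg$data$structure_dir)
    if (!dir.exists(cfg$data$structure_dir))
      stop("structure_dir not found: ", cfg$data$structure_dir)
  }
  mode <- cfg$protocol$mode
  if (!is.null(mode) &&
      !mode %in% c("random_within", "leave_one_pdb_out", "cross_pdb", "learning_curve"))
    stop("unknown protocol mode '", mode, "'")
  if (is.null(cfg$output_dir)) cfg$output_dir <- "probass_output"
  cfg$digest <- digest::digest(cfg[setdiff(names(cfg), "digest")])
  structure(cfg, class = "run_config")
}

.config_providers <- function(config) {
  if (isTRUE(config$providers$mock)) {
    seed <- config$providers$mock_seed %||% 1L
    list(seq = mock_sequence_provider(seed = seed),
         struct = mock_structure_provider(seed = seed))
  } else {
    list(seq = sequence_provider(config$providers$sequence_checkpoint %||%
                                   "esm2_t33_650M_UR50D"),
         struct = structure_provider(config$providers$structure_checkpoint %||%
                                       "esm_if1_gvp4_t16_142M_UR50"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config_dataset <- function(config, quiet = FALSE) {
  by_source <- list(inhouse = list(), skempi = list())
  for (tab in config$data$mutation_tables) {
    recs <- parse_mutation_table(tab$path, dialect = tab$dialect, quiet = quiet)
    src <- if (tab$dialect == "skempi_like") "skempi" else "inhouse"
    by_source[[src]] <- c(by_source[[src]], recs)
  }
  records <- resolve_duplicates(by_source$inhouse, by_source$skempi)
  pdbs <- unique(record_pdb_ids(records))
  structures <- list()
  for (pdb in pdbs) {
    path <- file.path(config$data$structure_dir, paste0(pdb, ".pdb"))
    if (!file.exists(path))
      stop("unresolved structure for complex ", pdb, ": ", path, " not found")
    spec <- config$data$partner_specs[[pdb]]
    if (is.null(spec))
      stop("no partner_spec declared for complex ", pdb)
    structures[[pdb]] <- load_complex(path, spec, pdb_id = pdb, quiet = quiet)
  }
  list(records = records, structures = structures)
}

.provenance <- function(config, providers, extra = list()) {
  c(list(config_digest = config$digest,
         sequence_checkpoint = providers$seq$checkpoint_id,
         structure_checkpoint = providers$struct$checkpoint_id,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra)
}

#' Pipeline commands
#'
#' Thin workflow wrappers tying the modules together; each writes its
#' outputs (with provenance: config digest, seeds, checkpoint ids) under
#' `config$output_dir`.
#'
#' * `cmd_featurize()` parses and merges the mutation tables, loads the
#'   structures, assembles the n x 1792 feature table and writes it with
#'   its sidecar metadata.
#' * `cmd_train()` trains the regressor on a featurized table and saves
#'   the model bundle.
#' * `cmd_evaluate()` runs the configured evaluation protocol and writes
#'   the report JSON + per-record prediction CSV.
#' * `cmd_predict()` scores a mutation table with a saved model.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param quiet Suppress progress messages.
#' @return `cmd_featurize()`: path of the feature table.
#'   `cmd_train()`: path of the model file. `cmd_evaluate()`: the
#'   `eval_report` (or list of per-point results for learning curves),
#'   invisibly, after writing files. `cmd_predict()`: data.frame of
#'   predictions, after writing `predictions.csv`.
#' @export
cmd_featurize <- function(config, quiet = FALSE) {
  providers <- .config_providers(config)
  ds <- .load_config_dataset(config, quiet = quiet)
  featurized <- featurize_dataset(ds$records, ds$structures,
                                  providers$seq, providers$struct,
                                  cache_dir = config$providers$cache_dir,
                                  quiet = quiet)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir, "features.csv")
  write_feature_table(featurized, path, providers$seq, providers$struct)
  write_mutation_table(featurized$records,
                       file.path(config$output_dir, "records.csv"))
  if (!quiet)
    message("featurized ", nrow(featurized$features), " records (",
            featurized$n_skipped, " skipped) -> ", path)
  invisible(path)
}

#' @rdname cmd_featurize
#' @export
cmd_train <- function(config, quiet = FALSE) {
  ft <- read_feature_table(file.path(config$output_dir, "features.csv"))
  hp <- utils::modifyList(default_hyperparameters(),
                          config$regressor %||% list())
  model <- train_ddg_model(ft$features, ft$targets, hp)
  path <- file.path(config$output_dir, "model.rds")
  save_ddg_model(model, path)
  prov <- .provenance(config, .config_providers(config),
                      list(hyperparameters = hp))
  jsonlite::write_json(prov, file.path(config$output_dir, "model.meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!quiet) message("model written to ", path)
  invisible(path)
}

#' @rdname cmd_featurize
#' @export
cmd_evaluate <- function(config, quiet = FALSE) {
  ft <- read_feature_table(file.path(config$output_dir, "features.csv"))
  records <- read_mutation_table(file.path(config$output_dir, "records.csv"))
  pdb_ids <- record_pdb_ids(records)
  hp <- utils::modifyList(default_hyperparameters(),
                          config$regressor %||% list())
  pr <- config$protocol %||% list()
  mode <- pr$mode %||% "random_within"
  seeds <- if (!is.null(pr$seeds)) as.integer(unlist(pr$seeds)) else NULL
  if (mode == "learning_curve") {
    curve <- learning_curve(ft$features, ft$targets,
                            fraction_step = pr$fraction_step %||% 0.05,
                            max_fraction = pr$max_fraction %||% 0.5,
                            seed = (seeds %||% 101L)[1L],
                            hyperparameters = hp)
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    body <- lapply(curve, function(pt)
      list(train_fraction = pt$train_fraction,
           pearson_r = pt$report$pearson_r, spearman_r = pt$report$spearman_r,
           rmse = pt$report$rmse, n_test = pt$report$n_test))
    jsonlite::write_json(list(mode = mode, points = body,
                              provenance = .provenance(config, .config_providers(config))),
                         file.path(config$output_dir, "learning_curve.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(curve))
  }
  report <- run_protocol(ft$features, ft$targets, mode = mode,
                         pdb_ids = pdb_ids,
                         repeats = pr$repeats %||% NULL, seeds = seeds,
                         train_fraction = pr$train_fraction %||% 0.8,
                         held_out = pr$held_out %||% NULL,
                         source_pdb = pr$source_pdb %||% NULL,
                         target_pdb = pr$target_pdb %||% NULL,
                         hyperparameters = hp)
  write_eval_report(report, config$output_dir, name = mode)
  if (!quiet) print(report)
  invisible(report)
}

#' @rdname cmd_featurize
#' @param model_path Path to a saved model bundle.
#' @param mutations_path Mutation table (in-house dialect) to score.
#' @export
cmd_predict <- function(config, model_path, mutations_path, quiet = FALSE) {
  model <- load_ddg_model(model_path)
  providers <- .config_providers(config)
  records <- parse_mutation_table(mutations_path, dialect = "inhouse_like",
                                  quiet = quiet)
  ds <- .load_config_dataset(config, quiet = TRUE)
  unknown <- setdiff(unique(record_pdb_ids(records)), names(ds$structures))
  if (length(unknown))
    stop("no structure for complex(es): ", paste(unknown, collapse = ", "))
  featurized <- featurize_dataset(records, ds$structures, providers$seq,
                                  providers$struct,
                                  cache_dir = config$providers$cache_dir,
                                  quiet = quiet)
  pred <- predict_ddg(model, featurized$features)
  out <- data.frame(pdb_id = record_pdb_ids(featurized$records),
                    mutations = vapply(featurized$records, function(r)
                      paste(vapply(r$mutations, format, ""), collapse = ","), ""),
                    ddg_pred = pred, stringsAsFactors = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(out)
}
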