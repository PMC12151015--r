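#' Default gradient-boosting hyperparameters
#'
#' Boosted regression trees with squared-error loss. Shallow trees
#' (depth 3) with a moderate learning rate suit the largely additive
#' structure of pooled embedding-difference features while keeping
#' single-threaded training fast; all values are overridable and are
#' recorded in the trained [ModelBundle][train_ddg_model]. Extra entries
#' beyond the named ones are passed through to the boosting backend
#' verbatim (e.g. `lambda`, `min_child_weight`, `subsample`).
#'
#' @param iterations Number of boosting rounds.
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage per round.
#' @param seed RNG seed for the learner.
#' @param nthread Threads used by the backend (1 = deterministic default).
#' @param max_bin Histogram bins per feature.
#' @param ... Extra backend parameters passed through.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(iterations = 500L, depth = 3L,
                                    learning_rate = 0.1, seed = 42L,
                                    nthread = 1L, max_bin = 64L, ...) {
  c(list(iterations = as.integer(iterations), depth = as.integer(depth),
         learning_rate = learning_rate, seed = as.integer(seed),
         nthread = as.integer(nthread), max_bin = as.integer(max_bin)),
    list(...))
}

MODEL_VERSION <- "probass-model-1"

#' Train the ddG regressor
#'
#' Fits gradient-boosted decision trees with squared-error loss mapping
#' 1792-entry feature vectors to experimental ddG_bind (kcal/mol).
#' Training is deterministic given (data, hyperparameters, seed) with a
#' single thread.
#'
#' @param features n x 1792 numeric matrix (canonical column order
#'   `seq_0..seq_1279`, `str_0..str_511`); n >= 10, no missing values.
#' @param targets Numeric vector of experimental ddG values, finite.
#' @param hyperparameters See [default_hyperparameters()].
#' @param seed Overrides `hyperparameters$seed` when given.
#' @return A `ModelBundle`: list with `learner` (opaque booster),
#'   `hyperparameters`, `feature_schema`, `training_digest`, `version`.
#' @export
train_ddg_model <- function(features, targets,
                            hyperparameters = default_hyperparameters(),
                            seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 10L)
    stop("need at least 10 training rows, got ", nrow(features))
  if (nrow(features) != length(targets))
    stop("features (", nrow(features), " rows) and targets (", length(targets),
         ") disagree")
  bad <- which(!is.finite(targets))
  if (length(bad))
    stop("non-finite target at row ", bad[1L])
  if (anyNA(features)) stop("features contain missing values")
  hp <- utils::modifyList(default_hyperparameters(), hyperparameters)
  if (!is.null(seed)) hp$seed <- as.integer(seed)

  extra <- hp[setdiff(names(hp), c("iterations", "depth", "learning_rate",
                                   "seed", "nthread", "max_bin"))]
  params <- c(list(objective = "reg:squarederror",
                   max_depth = hp$depth, eta = hp$learning_rate,
                   nthread = hp$nthread, seed = hp$seed,
                   tree_method = "hist", max_bin = hp$max_bin),
              extra)
  dtrain <- xgboost::xgb.DMatrix(features, label = targets)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$iterations, verbose = 0)
  structure(list(learner = xgboost::xgb.save.raw(booster),
                 hyperparameters = hp,
                 feature_schema = list(columns = colnames(features),
                                       width = ncol(features)),
                 training_digest = digest::digest(list(features, targets)),
                 version = MODEL_VERSION),
            class = "ddg_model")
}

#' @export
print.ddg_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat("<ddg_model>", hp$iterations, "rounds, depth", hp$depth, ", lr",
      hp$learning_rate, ", seed", hp$seed, "| width",
      x$feature_schema$width, "\n")
  invisible(x)
}

#' Predict ddG for feature rows
#'
#' @param model A `ddg_model` from [train_ddg_model()].
#' @param features m x 1792 matrix in the model's column schema.
#' @return Numeric vector of m predicted ddG values (kcal/mol), finite,
#'   order-preserving; rows are scored independently.
#' @export
predict_ddg <- function(model, features) {
  if (!inherits(model, "ddg_model")) stop("not a ddg_model")
  features <- as.matrix(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$feature_schema$width)
    stop("feature width ", ncol(features), " does not match model schema (",
         model$feature_schema$width, ")")
  if (!is.null(colnames(features)) && !is.null(model$feature_schema$columns) &&
      !identical(colnames(features), model$feature_schema$columns))
    stop("feature column names do not match the model schema")
  booster <- xgboost::xgb.load.raw(model$learner)
  as.numeric(predict(booster, xgboost::xgb.DMatrix(features)))
}

#' Save / load a trained model bundle
#'
#' The bundle file carries the serialized learner, hyperparameters,
#' feature schema, training digest and a version tag; loading a file
#' with a different version tag is refused. `load_ddg_model(save_ddg_model(m))`
#' predicts bitwise-identically to `m`.
#'
#' @param model A `ddg_model`.
#' @param path File path.
#' @return `save_ddg_model()`: `path` invisibly; `load_ddg_model()`: the
#'   model bundle.
#' @export
save_ddg_model <- function(model, path) {
  if (!inherits(model, "ddg_model")) stop("not a ddg_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ddg_model
#' @export
load_ddg_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file ", path, ": ", conditionMessage(e)))
  if (!is.list(model) || !identical(model$version, MODEL_VERSION))
    stop("model file ", path, " has version '",
         if (is.list(model)) model$version else "?",
         "', expected '", MODEL_VERSION, "'; refusing to load")
  structure(model, class = "ddg_model")
}
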