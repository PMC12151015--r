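# Shared fixtures, built once per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small loaded toy complex (12 + 10 residues).
small_structure <- function() cached("small_structure", function() {
  load_toy_complex(make_toy_complex(12, 10, seed = 3))
})

# A small featurized mutation set over the small complex.
small_featurized <- function() cached("small_featurized", function() {
  s <- small_structure()
  recs <- make_mutation_set(s, n_single = 40, n_double = 10, seed = 7)
  fz <- featurize_dataset(recs, stats::setNames(list(s), s$pdb_id),
                          mock_sequence_provider(1), mock_structure_provider(1),
                          quiet = TRUE)
  fz$truth <- make_synthetic_ddg(fz$features, informative_dims = 10,
                                 noise_sd = 0, seed = 5)
  fz$targets <- fz$truth$targets
  fz
})

# Three-complex dataset for the complex-aware protocols: distinct toy
# complexes with their own mutation sets, featurized jointly.
multi_complex_featurized <- function() cached("multi_complex", function() {
  structures <- list()
  records <- list()
  for (i in 1:3) {
    toy <- make_toy_complex(14, 12, seed = 20 + i, pdb_id = paste0("TOY", i))
    s <- load_toy_complex(toy)
    structures[[s$pdb_id]] <- s
    records <- c(records, make_mutation_set(s, n_single = 12 + i, seed = 30 + i))
  }
  fz <- featurize_dataset(records, structures, mock_sequence_provider(1),
                          mock_structure_provider(1), quiet = TRUE)
  truth <- make_synthetic_ddg(fz$features, informative_dims = 10,
                              noise_sd = 0.5, seed = 6)
  fz$targets <- truth$targets
  fz
})

# The recovery-scale fixture: 2000 single mutations on one complex, mock
# embeddings, 20 informative columns, noise SD = 0.25 x signal SD.
recovery_fixture <- function() cached("recovery", function() {
  toy <- make_toy_complex(60, 50, seed = 11)
  s <- load_toy_complex(toy)
  recs <- make_mutation_set(s, n_single = 2000, seed = 12)
  fz <- featurize_dataset(recs, stats::setNames(list(s), s$pdb_id),
                          mock_sequence_provider(2), mock_structure_provider(2),
                          quiet = TRUE)
  truth <- make_synthetic_ddg(fz$features, informative_dims = 20,
                              noise_ratio = 0.25, seed = 13)
  fz$truth <- truth
  fz$targets <- truth$targets
  fz
})

# Fast learner settings for tests that check protocol structure rather
# than predictive quality.
fast_hp <- function(...) default_hyperparameters(iterations = 20L, ...)

# Write an in-house dialect mutation CSV from a data.frame.
write_inhouse_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Direct-formula metric oracles, independent of the package's code path.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))
rmse_oracle <- function(pred, exp) sqrt(sum((exp - pred)^2) / length(pred))
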