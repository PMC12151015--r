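Package: probass
Title: Predicting Binding Free Energy Changes upon Mutation from Protein
    Language Model Embeddings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements ProBASS, a pipeline that predicts the change in
    protein-protein binding free energy upon mutation (ddG_bind, kcal/mol)
    by combining mean-pooled per-residue sequence-embedding differences
    (mutant minus wild type, 1280 dimensions) with mean-pooled wild-type
    inverse-folding structural embeddings (512 dimensions) and training a
    gradient-boosted decision-tree regressor on the 1792-dimensional
    concatenation. Includes mutation-table parsing for SKEMPI-like and
    in-house dialects, PDB complex loading and interface detection,
    deterministic mock embedding providers with on-disk caching, the full
    evaluation protocol suite (within-complex and whole-dataset 80/20
    splits, leave-one-complex-out, cross-complex transfer, learning
    curves, experimental-noise correlation ceilings, residual-outlier
    residue-class enrichment), and a synthetic-fixture generator with
    known ground truth for offline end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    digest,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
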