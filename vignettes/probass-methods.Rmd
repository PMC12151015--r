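---
title: "Predicting binding free energy changes from protein language model embeddings"
author: "probass package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding free energy changes from protein language model embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probass)
```

## The problem

A point substitution at a protein-protein interface changes the free
energy of binding; the change, ΔΔG~bind~ in kcal/mol (positive =
destabilizing in this package's convention), determines whether a mutant
complex still forms. Measuring ΔΔG~bind~ is slow; predicting it from
sequence and structure is a long-standing goal in protein engineering.
`probass` implements a supervised pipeline — the ProBASS approach — that
predicts ΔΔG~bind~ for one or two substitutions in a two-partner complex
by combining features from two kinds of pre-trained protein language
models (PLMs) and regressing measured ΔΔG~bind~ on them with
gradient-boosted decision trees.

## The model

For one mutation record in a complex with chain set $S$:

1. **Sequence block (1280 entries).** A transformer sequence PLM (the
   1280-wide, 650M-parameter class of model) produces per-residue
   embeddings for the wild-type chains and, in a second forward pass, for
   the mutant chains (both substitutions of a double mutant applied
   together). Each matrix is *mean-pooled* — the arithmetic mean over all
   residues of both partners, length-weighted, no per-chain reweighting —
   and the feature is the pooled difference
   $\bar e(\text{mut}) - \bar e(\text{wt})$.
2. **Structure block (512 entries).** An inverse-folding encoder maps the
   backbone (N, Cα, C) of the complex to 512-wide per-residue structural
   embeddings. Because these depend on backbone geometry only, wild type
   and mutant are nearly indistinguishable, so only the *wild-type*
   pooled structural embedding is used; it is constant across all
   mutations of one complex.
3. **Concatenation.** The feature vector is
   `[seq_delta | struct_wt]`, 1280 + 512 = 1792 entries, in that fixed
   block order (`seq_0..seq_1279`, `str_0..str_511`).
4. **Regression.** Gradient-boosted decision trees with squared-error
   loss map features to ΔΔG~bind~.

Mutant-minus-wild-type (rather than the reverse) is a convention; the
sign only flips learned weights. Pooling excludes any backend
special/boundary tokens — pooled values would otherwise shift with
sequence length for reasons unrelated to the proteins.

## Data handling

Mutation tables arrive in one of two declared dialects — a SKEMPI-like
one (mutation codes with embedded chain letters, `KI15A`,
semicolon-separated for doubles) and a simple in-house CSV (`K15A` on a
named chain column, comma-separated pairs). The dialect is never
sniffed; silent sniffing hides data errors. Rows that cannot be parsed,
use letters outside the 20-letter alphabet, repeat a site, or list a
wild type equal to the mutant are rejected row by row with logged
reasons, never repaired. When the same (complex, mutation set) is
measured in both sources, the in-house measurement wins; exact
duplicates within one source collapse to their arithmetic mean (the
cross-source precedence rule is prescribed; the within-source mean is
this package's choice, as no repair rule exists for it).

Structures are read from PDB coordinate records. Chain sequences come
from residues with a resolved Cα; modified residues with a standard
parent map to the parent's letter (MSE → M), unknown ones are skipped
with a warning, and residues without a Cα are excluded from both the
sequence and the structural input so the two embedding streams stay
index-aligned. Author numbering, including insertion codes, is carried
as opaque strings — no arithmetic is ever done on positions.

Interface positions are defined by a Cα-Cα distance to the opposite
partner of at most 4.0 Å, boundary inclusive. That is a deliberately
strict reading and it is exposed as a parameter (`cutoff`) so users can
relax it toward the more common 8-10 Å.

## Evaluation protocols

All protocols repeat the train/predict/score cycle over a published
seed list (101, 102, ... by default) so "repeated three/five times" is
reproducible; each repeat of the random 80/20 protocol resamples both
the split and the learner seed. Conventions:

* **Within-complex / whole-dataset**: uniform random 80/20 split; 3
  repeats for the single-complex setting, 5 for the whole dataset, by
  convention; mean ± SD of Pearson r reported.
* **Leave-one-complex-out**: every record of the held-out complex is the
  test set; disjointness of train and test complex ids is asserted on
  every call, never assumed.
* **Cross-complex**: train on all records of one complex, test on all
  records of another.
* **Learning curve**: the records are halved once (a training pool and a
  fixed test half), then the training set grows in 5% increments of the
  full dataset up to 50%, each subset extending the previous one.
  Nesting reduces point-to-point variance; the test half is identical at
  every point.
* **Noise ceiling**: each of `n_sim` simulations adds Gaussian noise
  (mean 0, per-measurement SD) to the measured values and records the
  correlation of the noisy replicate with the original. With
  homoscedastic noise the mean approaches the attenuation factor
  $\sigma_s / \sqrt{\sigma_s^2 + \sigma_n^2}$; at signal:noise = 2 that
  is $2/\sqrt 5 \approx 0.894$.
* **RMSE** is $\sqrt{\tfrac 1 n \sum_i (Y_i - \hat Y_i)^2}$ — the
  standard definition.

### Outlier enrichment

After an evaluation run, an ordinary least-squares line of predicted on
experimental ΔΔG is fitted and records beyond 1 residual SD (default)
are flagged: positive residuals are *over-destabilizing* predictions,
negative *over-stabilizing* (under positive-ΔΔG-=-destabilizing). For
each direction and each residue class — hydrophobic (F, I, L, Y, M, V),
polar (D, E, K, N, Q, R), structure-disrupting (P, G, N) — an exact
binomial tail p-value is computed against the class's frequency among
the substituted-in residues of all evaluated single mutations. The
dataset composition is the null: a uniform 1/20 null would mistake
dataset composition for model bias. Classification is by the
substituted-in (mutant) residue, and only single-mutation records enter
the class tests — a double mutant has no single residue class. P-values
are reported raw, matching how such enrichments are usually quoted; a
`holm` flag adds a Holm adjustment.

## The regressor

Gradient boosting is provided by xgboost with `reg:squarederror` —
squared-error loss, the standard reading of an "RMS" training loss.
Defaults: **500 rounds, depth 3, learning rate 0.1, 64 histogram bins,
one thread, seed 42**. Depth 3 rather than the deeper trees often used
elsewhere is a deliberate choice: the pooled-embedding-difference signal
is largely additive across feature coordinates, and shallow trees fit
additive structure with less variance and an order of magnitude less
compute; depth 3 still admits the low-order interactions double mutants
introduce. Every value is overridable per call and recorded in the
saved model bundle together with the feature schema and a training-data
digest. Training is deterministic for fixed data, hyperparameters and
seed on a single thread. There is no early stopping by default.

A closed-form sanity anchor used in the tests: with squared-error loss,
one round, no shrinkage, no L2 penalty and splits suppressed, the
booster predicts the training mean exactly.

## Embedding providers and the mock path

The two real PLM backends require multi-gigabyte Python checkpoints and
are not bundled; invoking them here raises an instructive error. All
offline work uses **mock providers** of the exact real widths (1280 /
512): row $i$ is a pure deterministic function of (residue letter,
chain, position, seed) with entries in $[-1,1]$. The mock is
*position-local* — a point mutation perturbs exactly one row — which
gives sharp unit tests for pooling and assembly. Real transformer
embeddings are **not** local, so no test may assume locality for a real
backend; locality is a property of the test double only. An on-disk
cache keyed by (provider, input digest) memoizes embedding calls;
corrupt entries are recomputed with a warning.

## The synthetic benchmark: what it does and does not show

The fixture generator builds two-chain toy complexes with idealized
geometry: straight Cα traces at 3.8 Å spacing, the partner chain offset
so the nearest cross-partner Cα pairs sit just inside 4 Å (interface
detection is non-empty by construction). Structural realism is
irrelevant to the contracts being tested, and a straight trace is
deterministic and cheap. Mutation sets are sampled uniformly without
replacement from all substitutions consistent with the sequences;
double-mutant site pairs stay within one chain, mirroring
inhibitor-side scans.

Ground-truth ΔΔG is a sparse linear function of the assembled features:
20 informative columns by default, drawn among columns with nonzero
variance (within a single complex the structural block is constant and
carries no signal), weights rescaled so the noise-free signal has SD 3
kcal/mol — giving the realistic ±12 kcal/mol range — plus Gaussian
noise. The default noise is 0.25 × signal SD, a noise ceiling of
$1/\sqrt{1.0625} \approx 0.970$, comparable to the ~0.95 ceilings
estimated from replicate binding measurements.

What passing the offline suite shows: the plumbing is correct (feature
geometry, alignment, split hygiene, determinism, metric arithmetic) and
the regressor recovers a known sparse-linear signal through the entire
pipeline at the stated noise. What it does not show: performance on
real complexes. Real embeddings are non-local and correlated, real
ΔΔG is not linear in them, and real datasets are imbalanced across
complexes. Headline correlations on real data (≈0.8 for single
mutations) require the curated experimental dataset and the real
checkpoints, and are integration-scale runs outside this test suite.

### Problem sizes used offline

Unit tests run on 12-22-residue complexes with tens of mutations. The
recovery benchmark uses one 110-residue complex, 2000 single mutations,
20 informative columns, noise 0.25 × signal SD, repeat seeds
101-103 — sizes chosen so the whole suite stays a desk-scale run while
the estimates (correlations of ~0.94 against a 0.970 ceiling) remain
stable to a few hundredths across seeds.

## Numerical choices and degenerate inputs

* Correlations on fewer than 3 points or zero-variance input are
  errors, not NA: every such case in this pipeline is a bug upstream.
* The interface cutoff comparison is `d² ≤ cutoff² + 1e-9` — inclusive
  at the boundary, tolerant of representation error in coordinates.
* `round((1-f)·n)` fixes test-set size in random splits (100 → 80/20,
  10 → 8/2).
* Empty designs, all-failed featurization, unknown complexes, schema
  (width or column-name) mismatches at prediction: all fatal with
  specific messages; row-level problems in parsing/featurization are
  per-row skips with logged reasons and counts.
* All split, fixture and mock randomness goes through seed-scoped RNG
  that restores the caller's RNG state.

## Known limitations

* Real-backend embedding extraction is out of process; the package
  defines the contract (widths, residue alignment, cache format) but
  ships only the mock implementation.
* Multi-chain binding partners are supported in the data model
  (`partner_spec` names chain groups explicitly) but the curated-data
  convention for grouping SKEMPI chains must be supplied by the user;
  nothing is inferred.
* ΔΔG conventions differ across sources; the package assumes
  positive-=-destabilizing throughout and does not auto-detect sign.
* The duplicate rule collapses *exact* (complex, mutation-set) keys
  only; no homology-aware deduplication across complexes.
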