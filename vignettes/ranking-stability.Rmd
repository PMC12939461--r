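---
title: "Auditing the stability of feature-importance rankings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the stability of feature-importance rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankstab)
```

## The audit

`rankstab` asks one question of any feature-importance method: if the
single most important feature is removed from the data and the method is
re-applied, does the rest of its ranking survive? For a method whose scores
carry interpretive weight — a biomarker short-list, a risk-factor ranking —
the answer should be yes, in the strongest possible sense: every surviving
feature moves up exactly one position and nothing else changes (a *uniform
rank shift*). The package operationalizes that as the strict consistency
criterion and wraps it in an end-to-end benchmark: scorers, perturbation,
downstream predictive evaluation, and a synthetic data generator that makes
every guarantee testable.

The target data regime is a samples × features table with a binary outcome:
mixed molecular modalities (expression, copy number, mutation indicators,
phosphoprotein), features outnumbering samples severalfold, and a rare
positive class (defaults emulate 705 samples × 1936 features with 13.3%
positives).

## The strict criterion, formally

Let `r_full` be the top-k ranking on the full table and `r_pert` the top-k
ranking after removing the top-m features of `r_full` and re-scoring with
the identical configuration. The verdict is **Consistent** iff

```
r_full[(m+1)..k] == r_pert[1..(k-m)]   (element-wise, order included)
```

and **Inconsistent** otherwise, with diagnostics (first divergent position,
symmetric set difference of the two windows, order-preservation flag).
Set-overlap indices such as Jaccard are computed on the same windows purely
as a contrast: the windows `[B, C, D]` vs `[C, B, D]` have Jaccard 1.0 and
are still Inconsistent, which is exactly the blindness of subset-stability
indices the strict criterion is designed to remove.

Two conventions here were genuinely open and are package decisions:

* **Joint removal.** At depth m > 1 the top-m features of the *original*
  ranking are removed together, not iteratively re-ranked one at a time;
  the removed set is then a subset of the initial ranking, which is the
  natural reading of "removing larger subsets of top-ranked features". An
  iterative mode exists behind `iterative = TRUE` for exploration (the two
  coincide for univariate scorers).
* **Full-length perturbed ranking.** The perturbed ranking is computed to
  length k and the comparison reads its first k − m entries. This
  reproduces the two-column report layout (original ranking next to the
  perturbed one, with a bar in the removed positions) and makes the
  perturbed table directly publishable; it is a convention, not a
  substantive choice, since only the first k − m entries are ever compared.

### Why univariate scorers cannot fail

For the variance and Spearman scorers, the score of feature f is a function
of column f (and, for Spearman, the outcome) alone. Removing other columns
leaves every surviving score bit-identical, and the tie-break key — the
feature's *original* column index, frozen at preprocessing and retained
through `drop_features()` — is also unchanged. The sort order of the
survivors is therefore literally the same sort on the same keys, so the
verdict is Consistent for every table, every k, every m < k, including
degenerate all-tied tables. This is a theorem about the design, not an
empirical tendency; the test suite still property-checks it on hundreds of
random tables with injected ties, because the theorem only holds if the
implementation actually keeps scores local and indices frozen.

Multivariate scorers (joint linear fits, tree ensembles, PCA) re-distribute
scores when the feature set changes — collinear and interacting features
are the classic trigger — and routinely come out Inconsistent. The
benchmark's point is to measure, not to fix, that behavior.

## Scorers: definitions and numerical choices

All scorers consume the post-preprocessing table: missing numerics imputed
with zero, categoricals one-hot encoded (missing entries become all-zero
indicator rows — the composition of the two rules), outcome coded 0/1, no
scaling or normalization. Linear scorers regress the raw 0/1 outcome as a
numeric target; their coefficients are the importance magnitudes, so a
classification likelihood is not needed and the regression reading keeps
the score definition exactly "absolute fitted coefficient".

* **OLS** (`ols_abs_coef`). With p > n the least-squares problem is
  rank-deficient, so the minimum-norm solution is used, computed from the
  SVD of the column-centered design with singular values below
  `max(n, p) * eps * d_max` treated as zero. The convention is recorded in
  the result metadata. Centering makes constant columns score exactly 0.
* **LASSO** (`lasso_abs_coef`). Coordinate descent via `glmnet` with
  `standardize = FALSE` and an intercept, so the penalty parameter is on
  the `(1/2n)·RSS + α·||β||₁` scale; the default α = 0.01 is a mild
  penalty intended to rank rather than aggressively sparsify. The
  convergence threshold is tightened to 1e-10 and the iteration budget
  raised to 1e5; a non-convergence warning is recorded in the result
  metadata rather than raised as an error. The single-feature case uses
  the closed-form soft-threshold update.
* **Random forest** (`forest_impurity`). 100 trees, Gini impurity
  importance normalized to sum to one, class weights `n/(2·n_class)` by
  default (the importance model sees the imbalance; the downstream
  evaluator deliberately does not — both switches are exposed). The
  backend reserves seed 0 for unseeded operation, so user seeds are
  offset by one internally; fits and predictions are pure functions of
  (data, config, seed) and run single-threaded for reproducibility.
* **Boosted trees** (`gbt_gain`). Binary logistic objective at the
  implementation's default hyperparameters, 100 rounds; importance is the
  normalized total-gain share (the implementation default, recorded in
  metadata), and unused features score exactly 0. Without subsampling the
  greedy split search is deterministic, and the test suite asserts
  identical rankings across seeds; the scorer is still flagged stochastic
  and records its seed, since determinism here is an empirical property of
  the configuration rather than of the algorithm class.
* **PCA** (`pca_loading_sum`). Columns are mean-centered, never
  variance-scaled; `n_components = "all"` means `min(n − 1, p)`, the rank
  bound of a centered matrix. Components with numerically zero variance
  (sdev below `1e-9` of the leading one) are discarded — otherwise a
  constant column could pick up arbitrary loadings on null components
  instead of its correct score of 0. Scores are sums of absolute loadings,
  hence invariant to component sign flips.
* **Variance** (`variance`). Sample variance with the n − 1 denominator.
  Rankings are invariant to that constant factor, so the choice is purely
  conventional; the tests assert the ranking-invariance, not the
  convention.
* **Spearman** (`spearman_abs`). Pearson correlation of average-rank
  transforms (ties get average ranks), absolute value; constant features
  score 0 by convention. Invariant to strictly increasing transforms.

Ties anywhere are broken by ascending original column index — a stable,
deterministic rule shared by every ranking operation, so repeated runs and
different scorers order tied features identically.

## Downstream evaluation

`evaluate_selector()` measures the predictive information content of a
scorer's top-k selection with a fixed evaluator so that differences are
attributable to selection, not classifier choice. Per repetition seed s:
a stratified fold assignment (per-fold positive counts within one of each
other; a pure function of outcome, fold count and seed), and per fold, the
scorer re-fitted on training rows only, its top-k features selected, a
100-tree random forest at library defaults trained on those features, and
the held-out fold predicted by majority vote at the default threshold.
Defaults are 10 folds × 10 seeds (100 cells).

Conventions the data regime forces:

* **Zero-division.** With ~13% positives, a fold can contain or predict no
  positives; sensitivity and F1 are defined as 0 there and a warning is
  emitted. Accuracy is unaffected.
* **Aggregation.** Means and SDs are taken over all seed × fold cells (the
  flat convention, stamped into `aggregation_tag`); per-seed-first nesting
  is computable from the returned `per_cell` table. The reported SD
  therefore mixes fold-to-fold and seed-to-seed variability.
* **One seed per repetition.** Seed s drives both the fold split and the
  evaluator's randomness; scorer hyperparameters (including the scorer's
  own seed) stay fixed across folds so the selection step is deterministic
  given the training rows.
* **No reweighting in the evaluator.** The evaluator runs without class
  weights or threshold tuning, isolating the intrinsic information content
  of the selected features; the switch exists for sensitivity analyses.

Leakage safety is auditable: `fold_selections()` exposes exactly the
selection step the harness uses, and the tests replace held-out rows with
noise and assert bit-identical selected sets.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure the benchmark
cares about, not any particular cohort's biology:

* exact minority count — `round(prevalence · n)` positives, not a binomial
  draw, so prevalence arithmetic is reproduced exactly;
* planted signal — class-conditional Gaussian shifts of `signal_effect`
  within-class SDs, which give analytically controlled rank association
  (logistic-inverse sampling would not give exact class counts);
* planted high-variance, outcome-independent features (variance ×
  `variance_boost`) that bait variance-based selection;
* exactly duplicated column pairs and equicorrelated blocks (common latent
  factor, blocks of five covering ~10% of continuous noise features) —
  the classic destabilizers of multivariate importances;
* modality prefixes (`rs_`, `cn_`, `mu_`, `pp_`) affecting names and
  marginals only (`mu_` features are sparse binary; planted structure is
  assigned to continuous-modality columns), not the dependence structure;
* missingness inserted *before* preprocessing so the zero-imputation path
  is exercised end to end.

Generation is bit-identical given the seed: the RNG is pinned to
Mersenne-Twister with inversion normals and rejection sampling, and the
ambient RNG state is saved and restored around every draw.

What the generator does **not** emulate: real multi-omics covariance
(pathway structure, copy-number segmentation, batch effects), censoring or
time-to-event information, and any association between modality and effect
size. Consequently, a scorer's Consistent verdict on synthetic tables
transfers to real data only insofar as it is structural (the univariate
theorem transfers; empirical stability of multivariate scorers does not),
and evaluation metrics on synthetic data say nothing about clinical
performance. Calibration is itself tested: with `signal_effect = 0`,
planted "signal" scores are statistically indistinguishable from noise
scores (rank-sum check at the 1% level over 50 replicates).

## Problem sizes and runtime

The shipped tests and the acceptance script scale the study design down so
the whole surface runs quickly on one CPU: the invariance sweep uses tables
up to 300 × 500 at depths 1/5/10; the end-to-end benchmark uses 300 × 200
with all seven scorers, 5 folds × 2 seeds; the leakage audit uses 200 × 50
over 10 seeds. These sizes were chosen so each claim is exercised at a
scale where failures are observable (p > k everywhere, rank-deficient OLS
included via a 30 × 300 fixture) while the full suite stays in the
low-minute range. Full-scale runs (705 × 1936, 10 × 10 evaluation) use the
same code paths and the package defaults; on a laptop they take on the
order of an hour, dominated by the tree-ensemble fits inside
cross-validation.

## Known limitations

* Only binary outcomes; no multi-class or time-to-event support.
* The evaluator family is fixed (random forest) by design; comparing
  evaluators is out of scope.
* No SVM coefficients, permutation importance, SHAP or gradient-based
  attributions — the audit targets model-native importance scores.
* The strict criterion is deliberately all-or-nothing: it reports *whether*
  the explanatory hierarchy survived, with diagnostics, but no graded
  stability score. Jaccard and positional agreement are reported only as
  contrast, and a Consistent verdict implies both equal 1.0 — the converse
  fails by construction.
* Linear-model importances are raw coefficient magnitudes on unscaled
  features, faithful to the audited definition but scale-dependent across
  features; that is a property of the audited methods, not of the audit.
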