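---
title: "Sign-handling pipelines for connectivity-based classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-handling pipelines for connectivity-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsign)
```

## The question

Global signal regression (GSR) removes the brain-wide mean signal from each
regional time series. Arithmetically, if every region's series has the
cross-region mean subtracted at each time point, the rows of the resulting
covariance matrix sum to zero — so whenever any region pair covaries
positively, some other pair *must* covary negatively. Anti-correlations
after GSR are therefore not an artifact to be cleaned away but a structural
feature of the data, and a binary brain graph built by keeping only "the
strongest" correlations implicitly decides what to do with them. `netsign`
operationalizes the three natural choices — positive-only (`pos`),
negative-only with sign flip (`neg`), absolute value (`abs`) — and measures
their downstream effect on case/control classification under
leave-one-site-out (LOSO) cross-validation.

## The synthetic cohort: what it emulates, and what it does not

Real multi-site resting-state cohorts cannot ship with a package, so the
unit of analysis here is a generative model with the statistical structure
the pipeline is sensitive to:

* **Modular dependence.** Regions are assigned round-robin to `n_modules`
  modules (deterministic, so unequal sizes are reproducible). The
  population correlation is `within_module_corr` inside a module and a
  group-dependent `between_module_corr_*` across modules, with unit
  variances. Positive semi-definiteness is verified by an eigenvalue check
  (minimum eigenvalue ≥ −1e−10); tiny violations within 1e−6 are repaired
  by eigenvalue clipping, anything worse is rejected with the offending
  parameters named — silently repairing a grossly invalid request would
  hide user error.
* **A planted group difference.** ASD and HC differ only in the
  between-module correlation. The package defaults are 0.1 (HC) vs 0.3
  (ASD) — a moderate, detectable network-topology difference; the
  calibration experiments below use 0.0 vs 0.4, a strong effect chosen so
  that classifier failure is attributable to the pipeline, not the signal.
* **GSR.** The default implementation subtracts the cross-region mean at
  each time point — the simplest operation consistent with "removing the
  global mean"; regressing each series on the global-mean series is
  available via `gsr_method = "regress"`. Mean subtraction makes the
  null-sum property above hold *exactly*, which the tests assert at 1e−8.
* **Site structure.** `default_site_templates()` encodes a 17-site cohort
  (1035 subjects) with per-site ASD/HC counts, age means/SDs and female
  fractions collapsed from per-sex demographic summaries; `noise_scale`
  and `n_timepoints` (default 150 time points, a typical resting-state run
  length) are the only scanner/protocol knobs. Ages are drawn from per-site
  normals clipped at 6 years.

What the generator does **not** emulate: image-space artifacts, head
motion, physiological nuisance structure, hemodynamic autocorrelation
(time points are i.i.d. draws), atlas geometry, or site effects beyond
amplitude and demographics. Passing calibration tests on this cohort shows
the pipeline machinery is sound and leak-free; it does not certify
accuracy levels on real data, where effect sizes are far smaller and site
confounds far richer.

## Graph construction

Pearson correlation of all region pairs (diagonal set to 1) feeds the sign
transform, then proportional thresholding keeps the top
`k = round(p · N(N−1)/2)` weights as edges over a grid p = 0.20–0.50 in
0.02 steps. Numerical choices, each fixed for reproducibility:

* the denominator is **all** node pairs, not just sign-retained ones, so a
  threshold means the same graph density in every pipeline — without this,
  "pipeline differences" would partly be density differences;
* `round` is half-away-from-zero (base R's banker's rounding is
  platform-consistent but surprises people);
* ties at the cut break by lexicographic (i, j) order, which also makes
  graphs nested across thresholds;
* exact-zero correlations are treated as absent in all three modes — zero
  carries no connection strength;
* if sign filtering leaves fewer than k weights (common for `neg` on
  weakly anti-correlated data), all retained pairs become edges and a
  warning is recorded rather than failing the subject.

A consequence worth knowing: `neg` applied to C is *identical* to `pos`
applied to −C at every threshold (sign duality), which the tests exploit
as an invariant.

## The feature vector

Per graph: 7 node-level measures × N nodes — degree, clustering
coefficient, local efficiency, betweenness centrality (unnormalized
Brandes, endpoints excluded), eigenvector centrality, participation
coefficient, within-module degree z-score — then 4 global measures:
characteristic path length, global efficiency, transitivity, degree
assortativity. Length 7N + 4 = 1404 at N = 200. This composition is a
reconstruction: the four stated measure families (integration,
segregation, centrality, resilience) plus degree and local efficiency are
the unique assignment consistent with a printed count of 1404 for a
200-region atlas, and the assembly order is fixed and documented in
`assemble_graph_features()`.

Degenerate cases resolve to sentinels so feature matrices stay
rectangular and finite: proportional thresholds as low as 20% can
disconnect graphs, so characteristic path length averages finite
distances only and efficiency counts unreachable pairs as 0;
assortativity of a regular graph is 0 (with a warning); the within-module
z-score is 0 when a module's degree SD is 0; eigenvector centrality is
computed on the largest connected component (unit Euclidean norm, ties on
lowest node index) and 0 elsewhere; clustering is 0 below degree 2.
Within-module SD is the population SD (divide by n), fixed and
documented.

Community structure for the participation coefficient and z-score comes
from Louvain modularity maximization. The algorithm is stochastic, so each
(subject, threshold) cell gets a fixed derived seed, making feature
extraction bit-reproducible; isolated nodes form singleton modules.

PCA features (when enabled) are principal components of the mean-centered
strict upper triangles of the *signed* correlation matrices, fit **inside
each training fold only** and applied to the fold's test subjects. Fitting
PCA on all subjects would leak test-site information into the features;
per-fold fitting is the leak-free choice and the package treats it as
non-negotiable default. The requested component count (default 600) is
truncated to the feasible rank with a warning.

## The classifier

A two-hidden-layer perceptron: input → 512 ReLU (L1-penalized weights) →
dropout 0.7 → 512 ReLU (L2-penalized weights) → dropout 0.7 → sigmoid
unit; binary cross-entropy loss; Adam. Features are standardized with
training-fold means and population SDs (zero-variance features map to 0
with a warning); labels are HC = 1, ASD = 0, so *sensitivity is HC
recall* and specificity is ASD recall — the reverse of the usual clinical
phrasing, kept deliberately. The 0.5 probability cut defines the
confusion metrics; AUC is the Mann–Whitney statistic with ties counted
half.

Parameters, with defaults and rationale:

| parameter | default | note |
|---|---|---|
| `hidden_units` | 512 | per hidden layer |
| `dropout_rate` | 0.7 | after each hidden layer |
| `learning_rate` | 2e−4 | initial Adam step |
| `adam_beta1`, `adam_beta2` | 0.99, 0.01 | see below |
| `l1_strength`, `l2_strength` | 1e−3, 1e−2 | not dictated by the design; tune per study |
| `validation_fraction` | 0.10 | stratified by class |
| `lr_decay_factor` | 0.5 | on validation-loss plateau |
| `patience`, `max_decays` | 5, 3 | plateau = no improvement ≥ 1e−4 |
| `max_epochs`, `batch_size` | 200, 32 | desk-scale convergence |

The validation split is drawn from training subjects *stratified by
class*: an unstratified 10% split at small per-site n routinely produces
single-class validation sets, which make the plateau detector blind.
Training is bitwise reproducible given `(seed, config, data)` — the seed
drives initialization, the split, minibatch order and dropout masks.

**On the Adam betas.** The defaults β₁ = 0.99, β₂ = 0.01 are implemented
exactly as configured even though β₂ = 0.01 is far from the conventional
0.999: with β₂ that small, the second-moment estimate is essentially the
current squared gradient, and the update degenerates toward
sign-of-gradient steps with heavy momentum. At the small sample sizes and
network widths used in this package's calibration experiments that
optimizer reliably saturates the output unit and stalls at chance (we
verified the gradients against numerical differentiation; the instability
is in the optimizer dynamics, not the code). `conventional_betas = TRUE`
restores (0.9, 0.999), and every desk-scale experiment in the tests and
the acceptance script uses it, with a narrower net (32 hidden units),
dropout 0.2 and learning rate 0.01 — sized for cohorts of ~10²
subjects and ~10² features rather than 10³ subjects × 1404 features.

## Evaluation and statistics

`run_experiment()` crosses sites × pipelines × thresholds × repetitions;
repetition r trains with seed `base_seed + r`. Standardization and PCA are
fit per fold; the tests include a leakage audit asserting that perturbing
a test-site subject's features leaves the fold's trained weights
bit-identical.

Aggregation mirrors the two-stage averaging of the study design: per
(site, pipeline, threshold) the repetition mean is taken first, then the
mean and SD across thresholds; overall rows are the unweighted mean of
site means and the test-set-size-weighted mean. (Averaging repetitions and
thresholds jointly gives the same mean but a different SD; the two-stage
order is the default and the one reported.) Folds with undefined AUC
(single-class test sites) are excluded from AUC aggregates with their
count reported.

Three comparison families, each Holm–Šidák corrected *per metric within
its family* — the family boundary is a design choice (sites × pairs for
the per-site Welch family, sites × thresholds × pairs for the
threshold-matched family, pairs for the paired-t family) and is kept
separate per metric so that, e.g., accuracy and AUC tests do not dilute
each other:

* per-site Welch tests on trial-level threshold-averaged repetition
  metrics (the "5 trials" unit);
* threshold-matched Welch tests (repetitions as units) — the heatmap
  analogue, `plot_threshold_heatmap()`;
* paired t-tests across sites on site-mean metrics.

Constant-sample degeneracies get sentinels rather than errors: equal
constant samples give p = 1; different constant samples give p = 0 with a
warning (the t statistic diverges). The Holm–Šidák step-down is
`1 − (1 − p₍ᵢ₎)^(m−i+1)` with a running maximum; it is validated against
the closed-form two-value example {0.01, 0.04} → {0.0199, 0.04} and a
simulated-null family-wise-error check.

`auc_age_regression()` fits site-mean AUC on a polynomial in site mean
age (default quadratic — the inverted-U hypothesis; degree 3 available).
It requires at least degree + 2 sites and at least degree + 1 distinct
ages, and reports R² and the overall F-test p-value via `glance()`.

## Problem sizes used in the shipped experiments

The calibration experiments are sized to run comfortably on one CPU: the
planted-effect cohort is 4 sites × 40 subjects, 20 regions, 300 time
points, between-module difference 0.4, pipeline `neg` at threshold 0.30
(mean LOSO accuracy ≥ 0.7 expected); the null calibration permutes
diagnosis labels 20 times over the same cohort (mean accuracy expected in
[0.4, 0.6]); the metric-oracle sweep uses 200 random graphs of ≤ 10 nodes
against exhaustive brute-force implementations at 1e−10; the
family-wise-error simulation uses 500 null replicates. The acceptance
script re-runs the planted-effect experiment over all three pipelines and
a coarse threshold grid (0.2–0.5 by 0.1) with 2 repetitions.

## Known limitations

* The generator's i.i.d.-in-time draws understate the effective
  autocorrelation of real BOLD series, so empirical correlation estimates
  are less noisy than at a matched real-data T.
* Louvain partitions differ across seeds on graphs with weak community
  structure; participation and z-score features inherit that variance
  (controlled here by fixed derived seeds, not eliminated).
* The `neg` pipeline at low thresholds can run out of negative entries on
  weakly anti-correlated (non-GSR) data; the warning-and-keep-all policy
  means such graphs are sparser than the nominal density.
* The printed-beta Adam configuration is faithful but fragile at desk
  scale; conclusions about pipeline ordering drawn from the small-scale
  experiments use the conventional-beta optimizer.
* No site-harmonization (e.g. ComBat) or mixed-effects modelling: site
  enters only through the LOSO design and the weighting of the summary
  rows.
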