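---
title: "MSN gradients: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSN gradients: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model behind `msngrad`, the
parameters that matter, the synthetic-data generator's assumptions, and the
numerical decisions that were genuinely open. It states no empirical claim
that the package's test suite and acceptance script do not themselves
compute.

## 1. From morphometry to an individual network

Each subject is a `regions × 5` table of cortical morphometry: thickness
(mm), volume (mm³), area (mm²), gaussian curvature (1/mm²), mean curvature
(1/mm). `zscore_features()` standardizes each feature across regions with
the *sample* SD (ddof = 1) — the convention is pinned because correlations
downstream are scale-free but tests of exact values are not. The MSN entry
is the Pearson correlation of two regions' standardized 5-vectors.

Two conventions are fixed here that the broader literature leaves implicit:

* **Diagonal = 0, not 1.** Self-similarity carries no information, is
  excluded from regional strength, and must never survive sparsification —
  a diagonal of 1 would always be a row's top entry.
* **Pearson over five points is noisy** and left unshrunk: the network
  definition *is* the five-feature profile correlation; regularizing it
  would change the estimand.

A region with a constant profile has undefined correlations; entries are
zeroed with a warning. The synthetic generator cannot produce this case
(continuous noise), so the handling is defensive only.

## 2. Gradient decomposition

Per subject: (1) keep the top `⌊0.10·n⌋` entries per MSN row by *signed*
value, diagonal excluded — signed selection matches the standard gradient
workflow, and negative survivors are rare at 10% density; (2) cosine
similarity between the full-length sparsified rows, mapped through the
normalized angle `1 − arccos(c)/π` into [0, 1] (cosines clamped to [−1, 1]
first to absorb floating-point overshoot); (3) diffusion map embedding.

The embedding uses the α-normalized kernel
`W_α = D^{−α} W D^{−α}` with α = 0.5 (the Fokker–Planck variant that
corrects for sampling density), the row-stochastic operator
`P = D_α^{−1} W_α`, and its eigendecomposition computed through the
symmetric conjugate `D_α^{1/2} P D_α^{−1/2}` for numerical stability. The
trivial constant eigenvector is dropped; components are ordered by
descending eigenvalue magnitude; at diffusion time t = 0 the i-th component
is scaled by `λ_i / (1 − λ_i)`. α = 0.5, t = 0, and k = 10 components are
the defaults of the dominant gradient toolbox and are exposed as arguments.

**Explained-variance fractions.** There is no universal normalization for
diffusion-map "variance explained". We define the fraction for component i
as `max(λ_i, 0) / Σ_j max(λ_j, 0)` over the full nontrivial spectrum
(computed densely), which guarantees non-negative, non-increasing fractions
summing to ≤ 1 over any leading subset. Fractions computed this way are
comparable across subjects because every subject's affinity has the same
size and unit diagonal.

**Alignment.** Eigenvector sign (and, with close eigenvalues, rotation) is
arbitrary. All subjects are aligned to a template embedded from the
element-wise average MSN of the whole cohort — both groups, so the template
is contrast-neutral — by the orthogonal Procrustes transform (rotation or
reflection, no scaling: scaling would distort the range and variance
metrics compared between groups). The template's own sign is fixed by
requiring the region with the largest |score| on gradient 1 to be positive.
Alignment never touches the explained-variance fractions.

Global gradient metrics are the component-1 fraction, the range
(max − min), and the variance (ddof = 1) of the aligned gradient-1 scores.

## 3. Group statistics

Site effects are removed by parametric empirical-Bayes ComBat (via the
`sva` package) on the subject × region gradient matrix, with group, age,
sex, and education protected; a single-site cohort passes through
untouched. Regional contrasts are OLS GLMs (intercept + group + covariates)
fitted in one decomposition for all regions; the reported t is the group
coefficient in the AD − NC direction with a two-sided t-distribution p and
BH-FDR q. FDR families are kept separate (regions; classes; networks) —
pooling them would couple unrelated resolution levels.

**KS distribution tests.** Whether the compared samples should be pooled
regional values or per-subject summaries is genuinely open. The default
pools each group's per-subject regional gradient values within a label
(`global` = all regions): this gives well-powered ECDFs, at the cost that
pooled values are stratified by region, making the asymptotic p
conservative under the null. The per-subject-mean alternative is available
via `pool = FALSE`. The test-suite calibration check therefore uses iid
across-subject samples at a single region, where the asymptotic p is valid.

## 4. Graph topology

The dense signed MSN must become a graph; no standard exists. Decision:
keep the top 10% of *positive* off-diagonal edges by weight (proportional
threshold mirroring the gradient sparsification; density exposed),
symmetric by construction of the upper triangle. Metrics follow the Brain
Connectivity Toolbox conventions for weighted graphs: Onnela clustering
(geometric mean of max-normalized triangle weights; reduces exactly to the
binary coefficient on 0/1 weights) and characteristic path length on
inverse-weight edge lengths. A disconnected graph yields a warning and the
largest-component path length. Binarized analysis is available by passing a
0/1-weighted graph.

## 5. Cognition

Class-level partial correlations residualize both the class-mean gradient
and the score on (intercept, age, sex, education) and correlate the
residuals; p uses `df = n − n_cov − 2`.

Prediction uses nested 5-fold cross-validated support vector regression.
The kernel is linear by default — interpretable and appropriate when
features (regions) outnumber subjects — with a radial option. The inner CV
(5-fold) tunes `C ∈ 10^{−2..2}` and `ε ∈ {0.01, 0.1, 1}`; a single-row grid
skips tuning. Feature standardization is fit on each outer training set
only and applied to its held-out fold, so no information leaks; the test
suite verifies this by corrupting held-out targets and checking the
held-out predictions are unchanged. Significance permutes the target and
re-runs the *entire* nested pipeline, with
`p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`. Prediction features are
region-level gradient-1 scores (not class means), matching the comparison
against region-level MSN strength; covariates are not used inside the
predictive model.

## 6. Transcription–neuroimaging association

With gene expression `X` (z-scored per gene across regions) and the
unthresholded regional t-map `y` (centered), the first PLS component has
weight direction `w ∝ X'y` — an identity for univariate responses shared by
NIPALS and SIMPLS, which the test suite exploits as an independent oracle.
Region scores are `Xw`; explained variance is the R² of `y` on the scores;
orientation is fixed so `cor(scores, y) ≥ 0`.

Significance: region labels of `y` are shuffled (10 000 permutations at
full scale). This plain shuffle does not preserve spatial autocorrelation —
a known limitation; `perm_test_pls()` accepts user-supplied null maps as a
hook. Gene ranking: 10 000 bootstrap resamples of regions, each replicate
weight vector sign-aligned to the original by the sign of `w'w_boot`
(otherwise component reflection inflates the SE), and `z = w / SD_boot(w)`.
Gene p-values use the standard normal reference for z — the z-score
construction implies an approximate normal reference, and a percentile
alternative can be built from the returned replicates. Gene sets are
`z > 0` and `z < 0` at BH-FDR q < 0.001, ranked by |z|.

## 7. The synthetic-data generator

What it emulates: per-region feature means following smooth low-frequency
profiles along an arbitrary 1-D region ordering (so neighbouring regions
have similar 5-feature profiles, MSNs acquire block structure, and a
meaningful principal axis exists); unit-SD Gaussian noise, so `effect_map`
entries are standardized effect sizes added to every feature of AD
subjects; additive per-site feature offsets (ComBat's location model) with
optional multiplicative noise scaling to exercise the scale component; age
and education Gaussian (clipped to plausible ranges), sex 0/1; Von Economo
classes in contiguous blocks of the ordering and Yeo networks in shorter
interleaved blocks (shuffleable). Cognition scores are linear combinations
of per-subject class-mean gradients plus Gaussian noise, with the
generating weights returned for recovery tests. Expression plants a gene
subset at a chosen expected correlation with a supplied region map by
Cholesky-style mixing with independent noise.

What it does not emulate: real morphometric feature covariance (unknown and
unpublished for any cohort of this kind — the smooth-profile choice is a
modelling convenience, not a claim about real data), cortical geometry,
spatial autocorrelation of expression maps, missing data, and scanner
artefacts beyond additive/multiplicative site effects. Passing tests
therefore demonstrate correctness of the *machinery* — estimators,
alignment, calibration, recovery under the generator's assumptions — not
performance on real cohorts.

A consequence worth stating: planting additive effects on *features*
perturbs the MSN and its gradients nonlinearly, so the gradient-level t-map
is not expected to correlate linearly with `effect_map`; the planted-effect
recovery guarantees hold at the feature level, where the effects are
defined.

## 8. Default study conditions and problem sizes

The demo configuration is a two-site cohort of 120 subjects (60 AD / 60 NC)
× 400 regions, regional effects ~ N(0, 0.5²), site offset 0.3 SD, cognition
coupled to standardized class means (weights −1, −0.5, +1, +0.5 on primary
sensory, secondary sensory, association 1 and 2 classes; noise SD 1 — class
means are standardized before coupling so signal and noise are on the same
scale), expression with 50 planted genes at r = 0.9 among 2000. Permutation
and bootstrap counts default to 10 000; the test suite runs reduced counts
(100–1000) and reduced replicate numbers chosen so the whole suite stays
interactive while Monte-Carlo error remains far below the margins being
asserted. Calibration checks (FDR under the global null, permutation-p
uniformity) use 80–120 replicates.

## 9. Known limitations

* No spatial-autocorrelation-preserving nulls anywhere (neither for the
  group contrasts nor for PLS permutations); hooks exist for user-supplied
  null maps.
* The pooled KS default is conservative under the null (Section 3).
* Diffusion embedding computes the full dense spectrum; fine up to a few
  thousand regions, not designed for voxel-level graphs.
* Enrichment of the selected gene sets is out of scope: the ranked
  `genes_plus` / `genes_minus` tables are the terminal output, formatted
  for external enrichment portals.
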