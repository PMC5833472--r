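---
title: "Methods: QC-driven preprocessing and biomarker screening for untargeted LC-MS fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC-driven preprocessing and biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboscreen)
```

## The problem this package addresses

Untargeted LC-MS metabolomics produces an aligned *feature table*: one
abundance per (sample, feature), where a feature is a (neutral mass,
retention time) signal standing in for a metabolite ion. Before any
biology can be read off such a table, three sources of technical
structure must be dealt with:

* **irreproducible features** — signals that appear erratically or with
  high variance across repeat injections of the same pooled material;
* **within-batch drift** — slow change of instrument response over the
  injection sequence of an analytical batch;
* **below-detection missingness** — abundances under the limit of
  detection (LOD) exported as blanks or zeros.

The experimental design this package assumes is the standard pooled-QC
design: a *quality control* (QC) sample, pooled from study plasma, is
injected at the start of every batch, after every 8 study samples, and
at the end of the batch. Repeat QC injections measure the same material,
so their spread per feature estimates pure technical variability, and
their trend over injection order traces drift.

Downstream, the package implements the complete case-control screening
stack used for clinical fingerprints: PLS-DA/OPLS-DA projections with
cross-validated quality statistics, assumption-gated univariate testing
with false-discovery-rate control, per-feature ROC validation, and a
multivariable SVM classification check, exercised end-to-end on a
synthetic generator with known ground truth.

## Data model

A `feature_table` holds the samples × features intensity matrix plus
per-sample metadata (group label, batch, injection index, QC flag,
polarity) and per-feature metadata (neutral mass, retention time,
polarity, optional annotation). Key conventions:

* Missing values are an explicit `NA` mask, never zero — zeros would
  corrupt both the QC coefficient of variation and the log transform.
  Zeros found in raw input are treated as below-detection and converted
  to `NA` with a message, since aligned vendor exports encode absence
  either way.
* A table holds exactly one polarity. Positive- and negative-mode
  acquisitions are separate runs with separate feature spaces and are
  analysed as fully independent tables; nothing couples the two modes.
* "Present" means a non-missing intensity > 0 — the only criterion
  observable after alignment.
* The injection index is batch-local; cross-batch order is the
  lexicographic (batch, injection index) order.
* Nested clinical subgroups (a subset of one group, e.g. cases that
  delivered within a week of diagnosis) are carried in an optional
  `subgroup` metadata column; every comparison label resolves first
  against `group`, then against `subgroup`.

## Preprocessing chain

`run_preprocess()` applies, in order:

1. **QC-presence filter** (default ≥ 50% of QC injections). A feature
   present in *exactly* half of the QCs survives: the removal rule is
   "present in less than the threshold".
2. **QC-CV filter** (default CV ≤ 30%): sd/mean over the feature's
   present QC intensities, on the raw scale with the sample (n − 1)
   standard deviation. Features with fewer than two present QC values
   have no CV and are removed with their own reason code.
3. **Group-presence filter** (default ≥ 90% in *any* study group):
   keeps features well observed in at least one group, so a metabolite
   absent in controls but consistent in cases is retained.
4. **Bracketing-QC drift correction.** For feature *f* in one batch,
   the expected QC level at injection *i* is the linear interpolation,
   on injection index, between the nearest preceding and following QC
   injections with a present value of *f*; positions outside the first
   or last such QC use that QC's value (constant extrapolation). The
   corrected value is
   `raw × ref_f / expected`, with `ref_f` the study-wide median of
   *f*'s present QC intensities, so all batches are rescaled to one
   common reference level — the point of the correction is cross-batch
   comparability, which a batch-local reference would not give.
   Piecewise-linear interpolation is the minimal model that honours
   both bracketing anchors; smoothing alternatives (LOESS, splines) are
   deliberately out of scope. If a batch holds fewer than two present
   QC values of *f*, that batch's values are left uncorrected and
   logged. Evaluated at a QC's own injection, expected = observed, so
   every QC value collapses to `ref_f` exactly — a useful invariant for
   testing.
5. **log10 transform**, bringing per-feature distributions close to
   normal for the downstream Gaussian machinery. Missing stays missing.

Filtering precedes correction, so the CVs recorded in the
`filter_report` are pre-correction values; the filters therefore judge
features on their *uncorrected* reproducibility, which is the
conservative choice. Filters only ever remove features — never samples,
never individual values.

## Multivariate models

`fit_plsda()` is a NIPALS PLS2 regression of the one-indicator-column-
per-class response on the feature matrix. Both X and Y are mean-centered
and unit-variance scaled (autoscaling): for fingerprints whose features
span orders of magnitude even after log10, autoscaling is the
conventional default and the one assumed by the usual chemometrics
workflows. Components carry a deterministic sign convention (the
largest-magnitude weight element is positive) so that refits and the
OPLS-DA equivalence below are exactly reproducible.

`fit_oplsda()` (two classes only) removes orthogonal-signal-correction
components — systematic variation uncorrelated with class — before
fitting a single predictive PLS component. With zero orthogonal
components its scores equal one-component PLS-DA scores to machine
precision; with orthogonal components the predictive scores are exactly
orthogonal to the removed ones.

Defaults: 2 predictive components for PLS-DA (the usual score-plot
plane), 1 predictive + 1 orthogonal for OPLS-DA.

`cross_validate()` uses a **stratified** random partition into 7 folds
(proportional class representation; plain random partitioning risks a
fold losing a small class outright). Every sample is held out exactly
once. Q² is computed per cumulative component count as 1 − PRESS/TSS on
the globally centered/scaled indicator matrix, with PRESS pooled over
folds — the pooled convention is used because per-fold TSS normalisation
is unstable for small folds. The classification table and CC%
(percent correctly classified) come from the argmax of predicted
indicator columns, ties resolved toward the earlier class level. When
the smallest class has fewer members than folds, the fold count shrinks
to that size with a warning.

`permutation_validate()` refits and cross-validates under random label
permutations and reports add-one p-values,
`p = (1 + #{permuted ≥ observed}) / (1 + n_permutations)`, for both R²Y
and Q²; p can never undercut `1/(n_permutations + 1)`. The default of
200 permutations balances resolution (minimum p ≈ 0.005) against
runtime.

QC injections take no part in model fitting; `project_samples()` applies
the stored centering/scaling to project them onto a fitted PLS-DA, the
standard visual check that pooled QCs cluster tightly and sit where
their pooling composition predicts.

## Univariate screening

For each feature and each two-group comparison, `compare_groups()`
excludes missing values within the feature, then chooses the test by
the classical assumption gates:

* Shapiro-Wilk normality within each group, and
* Levene's test of variance homogeneity with the **mean** as center
  (the classical form; the median-centered variant is the
  Brown-Forsythe modification).

If any gate p-value falls below α = 0.05 — or a gate cannot be
evaluated (a group below Shapiro's minimum of 3 values, or constant
values) — the two-sided Wilcoxon rank-sum test is used; otherwise a
one-way ANOVA, which for two groups is exactly the squared pooled-
variance t test. The Wilcoxon uses exact enumeration up to 25 values
per group and the normal approximation with continuity correction
above. The gate level equals the global α: one declared significance
level governs every decision. A feature with identical values
everywhere gets p = 1 and a zero-variance flag; a feature with fewer
than two present values in a group is untestable and leaves the FDR
family.

Benjamini-Hochberg adjustment (`adjust_fdr()`) is applied per
comparison and per polarity — each polarity is a separate acquisition
with its own feature space, so pooling families across modes would mix
unrelated tests and change each mode's reported significant counts.

Percent change is `100 × (mean_A − mean_B)/mean_B` computed on
**back-transformed corrected-scale arithmetic means** (`10^x` per
value), not on log means: fold-type changes of metabolite abundance are
conventionally reported on the measurement scale, and the arithmetic
mean of raw abundances is what a targeted assay would estimate.

## ROC validation and classification

For each FDR-significant feature, `roc_features()` reports:

* the Mann-Whitney **AUC** (pair counting with half-weight ties),
  auto-oriented to ≥ 0.5 with the direction recorded — reporting
  conventions fix AUC ≥ 0.5 and the orientation tells which group runs
  high;
* the **Youden-optimal threshold**: candidates are midpoints between
  adjacent distinct pooled scores plus ±∞; J = sensitivity +
  specificity − 1 is maximized, ties resolved toward higher
  sensitivity, then the lower threshold — a deterministic rule that
  favours catching cases when operating points are equivalent;
* **DeLong inference**: the structural-components variance of the AUC,
  a Wald 95% CI truncated to [0, 1], and a one-sided p-value against
  AUC = 0.5 (the direction of interest is "better than random"). With
  zero variance (perfect separation) the p-value is reported as a
  floor value with a `degenerate` flag rather than 0.

`impute_median_by_group()` fills each missing value with the median of
the feature's present values within the sample's own clinical group;
features with an entirely missing group are dropped from the
classification matrix and logged. `svm_loocv_accuracy()` then evaluates
a radial-basis SVM (cost 1, kernel width 1/n_features on standardized
features — the e1071 defaults) by leave-one-out cross-validation.
Features are standardized inside each training fold, so scaling leaks
nothing from the held-out sample. Imputation, however, is by default
performed once on the full matrix before LOOCV, mirroring the common
workflow; the held-out sample's intensities then contribute to medians
filling other samples. This leakage is mild (medians are robust) but
real, so a strict mode (`strict_impute = TRUE`) recomputes the group
medians inside every training fold; it is off by default to match the
conventional order of operations.

When a comparison yields zero significant features, or when its two
sample sets overlap (a nested subgroup versus its parent group —
two-class machinery is undefined on overlapping membership), ROC and
SVM are skipped with an explicit flag instead of erroring.

## The synthetic generator

`simulate_study()` emulates the study design the pipeline targets:
three clinical groups of 57/49/25 subjects with a nested subgroup of 37
inside the first (131 study samples), dealt into 4 batches by
stratified near-quarters, QC injections per the bracketing schedule,
and per-injection intensities

```
raw = 10^(baseline + log10(2)·log2_offset(group) + batch_offset + noise) × drift(position)
```

with below-LOD censoring to `NA`. Generator defaults, chosen once as
representative of a well-behaved plasma fingerprint run:

| parameter | default | rationale |
|---|---|---|
| features | 500 | enough for FDR behaviour; desk-scale runtime |
| baseline log10 | U(4, 7) | typical 10^4–10^7 count range |
| noise sd (log10) | 0.08 | ≈ 19% CV, well under the 30% QC gate |
| batch offset sd (log10) | 0.05 | ≈ 12% between-batch level shifts |
| drift | linear ×1.0 → ×0.8 | 20% within-batch decay, curvature configurable |
| LOD (log10) | 3.8 | censors the low tail of the weakest features |
| differential features | 30 at \|log2\| = 0.6 | ≈ 1.5-fold effects, detectable but not trivial |

Effects are multiplicative on the raw scale (additive on log10), which
is how fold changes of metabolite abundance behave. The pooled-QC
profile is the mean raw profile of batch 1's study samples, so QC
projections sit toward the centroid of the majority groups rather than
the global center — reproducing the behaviour of QCs pooled from an
unbalanced first batch. The generator can also plant features that each
violate exactly one cleaning filter (QC absence, QC instability as an
alternating ×2/×0.5 QC pattern, or patchy group presence), giving the
filter cascade an exact expected outcome.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: correlated feature blocks
(adducts, isotopes, pathway co-regulation; features here are
independent), retention-time or mass drift, heavy-tailed or skewed
biological variation beyond log-normality, missingness mechanisms other
than LOD censoring (e.g. alignment dropouts), and realistic effect-size
spectra. In particular, planted independent effects of 1.5-fold at
these noise levels are easy for an SVM, so synthetic classification
accuracies saturate near 100% — far above what overlapping clinical
metabolomes yield; the SVM checks here validate mechanics (determinism,
no leakage, chance-level behaviour under permutation), not clinical
attainability.

## Numerical choices and degenerate inputs

* Drift correction evaluates interpolation with `approx(rule = 2)`
  (constant extrapolation beyond the outer QCs); a missing QC anchor
  falls back to the nearest present QC on the same side.
* NIPALS iterates to a relative score change of 1e-12 (cap 500
  iterations); component signs are fixed by convention as above.
* Zero-variance features abort PLS fitting with the feature named;
  imputation drops features it cannot fill and records them.
* CV fold partitions, permutation draws and every other random step run
  under a locally seeded RNG that restores the caller's random state.
* Problem sizes in the test suite are chosen for desk-scale runs:
  oracle equivalences use 300–1000 random instances; calibration
  properties use 10–20 seeded replicates of 40–500-feature tables;
  the end-to-end design check runs the full 131-sample default scenario
  once.

## Known limitations

* Only two-group comparisons are implemented (the screening design is
  pairwise); no omnibus multi-group tests or covariate adjustment.
* OPLS-DA is two-class only, with a single predictive component.
* The bracketing correction assumes drift is smooth between QCs;
  abrupt mid-batch jumps are attenuated, not removed.
* Percent change requires positive reference means, i.e. a corrected
  raw-scale table upstream.
* No VIP-based variable selection; feature selection is purely by
  FDR-adjusted univariate significance.
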