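---
title: "From untargeted feature tables to a quantified diagnostic metabolite panel"
author: "metabopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From untargeted feature tables to a quantified diagnostic metabolite panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopanel)
```

## The problem

Untargeted plasma LC-MS metabolomics yields a table of aligned feature
intensities per injection. Turning such a table into a clinically usable
diagnostic requires a chain of steps, each with its own failure modes:
below-detection values must be imputed, instrument signal drift across the
injection sequence must be removed, a classifier must be trained without
information leaking across cross-validation folds, a *small* panel of
metabolites must be distilled from hundreds of features so that a targeted
assay is economical, the panel must be absolutely quantified against
stable-isotope-labeled internal standards (SIL-IS), and the resulting
concentrations must support both diagnosis (case vs control) and secondary
questions such as predicting the response to neoadjuvant chemotherapy (NAC)
from metabolite ratios.

`metabopanel` implements this chain as composable, individually tested
steps, together with synthetic-data generators that reproduce the
statistical structure of each stage so that every property of the pipeline
can be verified without access to instrument data. The `analysis/` scripts
in the source repository run the three phases in sequence on simulated
cohorts; `scripts/acceptance.R` recomputes the headline quantities from
scratch.

## Signal-drift correction

Pooled QC samples — aliquot mixtures of the study samples — are injected
before and after the sequence and after every 10 subject injections. For
each feature $j$ the QC intensities trace the instrument response over
injection order $t$. We fit a trend $\hat f_j(t)$ to the QC points and
correct every sample by

$$\tilde x_{ij} = x_{ij} \cdot \frac{\mathrm{ref}_j}{\hat f_j(t_i)},$$

where $\mathrm{ref}_j$ is the median QC intensity of the feature. Because
the correction is a per-injection scalar per feature, it can never reorder
values measured at the same injection, and dividing each batch by its own
trend while rescaling to the pooled reference level also harmonizes batch
offsets.

Two trend fitters are provided and are interchangeable via
`pipeline_config(trend_method = ...)`:

* `loess_like` — a local-linear smoother (`stats::loess`, degree 1) when at
  least 6 QC points are available, plain linear interpolation otherwise.
  It reproduces constant and exactly linear QC profiles without error.
* `ensemble_regression` — the average of 50 interpolants fitted to bootstrap
  resamples of the QC points, in the spirit of ensemble-of-trees QC
  correction. Each member retains the first and last QC so that no member
  extrapolates; the ensemble is seeded and therefore deterministic.

Predictions outside the QC order range are clamped to the nearest QC
prediction — extrapolating a fitted trend past the sequence ends can
produce sign flips or blow-ups, and clamping is the conservative choice.

A correction that *increases* a feature's QC relative standard deviation
(RSD) would mean the trend fit chased noise; such features are reverted to
their raw values and flagged in the QC report (`corrected = "no"`). As a
consequence the contract "QC RSD after ≤ QC RSD before" holds exactly for
every corrected feature, not merely on average.

Imputation precedes correction: every missing entry is replaced by 1/10 of
the feature's minimum observed intensity across all samples, the standard
below-detection substitution applied when feature tables are exported from
alignment software. Features with no observed value cannot be imputed and
are dropped with a warning.

## The classifier: a soft-margin linear SVM

Each sample's feature vector is first L2-normalized,
$f_i \leftarrow f_i / \sqrt{\sum_m f_m^2}$. The normalization uses only the
sample's own values, so applying it before the fold split cannot leak
information across samples. The classifier is the linear soft-margin SVM

$$\min_{w, b}\; \tfrac12\lVert w\rVert^2 + c \sum_i \max\bigl(0,\, 1 - y_i(w^\top x_i + b)\bigr),$$

with an unregularized bias — the standard soft-margin extension of the
maximum-margin hyperplane. The cost is fixed at $c = 4$ in the discovery
phase and $c = 5$ in the targeted validation phase. The solver is a
sequential-minimal-optimization routine on the dual (maximal-violating-pair
working sets, implemented in C++), which accepts a precomputed Gram matrix
so the tens of thousands of fits of a repeated-CV run can share one
`tcrossprod()` per feature subset. Its objective is verified in the test
suite against an independent interior-point QP solve to $10^{-6}$ relative
tolerance; the optimizer itself is deterministic, and randomness enters the
workflow only through data shuffling.

Labels are fixed as case $= +1$, control $= -1$; a decision value of
exactly zero predicts $+1$.

## Panel selection

`repeated_cv()` draws, per iteration, a fresh fold assignment *stratified
by class* (the cohorts are imbalanced, and unstratified folds could empty a
class), trains one SVM per fold on the remaining folds, and pools the
held-out predictions so each sample is predicted exactly once per
iteration. Feature importance is the squared weight $w_m^2$ — insensitive
to sign flips across refits — averaged over all `n_iter × folds` fold
models (mean-of-squares rather than square-of-means; with balanced folds
the two differ only in weighting, and mean-of-squares is the more robust
estimator). The full protocol uses 2000 iterations of 4-fold CV for
importance and 500 iterations for each top-N model up to $N = 100$.

`topn_accuracy_curve()` evaluates the top-$N$ column subsets of the
*once-normalized* matrix. Re-normalizing each subset would make the
single-feature model degenerate (a positive 1-vector always normalizes to
1), so subsets inherit the full-panel normalization, which is also why the
curve at $N$ = all features reproduces the full-table CV exactly.

`select_panel()` returns the smallest $N$ whose mean accuracy is within
`tolerance` of the curve maximum. The default tolerance of 0.01 (one
accuracy point) encodes "improved performance with a relatively small
number of features"; `tolerance = 0` degenerates to the first maximum. The
chemical-feasibility filter applied in practice (availability of standards,
matched MS/MS, peak shape) is a human decision, represented as an
`availability_mask` input rather than computed.

With two ionization modes, each mode is processed and ranked independently,
the top candidates per mode are pooled, and the top-N curve is computed on
the concatenated per-mode-normalized matrix — mode-qualified feature ids
(`pos:F0123`) keep the provenance visible.

Summary metrics are reported as the CI of the mean across iterations,
$\bar m \pm 1.96\, s/\sqrt{n_\text{iter}}$; at 2000 iterations these CIs
are very narrow, which is a statement about Monte-Carlo error of the mean,
not about the spread of single-iteration accuracies (a percentile summary
of `cv$metrics` is available to readers who want the latter).

## SIL-IS calibration and absolute quantification

The calibrated quantity is the response ratio $r$ = analyte peak area /
internal-standard peak area, which cancels matrix effects and detector
gain. Calibration fits $r = \beta_1 x + \beta_0$ by weighted least squares
with weights $1/x^2$ — the bioanalytical standard, equalizing *relative*
errors across a calibration range that spans three orders of magnitude
(weighting exponent 0 recovers OLS; the test suite verifies the fit against
explicit normal equations for exponents 0, 1, 2). Acceptance follows the
back-calculation rule: a level passes if its back-calculated concentration
is within ±15% of nominal (±20% at the lowest level, the LLOQ tolerance),
and the curve is accepted iff at least 75% of levels pass — the boundary is
enforced as ≥, so 10/13 passing levels accept and 9/13 reject.

The LLOQ is the lowest calibrator level meeting the ±20% bias rule (and a
≤20% replicate CV when replicates are available). The supplement holding
the study's own limits is not available, so the LLOD uses the conventional
$3.3\,\sigma/\text{slope}$ with $\sigma$ estimated from the residuals of
the lowest calibrator levels — a documented, replaceable constant.
Concentrations below the LLOQ are *flagged, not censored*, when fed to the
classifier: censoring would silently change the feature distribution the
model sees. Back-calculation is the exact algebraic inverse of the fitted
line, so negative concentrations can occur for blank-like samples and carry
a below-zero flag. A reconstitution dilution multiplier is available
(`dilution_factor`, default 1 = uncorrected). Calibration is fitted per
analytical run: each cohort file carries its own calibrators, and a
rejected curve for a panel analyte aborts the validation phase with a
`curve_rejected` condition carrying the full curve report.

## Evaluation and the NAC ratio marker

Diagnostic metrics take case as the positive class (sensitivity =
TP/(TP+FN), specificity = TN/(TN+FP)). The ROC is a threshold sweep with
tied scores grouped, and its trapezoidal AUC equals the Mann-Whitney
statistic $U/(n_+ n_-)$ with ties counted 1/2 — an exact identity the test
suite checks on a thousand random instances. Group differences use Welch's
t by default ("t-test" with no variance assumption; Student's t via
`var_equal = TRUE`), and families of tests are adjusted by
Benjamini-Hochberg.

The NAC analysis tests each panel metabolite within each tumor subtype
(pCR vs non-pCR) on the log scale, BH-adjusts across the whole
marker-by-subtype family, and evaluates the inosine/uridine ratio per
subtype: the ratio is formed on the concentration scale (scale-free), the
test is run on the log ratio (symmetric), and the AUC is identical on
either scale because the log is monotone. AUCs are oriented so that lower
marker levels in responders score above 0.5, matching the planted biology
(responders have reduced plasma nucleosides).

## What the generators emulate — and what they do not

`generate_untargeted_cohort()` produces lognormal intensities
(multiplicative noise and fold-changes compose additively on the log
scale), a shared drift multiplier raised to a per-feature sensitivity
exponent in $[0.5, 1.5]$ (drift is correlated but not identical across
features), pooled QCs built as the per-feature mean of subject true signals
and then subjected to the same drift and noise, contiguous batches with
lognormal offsets, and below-detection censoring at a per-feature quantile.
The default design is 200 cases / 100 controls with 479 features, QCs
bracketing the sequence and after every 10 subject injections, 10 planted
features at log2 fold-change 1.5 against 70% multiplicative noise
(a standardized log-scale effect of ≈1.6 before drift and censoring
attrition), drift amplitude 0.3 and 5% censoring.

Deliberate simplifications, and what they mean for interpreting green
tests:

* **Features are independent given the drift factor.** Real feature tables
  contain adducts, isotopologues and correlated pathways; planted-feature
  recovery here does not certify behavior under heavy collinearity.
* **All features share one abundance scale by default**
  (`feature_log_sd = 0`). This matches the single-scale cohort model and
  isolates the selection machinery from a separate, real phenomenon:
  squared-weight importance after row L2 normalization is
  *scale-confounded*, because a feature's weight scales inversely with its
  numeric magnitude. Setting `feature_log_sd > 0` reproduces the problem —
  low-abundance informative features become invisible to a fixed-cost SVM —
  and is left available precisely so users can study it. The same
  limitation appears in the validation phase: on raw (untransformed)
  concentrations, ng/mL-scale nucleosides contribute little to the decision
  values next to the 10^4 ng/mL amino acids. Raw concentrations are
  nevertheless the default (log transformation is available via
  `log_concentrations`) because the printed pipeline applies L2
  normalization directly to the exported quantities.
* **Drift is smooth and shared.** Abrupt instrument events (source
  cleaning, column swaps) are represented only as batch boundaries.
* **The NAC generator uses exchangeable marker noise** — a common log-scale
  SD (0.4) and a subject-level shared variance component equal to the
  marker-specific one (between-marker correlation 0.5, representing common
  physiological variation such as hydration and global metabolic state).
  Under this model a planted standardized effect $d$ on one marker yields
  the binormal AUC $\Phi(d/\sqrt2)$ both for the marker and for its ratio
  to an unaffected marker, and ratios genuinely benefit from cancelling the
  shared component — the mechanism by which a ratio can outperform its
  numerator. With unequal marker SDs or a different correlation the ratio
  AUC deviates from this closed form.
* **Targeted effect sizes are calibrated to the high-accuracy regime**
  reported for absolute-quantification diagnostic panels (case/control
  shifts of 1.6–1.8 SD on the log scale, giving a synthetic training
  accuracy near 0.91 and AUC near 0.96). With materially weaker shifts the
  classifier becomes sensitivity-skewed and its accuracy varies with cohort
  prevalence, which is a property of accuracy as a metric, not of the
  implementation.

## Numerical choices and degenerate inputs

* SMO stopping tolerance $10^{-8}$ on the KKT violation, iteration cap
  $10^6$; the bias is the mean over free support vectors, or the midpoint
  of the KKT interval if none is free.
* Importance ties are broken by ascending feature index (stable, total
  order); prediction ties (decision value exactly 0) go to the positive
  class.
* `fit_qc_trend()` requires ≥3 QC points for the ensemble and ≥2 for the
  interpolating smoother; with fewer, the error instructs the caller to
  fall back to a global-median factor, and the orchestrator then leaves the
  feature uncorrected and flagged.
* Weighted calibration requires ≥6 distinct positive levels ($1/x^2$ is
  undefined at zero concentration).
* An all-zero sample vector cannot be L2-normalized and is an error, as is
  a training set with a single class.
* Report provenance contains a config hash, the seed and the package
  version — and deliberately no timestamp, so identical configuration and
  seed give byte-identical reports.

## Problem sizes used in the checked examples

The test suite and the acceptance script run the protocol at desk scale,
chosen so the full suite completes in a few minutes on one core: 200-
iteration importance CV and 100-iteration top-N to $N = 30$ on a
500-feature cohort of 300 subjects (20 seeds for the recovery property),
50-iteration CV on six 300-subject null cohorts for the null calibration,
200 replicate targeted runs for quantification recovery, and 200–1000
replicate NAC cohorts for the closed-form AUC comparisons. The full
2000/500-iteration protocol is the package default
(`default_config()`) and runs unchanged, only longer.

Two statistical conventions in those checks deserve a note. First, the
null-calibration check compares the mean held-out accuracy to 50% using the
SE *across independent null cohorts*: a single cohort's CV accuracy
concentrates around its data-conditional mean, which deviates from 50% by
$O(n^{-1/2})$, so an iteration-level SE would understate the relevant
variation. Equal group sizes are used because with a 2:1 cohort the null
SVM converges to the majority-class rate, not 50%. Second, under the global
null the probability that BH at $q = 0.05$ yields zero rejections is
exactly $1 - q$ for independent features, so "no significant marker" is
expected in 95% of null cohorts, not all of them.
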