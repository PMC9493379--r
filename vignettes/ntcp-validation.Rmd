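---
title: "Validating and updating logistic NTCP models with ntcpval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating logistic NTCP models with ntcpval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcpval)
```

## The problem

Normal tissue complication probability (NTCP) models translate a
radiotherapy treatment plan into a predicted probability of a toxicity.
In the model-based selection of head-and-neck cancer patients for proton
therapy, a logistic NTCP model for grade II–IV dysphagia at six months is
evaluated on the best photon and the best proton plan of the same
patient, and the difference in predicted risk (ΔNTCP) decides who is
referred for protons. A model used this way must be *externally valid*:
its predictions must discriminate events from non-events and, more
stringently, be numerically calibrated on cohorts it was not developed
on. When calibration has drifted — different scoring practice, different
case mix, different treatment protocols — the model should be updated,
but by the smallest amount the data actually support, because every
re-estimated parameter costs transferability.

`ntcpval` implements this validation-and-updating loop: applying a
published logistic model, the four-level updating hierarchy with a
closed-testing selection rule, a discrimination and calibration metric
battery, and a synthetic cohort generator that makes all of it testable
end to end.

## The updating hierarchy and the closed testing procedure

Write $S_i$ for the original model's linear predictor of patient $i$.
The hierarchy of updates is nested by construction:

| level | free parameters | form |
|---|---|---|
| original | 0 | $\mathrm{logit}(p) = S$ |
| re-calibration in the large | 1 | $\mathrm{logit}(p) = \alpha + S$ |
| logistic recalibration | 2 | $\mathrm{logit}(p) = \alpha + \beta_{cal} S$ |
| model revision | $k+1$ | $\mathrm{logit}(p) = \gamma_0 + \gamma^\top x$ |

Each refit is Bernoulli maximum likelihood via iteratively reweighted
least squares (`stats::glm`, relative convergence tolerance $10^{-8}$,
at most 100 iterations); non-convergence and (quasi-)separation are
reported explicitly, never silently.

The closed testing procedure runs likelihood-ratio tests of each simpler
level *against the revision* — the one model flexible enough to hold
under every alternative — and selects the simplest level whose test is
non-significant: original vs revision on $k+1$ degrees of freedom, then
intercept update vs revision on $k$, then recalibration vs revision on
$k-1$. Anchoring every test at the revision is what makes the sequence a
closed procedure with family-wise error control: when the original model
is in fact correct, the probability of selecting *any* update is at most
the significance level (0.05 by default). We considered the alternative
reading in which each calibrated model is tested directly against the
original; that ordering does not control the family-wise error of the
selection, so the revision-anchored tree is the implementation and all
three tests are always reported (with a `used` flag) so any other
ordering can be audited from the same object. The component fits
(`fit_intercept_update()`, `fit_logistic_recalibration()`,
`fit_revision()`) and `lr_test()` are exported, so a different decision
tree can be composed directly if a user wants one. LR statistics are
floored at zero when optimizer noise makes them marginally negative
(beyond $10^{-6}$ a warning is raised).

## Performance metrics

* **AUC** is computed from midranks — exactly the Mann–Whitney
  concordance over all event/non-event pairs with ties counted one half.
  The 95% interval uses the DeLong variance by default; a seeded
  stratified bootstrap is available.
* **Sensitivity/specificity** need a classification threshold the
  validation literature rarely states; the default is 0.5, a
  Youden-optimal threshold is available, and the threshold used is always
  reported alongside the values.
* **Brier score** is the mean squared error of the predicted
  probabilities.
* **Hosmer–Lemeshow** groups patients into $g = 10$ quantile bins of
  predicted probability by default and compares observed with expected
  events. Degrees of freedom default to $g - 2$, the convention for
  probabilities fitted on the same data; for externally specified
  probabilities — the validation setting — the statistic is closer to
  $\chi^2_g$, so `df_offset = 0` is exposed and used in the package's own
  uniformity checks. Bins whose expected events (or non-events) are
  exactly zero are merged with a neighbour under a warning.
* **Flexible calibration curves** smooth the binary outcome on the
  predicted probability with lowess (local linear, span 0.75, no
  robustness iterations — robustness downweighting is designed for
  heavy-tailed residuals and misbehaves on 0/1 outcomes), evaluated on a
  101-point grid over the observed prediction range and truncated to
  $[0,1]$. At least 20 observations are required; below that no smoothed
  curve is meaningful. **Emax / Eavg / E90** are the maximum, mean and
  90th-percentile (linear-interpolation quantile) absolute difference
  between each patient's predicted probability and the curve's calibrated
  estimate.

Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before
log-likelihoods so that a grossly wrong prediction yields a large but
finite penalty. Doses above a configurable 80 Gy ceiling warn rather than
error: values that high are almost certainly unit mistakes, but the
ceiling is a plausibility screen, not physics.

## What the synthetic cohorts emulate

`cohort_recipe()` defaults describe a 277-patient head-and-neck
(chemo)radiotherapy validation cohort: modality mix 204/59/14
(photon / photon+chemo / proton), per-arm dose means and SDs for the four
organs at risk, 68% pharyngeal tumours, 15% baseline dysphagia
prevalence, and the packaged original dysphagia model as the outcome
truth. The development-cohort baseline prevalence of 25% is worth using
as a preset when studying case-mix shift, which is one plausible cause of
real-world calibration drift.

Doses are generated as a Gaussian copula: a latent multivariate normal
with exchangeable correlation $\rho$ (default 0.4) supplies the
dependence, and each margin is mapped through the quantile function of
its normal distribution truncated to $[0, 80]$ Gy. Published cohort
tables give only marginal moments, but doses to neighbouring swallowing
structures are anatomically correlated, and correlated predictors are
exactly what stresses a revision fit realistically; $\rho = 0.4$ is a
moderate, deliberately round choice. The quantile-transform construction
was chosen over rejection/resampling of out-of-range draws because it
keeps every marginal *exactly* truncated normal (so sample moments can be
checked against closed-form truncated-normal moments,
`truncnorm_moments()`) and the latent correlation exactly $\rho$;
row-wise resampling would entangle each dose's marginal with the joint
acceptance region of all four, shifting means by an amount with no closed
form. The Pearson correlation of the generated doses is slightly below
the latent $\rho$ (a monotone-transform attenuation, small at these
truncation levels).

Draw order within a seed is fixed — modality, latent dose normals,
tumour location, baseline dysphagia, outcome — using R's default
Mersenne-Twister stream, so a recipe plus seed reproduces a cohort
byte-for-byte. Replication harnesses derive per-replicate seeds from the
master seed by a counter scheme, keeping every replicate individually
reproducible.

Miscalibration is specified generatively: the outcome probability is
$\mathrm{logit}^{-1}(\gamma S + \delta)$ after optional coefficient
overrides, so the three knobs correspond one-to-one to the three
departures the updating hierarchy can repair (intercept shift δ, slope
distortion γ, changed coefficients). Under the all-defaults recipe the
implied event rate is about 0.44 — the mean prediction of the packaged
model over this dose distribution — which is higher than the roughly 31%
(87/277) observed in the real validation cohort; that gap is itself a
calibration-in-the-large signal in the real data and we deliberately do
not tune the generator to hide it.

What the generator does **not** emulate: real inter-organ dose
correlation structure (plan optimizers create patterned, not
exchangeable, correlations), dependence of dose on tumour location,
longitudinal toxicity trajectories, and inter-observer variability in
toxicity scoring. Passing simulation tests therefore demonstrates the
statistical machinery is correct under a realistic-moment cohort, not
that any particular clinical model is transportable.

## Numerical and design choices

* Closed-form cases are used where they exist (intercept update on a
  constant linear predictor equals $\mathrm{logit}(\bar y) - S$) as test
  oracles, and two-parameter recalibration MLEs are cross-checked against
  an iteratively refined dense grid search on tiny cohorts.
* Rank-deficient revision designs are detected by QR factorization before
  fitting and reported with the aliased predictor names.
* Quantiles (E90, Hosmer–Lemeshow bins) use R's default
  linear-interpolation convention (type 7).
* Reports are JSON-first and embed the resolved configuration, seed and
  package version; calibration-curve and ROC coordinates are stored in
  the JSON so every figure can be redrawn without recomputation, and
  repeated runs with the same inputs are byte-identical.

The package's simulation checks use cohorts up to $n = 100{,}000$ for
moment fidelity, $n = 50{,}000$ for parameter-recovery asymptotics, and
150–300 replicates for closed-testing selection frequencies — sizes at
which binomial Monte-Carlo error is small relative to the margins being
asserted while the whole suite stays comfortably interactive.

## Known limitations

* The closed testing procedure assumes the four fits exist; pathological
  cohorts (single-class outcomes, constant linear predictors, perfect
  separation) abort with named errors rather than degrading.
* The revision level re-estimates the original predictor set only; model
  *extension* with new predictors is a different exercise and is out of
  scope.
* A revision selected on one cohort is itself unvalidated: its apparent
  performance on the selecting cohort is optimistic, and it should be
  externally validated on an independent dataset before clinical use.
* Multiple imputation is intentionally absent: the cohort contract is
  complete cases, and missingness is an error at the door.
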