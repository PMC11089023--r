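---
title: "Methods: ECV imaging biomarker and progression risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECV imaging biomarker and progression risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvrisk)
```

## The problem and the model

Locally advanced pancreatic cancer treated with intraoperative radiotherapy
is usually assessed as stable disease by diameter-based criteria a month
after treatment, yet progression-free survival (PFS) under that label is
heterogeneous. The package implements a stratification approach built on a
CT tissue biomarker — the extracellular volume fraction (ECV) — combined
with two radiological features and the CA19-9 tumor-marker response, folded
into an integer risk score evaluated with censoring-aware survival
machinery.

### ECV from paired-phase CT

For aligned unenhanced and portal-venous-phase volumes, enhancement is
ΔHU = PVP − unenhanced per voxel, and

$$\mathrm{ECV} = (1 - \mathrm{hct})\,
  \frac{\Delta HU_{tumor}}{\Delta HU_{aorta}} \times 100\%,$$

where the blood-pool enhancement $\Delta HU_{aorta}$ is the mean ΔHU over an
aortic mask and hct is the patient's hematocrit. The formula assumes
contrast has equilibrated between plasma and the extravascular extracellular
space at the portal-venous phase, so the tissue-to-blood enhancement ratio,
corrected for the cellular fraction of blood, estimates the fraction of
tissue volume accessible to contrast. Assumptions worth stating explicitly:

* **Voxel alignment.** Registration is an upstream responsibility; the
  constructors refuse mismatched grids, and `apply_misregistration()` exists
  precisely to quantify what phase mismatch does (the phantom study in
  `analysis/01_phantom_ecv.R` shows a 1-voxel shift already biases the VOI
  mean by ~0.6 ECV points on the default phantom).
* **No clipping.** Voxels with ECV outside [0, 100] % (noise, vessels,
  spill-over) are flagged and preserved, never altered, so masks can be
  audited.
* **Blood-pool summary.** Mean over the aortic mask by default (median
  available); the choice matters only when the mask is contaminated.
* **Hematocrit units.** Fractions in [0, 1); values in (1, 100] are accepted
  as percent with a warning, since lab sheets print percent.

### The risk score

The shipped table assigns: CA19-9 non-response 2 points; rim-enhancement 1;
peripancreatic fat infiltration 1; ECV ≥ 20 % −2, 16–20 % 0 (reference),
< 16 % 1. Totals span −2..5 and total ≥ 2 is high risk. Two conventions are
deliberate:

* The ECV bins partition the axis as right-open intervals with 20 % assigned
  to the protective ≥ 20 % bin, because that boundary is explicit in the
  published table.
* "Over 50 % reduction" in CA19-9 is read strictly (a fall of exactly 50 %
  with a post value still above 37 U/mL is a non-response), and
  normalisation means strictly below 37 U/mL.

The published points are shipped verbatim rather than re-derived. A Sullivan
construction (`sullivan_points()`: points = round(β·(v − v_ref)/B), rounding
half away from zero, bin midpoints as category values) is provided as a
tool, but no single base increment B reproduces the published table from the
published coefficients — e.g. CA19-9 non-response (β ≈ 0.466) carries 2
points while rim-enhancement (β ≈ 0.722) carries 1 — so the printed table is
treated as canonical and the derivation is documented as not reproducible.

## Synthetic data: what it emulates and what it does not

### Phantoms

`generate_phantom()` builds a homogeneous background with a spherical tumor
and a cylindrical aorta, each enhancing by a fixed ΔHU, plus optional
additive Gaussian HU noise on the enhanced phase. Ground-truth ECV is known
analytically per voxel, so noiseless recovery must be exact (asserted at
1e−9) and every downstream statistic has an oracle. The phantoms do not
model anatomy, partial-volume effects, beam hardening or contrast kinetics;
passing phantom tests demonstrates correctness of the arithmetic and the
mask plumbing, not robustness to scanner physics.

### Cohorts

`generate_cohort()` draws independent binary covariates (rim-enhancement
37/103, fat infiltration 41/103, CA19-9 non-response 39/103 — the published
prevalences), ECV from Normal(19.1, 6.38) truncated to [0, 60] % (sd from
the published IQR 14.7–23.3 via IQR/1.349), and PFS times from a Weibull
proportional-hazards model with the published multivariable log-hazards
(HRs 2.058, 1.612, 1.594, and 0.941 per ECV percentage point). Covariates
are simulated independently because no correlation structure is published;
censoring defaults to none because the reference cohort observed progression
in every patient, with administrative censoring available for testing
censoring-aware statistics.

The baseline hazard has no published parametric form, so a two-parameter
Weibull is fitted by least squares on the complementary log-log scale to the
three published marginal PFS anchors (88.3 / 52.4 / 20.4 % at 3 / 6 / 12
months), giving k ≈ 1.84, λ ≈ 8.71 months. Because those anchors are
*marginal* quantities, the linear predictor is centered at its population
expectation by default (`center_covariates = TRUE`): the calibrated Weibull
then plays the role of the marginal hazard, and covariate effects spread
individuals around it. With centering, the simulated marginal median PFS
lands near 6.9–7.0 months against the published 6.40; the residual gap is
the price of (a) forcing a 2-parameter Weibull through three anchors that a
Kaplan–Meier step curve generated, and (b) the frailty-like dispersion the
centered linear predictor adds to the marginal. Without centering the
marginal median would inflate to ~9.6 months, which is why centering is the
default and not a tuning knob.

## Survival machinery: estimators and numerical choices

* **KM / log-rank / Cox** are delegated to the `survival` package
  (product-limit, (O−E)²/V on 1 df, partial likelihood with Efron tie
  handling). A median that the curve never reaches is reported "not
  reached", never extrapolated.
* **Univariate screen**: single-covariate Cox fits, retain p < 0.05, then
  one multivariable fit on the retained set. Stepwise direction/criteria are
  not published; the two-stage screen is the default and no automatic
  stepwise search is performed.
* **Time-dependent ROC**: cumulative-cases / dynamic-controls with IPCW.
  Cases by horizon t are weighted by 1/Ĝ(T⁻), controls at risk beyond t by
  1/Ĝ(t), with Ĝ the Kaplan–Meier estimate of the censoring distribution;
  ties in the marker count one half. Incident/dynamic variants are out of
  scope.
* **Maxstat cutpoint**: subjects receive log-rank (Savage) scores
  aᵢ = δᵢ − Λ̂(Tᵢ); each candidate cut (midpoints between distinct score
  values whose below-cut proportion lies in the 0.10–0.90 window) gets the
  standardized statistic |S − E(S)|/√Var(S) under sampling-without-
  replacement moments; the maximum is selected. Inference is by seeded
  permutation of the scores against the outcomes, which accounts for the
  multiplicity of the scan exactly rather than via an improved-Bonferroni
  bound. The returned cutpoint is the smallest observed value above the
  maximizing midpoint, so the induced split is `score < c` vs `score ≥ c`,
  matching `stratify()`.
* **Calibration**: quantile bins of predicted survival at the horizon vs
  within-bin KM at the horizon, percentile bootstrap CIs (subjects resampled
  within bin, seeded); degenerate bins are collapsed with a warning;
  `n_boot = 0` yields point estimates only.
* **Classification at a horizon**: predicted positive = predicted survival ≥
  π; observed positive = progression-free at t; subjects censored before t
  are unclassifiable and are excluded *and counted*. Proportion CIs are
  exact Clopper–Pearson, chosen because exact-style intervals are the
  convention for these small-cell clinical tables.

## Problem sizes and reproducibility

The test suite and the acceptance script use cohort sizes chosen to make
each check sharp but cheap: n = 5000 for Cox parameter recovery (sampling
error on the hazard-ratio scale well under the assertion bands), n = 50,000
for the marginal-median check, 100 replicates for the maxstat recovery and
type-I studies, and 200 replicates at n = 500 for Cox CI coverage. Every
stochastic routine takes an explicit seed, and fixed seed implies
bit-identical phantoms, cohorts, permutation p-values and pipeline outputs
(asserted byte-for-byte in the pipeline tests).

## Known limitations

* Phantoms are geometric, noise is additive Gaussian in HU; no claim about
  scanner physics or segmentation difficulty follows from green tests.
* The cohort simulator matches published *marginals*; joint structure
  (covariate correlations, non-proportional hazards) is unmodelled, so
  simulation-based performance numbers (AUCs, cutpoints) characterise the
  method, not the clinical population.
* The published per-cell classification table of the reference study cannot
  be reconciled internally and is not reproduced; only the metric
  definitions are implemented.
* Proportional-hazards diagnostics, competing risks, time-varying covariates
  and overall survival are out of scope.
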