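# ecvrisk

Progression-risk analysis for locally advanced pancreatic cancer (LAPC)
treated with intraoperative radiotherapy (IORT), built around a CT imaging
biomarker: the tumor **extracellular volume fraction (ECV)** estimated from a
routine paired unenhanced / portal-venous-phase (PVP) contrast-enhanced CT.

Most LAPC patients are classed as stable disease by RECIST shortly after
IORT, yet their outcomes diverge sharply. This package implements, end to
end and fully testable on synthetic data:

1. **ECV mapping.** With hematocrit *hct* and enhancement
   ΔHU = PVP − unenhanced,

   ECV = (1 − hct) · (ΔHU_tumor / ΔHU_aorta) · 100 %

   computed voxel-wise, normalised by the blood-pool (aortic) enhancement,
   with VOI statistics, reader averaging, and segmentation agreement (Dice,
   Cohen's kappa, ICC(A,1)).
2. **A points-based risk score.** CA19-9 non-response 2 points,
   rim-enhancement 1, peripancreatic fat infiltration 1, and ECV binned as
   < 16 % → 1, 16–20 % → 0, ≥ 20 % → −2 (high stromal ECV is protective).
   Totals range −2 to 5; total ≥ 2 is high risk. The generic Sullivan
   construction (integer points from Cox coefficients via a base increment)
   is included as a construction tool.
3. **Survival evaluation.** Kaplan–Meier and log-rank, multivariable Cox
   (Efron ties) with univariate screening, time-dependent ROC with inverse
   probability of censoring weighting, maximally selected rank-statistics
   cutpoints with permutation inference, bootstrap calibration curves, and
   horizon classification metrics with Clopper–Pearson intervals.
4. **Synthetic data.** CT phantoms with analytically known ECV and Weibull
   proportional-hazards cohorts whose prevalences, hazard ratios and
   baseline survival are calibrated to the published cohort summaries, so
   every stage has an exact or statistical oracle.

## Worked example

```r
library(ecvrisk)

# A patient with CA19-9 non-response, rim-enhancement, fat infiltration,
# and a VOI-mean ECV of 15.9%:
pt <- data.frame(ca199_responder = FALSE, rim_enhancement = 1,
                 fat_infiltration = 1, ecv_pct = 15.9)
total_score(pt)[, c("total", "risk_class")]
#>   total risk_class
#> 1     5       high
```

A total of 5 points (2 + 1 + 1 + 1) places the patient above the high-risk
cutoff of 2; the mirror-image favourable patient (responder, no adverse
imaging features, ECV 23.7 %) scores −2 and is low risk.

The imaging side, from a phantom with known truth:

```r
ph    <- generate_phantom(phantom_spec(delta_hu_tumor = 30,
                                       delta_hu_aorta = 100,
                                       hematocrit = 0.40, noise_sd = 0))
delta <- compute_delta_hu(ph$pair)
da    <- blood_pool_delta(delta, ph$aorta_mask)
map   <- compute_ecv_map(delta, da, hematocrit = 0.40)
mean_ecv_in_voi(map, ph$tumor_mask)
#> [1] 18
```

exactly (1 − 0.40) · (30/100) · 100 = 18 %.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

| script | what it shows |
| --- | --- |
| `01_phantom_ecv.R` | exact noiseless ECV recovery; noise and misregistration sensitivity |
| `02_cohort_calibration.R` | Weibull baseline fitted to the 3/6/12-month PFS anchors; marginal checks |
| `03_cox_recovery.R` | univariate screen + multivariable Cox recovering the generating hazard ratios |
| `04_score_evaluation.R` | full pipeline: scoring, stratified KM, time-dependent AUC, maxstat cutpoint |

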