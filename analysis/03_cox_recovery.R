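#!/usr/bin/env Rscript
# Parameter-recovery experiment for the multivariable Cox model.
#
# Simulates a cohort of n = 5000 with the published multivariable
# log-hazards as ground truth, runs the univariate screen (p < 0.05) plus
# the four-covariate Cox fit, and tabulates fitted vs generating hazard
# ratios. This is the evidence that the survival-evaluation stack estimates
# what the generator encodes.

suppressPackageStartupMessages(library(ecvrisk))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n = 5000L, seed = 314159L)
cohort <- generate_cohort(spec)
covars <- c("ca199_nonresponse", "ecv_pct", "rim_enhancement", "fat_infiltration")

screen <- univariate_screen(cohort, covars, alpha = 0.05)
cat("Univariate screen (p < 0.05) retained:",
    paste(screen$retained, collapse = ", "), "\n\n")

fit <- screen$multivariable
truth <- exp(spec$beta[fit$table$term])
out <- data.frame(term = fit$table$term,
                  true_hr = unname(truth),
                  fitted_hr = fit$table$hr,
                  lower = fit$table$lower, upper = fit$table$upper,
                  p_value = fit$table$p_value)
out$rel_error_pct <- 100 * (out$fitted_hr - out$true_hr) / out$true_hr
write.csv(out, "results/cox_recovery.csv", row.names = FALSE)

cat("Multivariable Cox fit vs generating hazard ratios (n = 5000):\n")
print(out, row.names = FALSE, digits = 4)
cat("\nAll generating hazard ratios are inside the fitted 95% CIs:",
    all(out$lower <= out$true_hr & out$true_hr <= out$upper), "\n")
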