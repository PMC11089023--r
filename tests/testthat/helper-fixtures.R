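# Small fixtures shared across test files; everything is generated in code.

noiseless_phantom <- function(...) {
  generate_phantom(phantom_spec(noise_sd = 0, ...))
}

# Compact cohort with a known strong binary effect, for fit/screen tests.
binary_effect_cohort <- function(n, hr, seed, rate = 0.1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  data.frame(pfs_months = rexp(n, rate * hr^x),
             event = 1L,
             x = x)
}

# VOI-mean ECV recomputed from a phantom through the imaging module.
recover_voi_mean <- function(ph, pvp = NULL) {
  pair <- if (is.null(pvp)) ph$pair else
    phase_volume_pair(ph$pair$unenhanced, pvp)
  delta <- compute_delta_hu(pair)
  da <- blood_pool_delta(delta, ph$aorta_mask)
  map <- compute_ecv_map(delta, da, ph$spec$hematocrit)
  mean_ecv_in_voi(map, ph$tumor_mask)
}
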