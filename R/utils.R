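#' @keywords internal
"_PACKAGE"

# Stop with a caller-facing message (no call in the condition).
abort <- function(...) stop(..., call. = FALSE)

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Validate a hematocrit given as a fraction; values in (1, 100] are read as
# percent and rescaled, with a warning, so lab-sheet entries like "43" work.
normalize_hematocrit <- function(hct) {
  if (length(hct) != 1L || !is.finite(hct)) {
    abort("hematocrit must be a single finite number")
  }
  if (hct > 1 && hct <= 100) {
    warning(sprintf("hematocrit %.3g interpreted as percent; using %.3g", hct, hct / 100))
    hct <- hct / 100
  }
  if (hct < 0 || hct >= 1) {
    abort("hematocrit must lie in [0, 1) (fraction) or (1, 100] (percent)")
  }
  hct
}

# Seed handling: every stochastic entry point takes `seed`; NULL leaves the
# RNG state untouched so callers can manage their own stream.
set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("seed must be a single finite number or NULL")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Truncated-normal sampler via inverse CDF; exact, vectorised, seedable by
# the caller's RNG state.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
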