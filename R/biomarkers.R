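#' Percent change in CA19-9 after treatment
#'
#' \eqn{(post - baseline)/baseline \times 100}; negative values are declines.
#' Scale-invariant: multiplying both measurements by the same positive factor
#' leaves the change unchanged.
#'
#' @param baseline,post serum CA19-9 in U/mL; baseline must be positive.
#'   Vectorised.
#' @return Signed percent change.
#' @export
ca199_change <- function(baseline, post) {
  if (any(baseline <= 0)) abort("baseline CA19-9 must be positive")
  (post - baseline) / baseline * 100
}

#' CA19-9 response after treatment
#'
#' A patient responds when CA19-9 falls by more than 50% from baseline
#' (strictly) or normalises below 37 U/mL. Only patients with baseline
#' CA19-9 above 37 U/mL are eligible (CA19-9 non-secretors and
#' already-normal baselines cannot be assessed); ineligible records raise an
#' error rather than returning a silent non-response.
#'
#' @param baseline,post serum CA19-9 in U/mL. Vectorised.
#' @return Logical: `TRUE` = responder.
#' @export
ca199_response <- function(baseline, post) {
  if (any(baseline <= 37)) {
    abort("ineligible record: baseline CA19-9 must exceed 37 U/mL")
  }
  ca199_change(baseline, post) < -50 | post < 37
}

#' Risk-score points for an ECV measurement
#'
#' The ECV item of the scoring table: high stromal ECV is protective, so
#' points decrease with ECV. Bins partition the axis as `< 16` (1 point),
#' `[16, 20)` (0 points, reference) and `>= 20` (−2 points).
#'
#' @param ecv ECV fraction in percent, finite and non-negative. Vectorised.
#' @return Integer points in `{-2, 0, 1}`.
#' @export
ecv_points <- function(ecv) {
  if (any(!is.finite(ecv)) || any(ecv < 0)) abort("ecv must be finite and non-negative")
  ifelse(ecv >= 20, -2L, ifelse(ecv >= 16, 0L, 1L))
}

#' Cohen's kappa for two categorical readers
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} where
#' \eqn{p_o} is observed agreement and \eqn{p_e} the agreement expected from
#' the readers' marginal label frequencies. Symmetric in the readers; 1 for
#' perfect agreement; undefined when both readers use a single common
#' category (\eqn{p_e = 1}).
#'
#' @param reader1,reader2 equal-length categorical vectors (length >= 2).
#' @return Scalar kappa.
#' @export
cohens_kappa <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) abort("readers must rate the same cases")
  if (length(reader1) < 2L) abort("need at least two cases")
  lev <- sort(unique(c(as.character(reader1), as.character(reader2))))
  if (length(lev) < 2L) abort("kappa undefined: only one category observed")
  tab <- table(factor(reader1, lev), factor(reader2, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) abort("kappa undefined: expected agreement is 1")
  (po - pe) / (1 - pe)
}

#' Intraclass correlation for two quantitative readers
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (ICC(A,1)
#' in the McGraw–Wong taxonomy), computed from the two-way ANOVA mean
#' squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{n} subjects and \eqn{k = 2} raters. Equals 1 for identical
#' readings with non-zero between-subject variance; symmetric in the readers.
#'
#' @param reader1,reader2 equal-length numeric vectors (length >= 3).
#' @return Scalar ICC.
#' @export
icc <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) abort("readers must rate the same cases")
  n <- length(reader1)
  if (n < 3L) abort("need at least three cases")
  ratings <- cbind(reader1, reader2)
  k <- 2L
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0) abort("ICC undefined: zero total variance")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Interpret an agreement coefficient
#'
#' Conventional qualitative bands for kappa/ICC: below 0.20 poor, up to 0.40
#' fair, up to 0.60 moderate, up to 0.80 good, above 0.80 excellent. (The
#' printed bands leave a gap between 0.20 and 0.21; values there are mapped
#' to "fair".)
#'
#' @param x agreement coefficient.
#' @return Character band label.
#' @export
agreement_band <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) abort("x must be a single number")
  if (x < 0.20) "poor"
  else if (x <= 0.40) "fair"
  else if (x <= 0.60) "moderate"
  else if (x <= 0.80) "good"
  else "excellent"
}

#' Derive scoring features for a cohort table
#'
#' Adds the derived columns the scoring table consumes: `ca199_responder`
#' (from either an explicit `ca199_nonresponse` indicator or baseline/post
#' marker columns) and passes through `rim_enhancement`, `fat_infiltration`,
#' `ecv_pct`.
#'
#' @param cohort data frame with either `ca199_nonresponse` or
#'   `ca199_baseline` + `ca199_post`, plus `rim_enhancement`,
#'   `fat_infiltration`, `ecv_pct`.
#' @return The data frame with a logical `ca199_responder` column added.
#' @export
derive_features <- function(cohort) {
  needed <- c("rim_enhancement", "fat_infiltration", "ecv_pct")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    abort("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if ("ca199_nonresponse" %in% names(cohort)) {
    cohort$ca199_responder <- cohort$ca199_nonresponse == 0
  } else if (all(c("ca199_baseline", "ca199_post") %in% names(cohort))) {
    cohort$ca199_responder <- ca199_response(cohort$ca199_baseline, cohort$ca199_post)
  } else {
    abort("need ca199_nonresponse or ca199_baseline + ca199_post")
  }
  cohort
}
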