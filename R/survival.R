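#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator via [survival::survfit()]. Without censoring this
#' equals the empirical survivor function. The median is the first time at
#' which the curve drops to 0.5 or below; when the curve never reaches 0.5
#' the median is reported as not reached (`NA` with `median_reached = FALSE`)
#' rather than extrapolated.
#'
#' @param time positive follow-up times in months.
#' @param event 1 = progression, 0 = censored.
#' @return Object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `median`, `median_reached`, and the underlying `survfit`.
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med, median_reached = !is.na(med),
                 fit = fit),
            class = "km_curve")
}

#' Survival probability at given times from a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation; times before the first event
#' return 1.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param times query times.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(times, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Two-group log-rank test
#'
#' Standard (O − E)^2 / V chi-square on 1 degree of freedom via
#' [survival::survdiff()]. Invariant to swapping group labels; identically
#' distributed groups give statistic 0.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return List with `chisq`, `p_value`, `obs`, `exp` per group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2L) abort("log-rank test requires exactly two groups")
  if (any(tabulate(g, 2L) == 0L)) abort("both groups must contain subjects")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximisation with the Efron tie correction via
#' [survival::coxph()]. Reports per-covariate log-hazards, hazard ratios
#' with 95% Wald confidence intervals, and p-values.
#'
#' @param data data frame with `pfs_months`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @return Object of class `cox_fit`: list with `table` (data frame: `term`,
#'   `beta`, `hr`, `lower`, `upper`, `p_value`), `loglik`, `n`, `n_event`
#'   and the underlying `coxph` fit.
#' @export
fit_cox <- function(data, covariates) {
  check_cohort(data, covariates)
  if (sum(data$event) < length(covariates) + 1L) {
    abort("too few events for the number of covariates")
  }
  fml <- stats::as.formula(paste("survival::Surv(pfs_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    abort("Cox fit did not converge")
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    beta = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2],
                 n = s$n, n_event = s$nevent, fit = fit),
            class = "cox_fit")
}

#' Univariate screen followed by a multivariable Cox fit
#'
#' Fits one single-covariate Cox model per candidate, retains candidates with
#' p below `alpha`, then fits one multivariable model on the retained set —
#' the usual two-stage variable selection of clinical survival analyses.
#'
#' @param data data frame with `pfs_months`, `event` and candidate columns.
#' @param candidates character vector of candidate covariates.
#' @param alpha retention threshold on the univariate p-value.
#' @return List with `univariate` (data frame of per-candidate fits),
#'   `retained` (character) and `multivariable` (a `cox_fit`, or `NULL` when
#'   nothing is retained).
#' @export
univariate_screen <- function(data, candidates, alpha = 0.05) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  uni <- do.call(rbind, lapply(candidates, function(v) fit_cox(data, v)$table))
  retained <- uni$term[uni$p_value < alpha]
  multi <- if (length(retained)) fit_cox(data, retained) else NULL
  list(univariate = uni, retained = retained, multivariable = multi)
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-cases / dynamic-controls AUC at horizon `t`: cases are subjects
#' with an observed event by `t`, controls are subjects still at risk beyond
#' `t`, and each contributes an IPCW weight from the Kaplan-Meier estimate of
#' the censoring distribution (cases weighted by \eqn{1/\hat G(T_i^-)},
#' controls by \eqn{1/\hat G(t)}). The AUC is the weighted probability that a
#' case's marker exceeds a control's, with ties counted half.
#'
#' @param marker per-subject risk marker (higher = higher risk).
#' @param time,event follow-up times and event indicators.
#' @param horizon evaluation time `t` in months.
#' @return Object of class `time_roc`: list with `auc`, `horizon`,
#'   `n_cases`, `n_controls`, `weighting = "ipcw-cumulative/dynamic"`.
#' @export
time_dependent_auc <- function(marker, time, event, horizon) {
  check_surv(time, event)
  if (length(marker) != length(time)) abort("marker and survival data differ in length")
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case)) abort("no events before the horizon")
  if (!any(is_ctrl)) abort("no subjects at risk beyond the horizon")
  # censoring survivor function G(t) = KM of (time, 1 - event)
  gfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  gsurv <- function(t) {
    idx <- findInterval(t, gfit$time)
    pmax(c(1, gfit$surv)[idx + 1L], .Machine$double.eps)
  }
  # left limit G(T-) for cases: evaluate just below the event time
  w_case <- 1 / gsurv(time[is_case] - .Machine$double.eps^0.5)
  w_ctrl <- rep(1 / gsurv(horizon), sum(is_ctrl))
  mc <- marker[is_case]
  mk <- marker[is_ctrl]
  cmp <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
  wmat <- outer(w_case, w_ctrl)
  structure(list(auc = sum(wmat * cmp) / sum(wmat),
                 horizon = horizon,
                 n_cases = sum(is_case), n_controls = sum(is_ctrl),
                 weighting = "ipcw-cumulative/dynamic"),
            class = "time_roc")
}

#' Maximally selected rank-statistics cutpoint
#'
#' Scans candidate cutpoints of a score against a censored outcome: subjects
#' are scored with log-rank (Savage) scores
#' \eqn{a_i = \delta_i - \hat\Lambda(T_i)} (Nelson-Aalen cumulative hazard),
#' and for every candidate split the standardized two-group log-rank
#' statistic \eqn{|S_c - E(S_c)| / \sqrt{Var(S_c)}} is computed under the
#' permutation (sampling-without-replacement) moments. The cutpoint with the
#' maximal statistic is selected; inference on the maximum uses a seeded
#' permutation test (the score vector is permuted against the outcomes),
#' which accounts for the multiplicity of the scan.
#'
#' Candidates are the midpoints between consecutive distinct score values
#' whose left-group proportion lies inside the quantile window. The returned
#' `cutpoint` is the smallest observed score value above the selected
#' midpoint, so the induced split is `score < cutpoint` vs `score >= cutpoint`
#' (matching [stratify()]).
#'
#' @param score per-subject score values.
#' @param time,event follow-up times and event indicators.
#' @param window proportion window (low, high): only splits leaving at least
#'   `low` and at most `high` of subjects below the cut are considered.
#' @param n_perm number of permutations for the p-value (0 = no p-value).
#' @param seed RNG seed for the permutations.
#' @return Object of class `cutpoint_result`: list with `cutpoint`,
#'   `statistic` (maximal standardized statistic), `p_value`, `candidates`
#'   (data frame of midpoint cuts and statistics), `n_perm`.
#' @export
maxstat_cutpoint <- function(score, time, event, window = c(0.1, 0.9),
                             n_perm = 999L, seed = 1L) {
  check_surv(time, event)
  if (length(score) != length(time)) abort("score and survival data differ in length")
  n <- length(score)
  a <- logrank_scores(time, event)
  ord <- order(score)
  s_sorted <- score[ord]
  a_sorted <- a[ord]
  distinct <- unique(s_sorted)
  if (length(distinct) < 2L) abort("score is constant: no candidate cutpoints")
  # split after position m: left group = m smallest scores
  last_idx <- cumsum(table(factor(s_sorted, levels = distinct)))
  m_all <- last_idx[-length(last_idx)]           # sizes of the left group
  prop <- m_all / n
  keep <- prop >= window[1] & prop <= window[2]
  if (!any(keep)) abort("no candidate cutpoints inside the quantile window")
  m <- m_all[keep]
  mids <- (distinct[-length(distinct)] + distinct[-1])[keep] / 2
  upper_vals <- distinct[-1][keep]               # smallest value above each midpoint
  abar <- mean(a)
  sig2 <- mean((a - abar)^2)
  std_stats <- function(av) {
    cs <- cumsum(av)[m_all][keep]
    v <- m * (n - m) * sig2 / (n - 1)
    abs(cs - m * abar) / sqrt(v)
  }
  zs <- std_stats(a_sorted)
  best <- which.max(zs)
  p_value <- NA_real_
  if (n_perm > 0) {
    set_seed_if_given(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zb <- std_stats(sample(a))
      if (max(zb) >= zs[best]) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(cutpoint = upper_vals[[best]],
                 statistic = zs[[best]],
                 p_value = p_value,
                 candidates = data.frame(midpoint = mids, n_below = m,
                                         statistic = zs),
                 n_perm = n_perm),
            class = "cutpoint_result")
}

# Log-rank (Savage) scores: event indicator minus Nelson-Aalen cumulative
# hazard at the subject's observed time.
logrank_scores <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  r <- vapply(ut, function(t) sum(time >= t), numeric(1))
  haz <- cumsum(d / r)
  idx <- findInterval(time, ut)
  lam <- c(0, haz)[idx + 1L]
  event - lam
}

#' Bootstrap calibration curve for predicted survival
#'
#' Bins subjects by predicted survival probability at the horizon, compares
#' the bin-mean prediction with the Kaplan-Meier observed survival at the
#' horizon within the bin, and attaches bootstrap percentile confidence
#' intervals (subjects resampled within bin). A well-calibrated model puts
#' every bin on the diagonal.
#'
#' @param predicted per-subject predicted survival probabilities at `horizon`,
#'   in `[0, 1]`.
#' @param time,event follow-up times and event indicators.
#' @param horizon evaluation time in months.
#' @param n_boot bootstrap resamples (0 = point estimates only).
#' @param n_bins number of quantile bins; bins with identical boundaries are
#'   collapsed with a warning.
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed`, `lower`, `upper`.
#' @export
calibration_curve <- function(predicted, time, event, horizon,
                              n_boot = 1000L, n_bins = 5L, seed = 1L) {
  check_surv(time, event)
  if (any(predicted < 0 | predicted > 1)) abort("predictions must lie in [0, 1]")
  if (length(predicted) != length(time)) abort("predictions and data differ in length")
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) - 1L < n_bins) {
    warning("collapsed empty/degenerate calibration bins: using ",
            length(br) - 1L, " bins")
  }
  if (length(br) < 2L) {
    bin <- factor(rep(1L, length(predicted)))
  } else {
    bin <- cut(predicted, br, include.lowest = TRUE)
  }
  set_seed_if_given(seed)
  rows <- lapply(levels(bin), function(b) {
    sel <- bin == b
    km_obs <- km_surv_at(km_estimate(time[sel], event[sel]), horizon)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      idx <- which(sel)
      boots <- vapply(seq_len(n_boot), function(i) {
        take <- sample(idx, length(idx), replace = TRUE)
        if (sum(event[take]) == 0) return(1)
        km_surv_at(km_estimate(time[take], event[take]), horizon)
      }, numeric(1))
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
    data.frame(bin = b, n = sum(sel),
               mean_predicted = mean(predicted[sel]),
               observed = km_obs, lower = ci[1], upper = ci[2])
  })
  do.call(rbind, rows)
}

#' Classification metrics of a survival prediction at a horizon
#'
#' Dichotomises predicted survival at threshold `pi` (predicted positive =
#' predicted probability of remaining progression-free at `t` at least `pi`)
#' against the observed state at the horizon (observed positive = still
#' progression-free at `t`). Subjects censored before the horizon cannot be
#' classified; they are excluded and counted. Confidence intervals are
#' exact Clopper-Pearson.
#'
#' @param predicted per-subject predicted survival probabilities at `horizon`.
#' @param threshold classification threshold `pi` in `[0, 1]`.
#' @param time,event follow-up times and event indicators.
#' @param horizon evaluation time in months.
#' @return List with `metrics` (data frame: `metric`, `estimate` (percent),
#'   `lower`, `upper`, `numerator`, `denominator`), `confusion` (TP/FP/FN/TN
#'   counts; "positive" = progression-free), `n_excluded`.
#' @export
horizon_classification_metrics <- function(predicted, threshold, time, event,
                                           horizon) {
  check_surv(time, event)
  if (length(predicted) != length(time)) abort("predictions and data differ in length")
  classifiable <- (event == 1 & time <= horizon) | time > horizon
  n_excluded <- sum(!classifiable)
  pred_pos <- predicted[classifiable] >= threshold
  obs_pos <- time[classifiable] > horizon
  tp <- sum(pred_pos & obs_pos); fp <- sum(pred_pos & !obs_pos)
  fn <- sum(!pred_pos & obs_pos); tn <- sum(!pred_pos & !obs_pos)
  prop_ci <- function(num, den) {
    if (den == 0) {
      return(data.frame(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                        numerator = num, denominator = den))
    }
    ci <- stats::binom.test(num, den)$conf.int
    data.frame(estimate = 100 * num / den, lower = 100 * ci[1],
               upper = 100 * ci[2], numerator = num, denominator = den)
  }
  metrics <- rbind(
    cbind(metric = "accuracy", prop_ci(tp + tn, tp + tn + fp + fn)),
    cbind(metric = "sensitivity", prop_ci(tp, tp + fn)),
    cbind(metric = "specificity", prop_ci(tn, tn + fp)),
    cbind(metric = "ppv", prop_ci(tp, tp + fp)),
    cbind(metric = "npv", prop_ci(tn, tn + fn))
  )
  list(metrics = metrics,
       confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
       n_excluded = n_excluded)
}

check_surv <- function(time, event) {
  if (length(time) != length(event)) abort("time and event differ in length")
  if (anyNA(time) || anyNA(event)) abort("missing values in survival data")
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be finite and positive")
  if (!all(event %in% c(0, 1))) abort("event indicator must be 0/1")
  invisible(TRUE)
}

check_cohort <- function(data, covariates) {
  needed <- c("pfs_months", "event", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) abort("missing columns: ", paste(missing_cols, collapse = ", "))
  check_surv(data$pfs_months, data$event)
  if (anyNA(data[covariates])) abort("missing values in covariates")
  invisible(TRUE)
}
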