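test_that("Kaplan-Meier matches hand product-limit values", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2: S(1) = 2/3, S(3) = 0
  kc <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(kc, c(1, 3)), c(2 / 3, 0))
  expect_equal(kc$median, 3)
  # all censored: flat at 1, median not reached
  k0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  expect_false(k0$median_reached)
})

test_that("KM without censoring equals the empirical survivor function", {
  set.seed(11)
  t <- rexp(500, 0.2)
  km <- km_estimate(t, rep(1, 500))
  grid <- quantile(t, c(0.1, 0.25, 0.5, 0.75, 0.9))
  emp <- vapply(grid, function(g) mean(t > g), numeric(1))
  expect_equal(unname(km_surv_at(km, grid)), unname(emp), tolerance = 1e-12)
})

test_that("log-rank: zero on identical groups, label-symmetric, hand value", {
  t <- c(1, 2, 3, 1, 2, 3); e <- rep(1, 6); g <- rep(1:2, each = 3)
  expect_equal(logrank_test(t, e, g)$chisq, 0, tolerance = 1e-12)
  # hand-tabulated O-E over risk sets for (1,2,3) vs (4,5,6), all events:
  # O_A = 3, E_A = 0.5 + 0.4 + 0.25 = 1.15, V = 0.25 + 0.24 + 0.1875
  lr <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), g)
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  lr_swap <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), 3 - g)
  expect_equal(lr_swap$chisq, lr$chisq, tolerance = 1e-12)
  # strong simulated effect is detected
  co <- binary_effect_cohort(1000, hr = 3, seed = 12)
  expect_lt(logrank_test(co$pfs_months, co$event, co$x)$p_value, 0.001)
  expect_error(logrank_test(t, e, rep(1, 6)), "two groups")
})

test_that("Cox fit recovers a known hazard ratio and nulls stay null", {
  co <- binary_effect_cohort(5000, hr = 2, seed = 13)
  fit <- fit_cox(co, "x")
  expect_equal(fit$table$hr, 2, tolerance = 0.1)
  expect_true(fit$table$lower < fit$table$hr & fit$table$hr < fit$table$upper)
  null <- binary_effect_cohort(2000, hr = 1, seed = 14)
  nf <- fit_cox(null, "x")$table
  expect_lt(abs(nf$beta), 0.15)
  expect_true(nf$lower < 1 && nf$upper > 1)
  few <- co[1:3, ]; few$event <- c(1L, 0L, 0L)
  expect_error(fit_cox(few, "x"), "too few events")
})

test_that("Cox confidence intervals cover the truth at nominal rate", {
  covered <- vapply(1:200, function(i) {
    co <- binary_effect_cohort(500, hr = 2, seed = 1000 + i)
    tab <- fit_cox(co, "x")$table
    tab$lower <= 2 && 2 <= tab$upper
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("univariate screen retains strong covariates and respects alpha", {
  set.seed(15)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  d <- data.frame(pfs_months = rexp(n, 0.1 * 2.5^x), event = 1L,
                  x = x, noise = noise)
  sc <- univariate_screen(d, c("x", "noise"))
  expect_true("x" %in% sc$retained)
  expect_s3_class(sc$multivariable, "cox_fit")
  none <- univariate_screen(d, c("x", "noise"), alpha = 0)
  expect_length(none$retained, 0)
  expect_null(none$multivariable)
  # pure-noise candidates retained ~5% of the time
  hits <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    dd <- data.frame(pfs_months = rexp(200, 0.1), event = 1L,
                     z = rnorm(200))
    length(univariate_screen(dd, "z")$retained)
  }, numeric(1))
  expect_lt(mean(hits), 0.12)
})

test_that("time-dependent AUC: perfect, independent and sign-flipped markers", {
  set.seed(16)
  t <- rexp(400, 0.1); e <- rep(1, 400)
  expect_equal(time_dependent_auc(-t, t, e, 6)$auc, 1)
  flip <- time_dependent_auc(t, t, e, 6)$auc
  expect_equal(flip, 1 - time_dependent_auc(-t, t, e, 6)$auc, tolerance = 1e-12)
  m <- rnorm(400)
  a <- time_dependent_auc(m, t, e, 6)
  expect_true(a$auc >= 0 && a$auc <= 1)
  # invariant under monotone transformation of the marker
  expect_equal(time_dependent_auc(exp(m / 2), t, e, 6)$auc, a$auc,
               tolerance = 1e-12)
  expect_error(time_dependent_auc(m, t, e, 1e6), "at risk")
})

test_that("IPCW AUC is unbiased to 0.5 under independence with censoring", {
  set.seed(17)
  n <- 3000
  m <- rnorm(n)
  t <- rexp(n, 0.1)
  cens <- rexp(n, 0.05)
  obs <- pmin(t, cens); e <- as.integer(t <= cens)
  a <- time_dependent_auc(m, obs, e, 6)
  expect_equal(a$auc, 0.5, tolerance = 0.03)
})

test_that("maxstat scan selects the maximizing cut and handles degeneracy", {
  set.seed(18)
  n <- 300
  score <- sample(-2:5, n, replace = TRUE)
  time <- rexp(n, 0.1 * ifelse(score >= 2, 3, 1))
  cp <- maxstat_cutpoint(score, time, rep(1, n), n_perm = 99, seed = 1)
  expect_equal(cp$cutpoint, 2)
  expect_lt(cp$p_value, 0.05)
  # selected statistic is the maximum over candidates by construction
  expect_equal(cp$statistic, max(cp$candidates$statistic))
  expect_true(all(cp$candidates$statistic <= cp$statistic))
  # deterministic given the seed
  cp2 <- maxstat_cutpoint(score, time, rep(1, n), n_perm = 99, seed = 1)
  expect_identical(cp$p_value, cp2$p_value)
  expect_error(maxstat_cutpoint(rep(1, n), time, rep(1, n)), "constant")
})

test_that("calibration curve puts a calibrated model on the diagonal", {
  set.seed(19)
  n <- 1500
  lp <- rnorm(n, sd = 0.7)
  t <- 8 * (-log(runif(n)) / exp(lp))
  e <- rep(1L, n)
  pred <- exp(-(6 / 8) * exp(lp))   # true model survival at 6 months
  cal <- calibration_curve(pred, t, e, horizon = 6, n_boot = 200, seed = 5)
  expect_true(all(cal$lower <= cal$observed & cal$observed <= cal$upper))
  on_diag <- cal$lower <= cal$mean_predicted & cal$mean_predicted <= cal$upper
  expect_gte(mean(on_diag), 0.8)
  # degenerate configs
  nociw <- calibration_curve(pred, t, e, 6, n_boot = 0)
  expect_true(all(is.na(nociw$lower)))
  expect_warning(
    one <- calibration_curve(rep(0.5, 100), t[1:100], e[1:100], 6,
                             n_boot = 0, n_bins = 4),
    "collapsed")
  expect_equal(nrow(one), 1)
  # deterministic given the seed
  cal2 <- calibration_curve(pred, t, e, 6, n_boot = 200, seed = 5)
  expect_identical(cal, cal2)
})

test_that("horizon classification metrics reproduce confusion arithmetic", {
  # perfect predictor
  t <- c(rep(2, 5), rep(10, 5)); e <- rep(1L, 10)
  pred <- c(rep(0, 5), rep(1, 5))
  perf <- horizon_classification_metrics(pred, 0.5, t, e, 6)
  expect_true(all(perf$metrics$estimate == 100))
  # constructed confusion: TP=9 FN=3 FP=42 TN=49 (positive = progression-free)
  tp <- 9; fn <- 3; fp <- 42; tn <- 49
  time2 <- c(rep(10, tp), rep(10, fn), rep(2, fp), rep(2, tn))
  ev2 <- rep(1L, length(time2))
  pred2 <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  m <- horizon_classification_metrics(pred2, 0.5, time2, ev2, 6)
  est <- setNames(m$metrics$estimate, m$metrics$metric)
  expect_equal(unname(est["sensitivity"]), 75.0)
  expect_equal(unname(est["specificity"]), 100 * 49 / 91, tolerance = 1e-10)
  expect_equal(m$confusion, c(TP = 9, FP = 42, FN = 3, TN = 49))
  # threshold 0 predicts everyone positive: specificity 0
  all_pos <- horizon_classification_metrics(rep(0.5, length(time2)), 0,
                                            time2, ev2, 6)
  spec0 <- all_pos$metrics[all_pos$metrics$metric == "specificity", ]
  expect_equal(spec0$estimate, 0)
  # censored-before-horizon subjects are excluded and counted
  t3 <- c(4, 10, 2); e3 <- c(0L, 1L, 1L)
  m3 <- horizon_classification_metrics(c(0.5, 0.9, 0.1), 0.5, t3, e3, 6)
  expect_equal(m3$n_excluded, 1)
})
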