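test_that("published worked examples score 5 (high) and -2 (low)", {
  high <- data.frame(ca199_responder = FALSE, rim_enhancement = 1,
                     fat_infiltration = 1, ecv_pct = 15.9)
  low <- data.frame(ca199_responder = TRUE, rim_enhancement = 0,
                    fat_infiltration = 0, ecv_pct = 23.7)
  sh <- total_score(high)
  sl <- total_score(low)
  expect_equal(sh$total, 5L)
  expect_equal(as.character(sh$risk_class), "high")
  expect_equal(sl$total, -2L)
  expect_equal(as.character(sl$risk_class), "low")
  # intermediate case: responder + rim present + ECV in reference bin
  mid <- total_score(data.frame(ca199_responder = TRUE, rim_enhancement = 1,
                                fat_infiltration = 0, ecv_pct = 17))
  expect_equal(mid$total, 1L)
  expect_equal(as.character(mid$risk_class), "low")
})

test_that("score range enumeration is exhaustive and matches interval arithmetic", {
  rng <- enumerate_score_range(default_score_table())
  expect_equal(rng$min, -2)
  expect_equal(rng$max, 5)
  expect_equal(rng$achievable, -2:5)
  expect_equal(rng$n_combinations, 24)   # 2 x 2 x 3 x 2 categories
  # interval arithmetic agrees with the brute force
  tab <- default_score_table()
  per_item <- lapply(tab$items, function(it) {
    if (it$type == "binary") c(it$points_true, it$points_false) else it$points
  })
  expect_equal(rng$min, sum(vapply(per_item, min, numeric(1))))
  expect_equal(rng$max, sum(vapply(per_item, max, numeric(1))))
  # single binary item
  one <- score_table(list(x = list(feature = "x", type = "binary",
                                   points_true = 1L, points_false = 0L)),
                     cutoff = 1L)
  expect_equal(enumerate_score_range(one)[c("min", "max")], list(min = 0, max = 1))
})

test_that("stratification boundary is inclusive for high risk and monotone", {
  expect_equal(as.character(stratify(2)), "high")
  expect_equal(as.character(stratify(1)), "low")
  expect_equal(as.character(stratify(-2)), "low")
  v <- stratify(-2:5)
  expect_true(!is.unsorted(as.integer(v)))  # non-decreasing in total
})

test_that("total_score is monotone in each feature and rejects bad input", {
  base <- data.frame(ca199_responder = TRUE, rim_enhancement = 0,
                     fat_infiltration = 0, ecv_pct = 25)
  worse <- list(
    transform(base, ca199_responder = FALSE),
    transform(base, rim_enhancement = 1),
    transform(base, fat_infiltration = 1),
    transform(base, ecv_pct = 10)
  )
  t0 <- total_score(base)$total
  for (w in worse) expect_gte(total_score(w)$total, t0)
  expect_error(total_score(data.frame(rim_enhancement = 1)), "missing scored feature")
  expect_error(total_score(transform(base, ecv_pct = NA_real_)), "missing")
})

test_that("Sullivan construction rounds scaled coefficients half away from zero", {
  bin <- function(beta, B) {
    sullivan_points(
      betas = c(f = beta),
      categories = list(f = data.frame(category = c("absent", "present"),
                                       value = c(0, 1), ref = c(TRUE, FALSE))),
      base_increment = B)
  }
  expect_equal(bin(log(2), log(2))$points, c(0L, 1L))
  expect_equal(bin(1.386, 0.693)$points, c(0L, 2L))
  # continuous feature with midpoint values 14 / 18 (ref) / 22
  ecv <- sullivan_points(
    betas = c(ecv = log(0.941)),
    categories = list(ecv = data.frame(category = c("<16", "16-20", ">=20"),
                                       value = c(14, 18, 22),
                                       ref = c(FALSE, TRUE, FALSE))),
    base_increment = 0.466)
  expect_equal(ecv$points, c(1L, 0L, -1L))
  expect_error(sullivan_points(c(f = 1), list(f = data.frame(
    category = "a", value = 0, ref = FALSE)), 1), "reference")
  expect_error(bin(1, 0), "positive")
})

test_that("score table JSON round trip preserves scoring behaviour", {
  tab <- default_score_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tab, path)
  back <- read_score_table(path)
  pts <- data.frame(ca199_responder = FALSE, rim_enhancement = 1,
                    fat_infiltration = 1, ecv_pct = 15.9)
  expect_equal(total_score(pts, back)$total, total_score(pts, tab)$total)
  expect_equal(back$cutoff, tab$cutoff)
  expect_error(score_table(tab$items, cutoff = 10L), "achievable")
})
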