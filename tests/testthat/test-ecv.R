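test_that("delta-HU map is voxel-wise PVP minus unenhanced", {
  n <- array(40, dim = c(4, 4, 2))
  p <- array(70, dim = c(4, 4, 2))
  pair <- phase_volume_pair(n, p)
  expect_true(all(compute_delta_hu(pair) == 30))
  expect_true(all(compute_delta_hu(phase_volume_pair(n, n)) == 0))
  expect_error(phase_volume_pair(n, array(70, dim = c(4, 4, 3))), "grid shape")
  expect_error(phase_volume_pair(n, array(NA_real_, dim = c(4, 4, 2))), "finite")
})

test_that("blood-pool enhancement summarises the aorta mask and must be positive", {
  delta <- array(0, dim = c(2, 2, 2))
  mask <- array(0L, dim = c(2, 2, 2))
  mask[1:2, 1, 1] <- 1L
  delta[1, 1, 1] <- 90; delta[2, 1, 1] <- 110
  expect_equal(blood_pool_delta(delta, mask), 100)
  delta[] <- 100
  expect_equal(blood_pool_delta(delta, mask), 100)
  expect_error(blood_pool_delta(array(0, dim = c(2, 2, 2)), mask), "positive")
  expect_error(blood_pool_delta(delta, array(0L, dim = c(2, 2, 2))), "empty")
})

test_that("ECV map applies the formula, flags out-of-range voxels, never clips", {
  delta <- array(c(30, 0, 150, -10), dim = c(4, 1, 1))
  map <- compute_ecv_map(delta, 100, 0.40)
  expect_equal(map$ecv[1, 1, 1], 18)
  expect_equal(map$ecv[2, 1, 1], 0)
  expect_equal(map$ecv[3, 1, 1], 90)
  expect_equal(map$ecv[4, 1, 1], -6)      # preserved, not clipped
  expect_equal(map$n_flagged, 1)
  expect_true(map$flags[4, 1, 1])
  expect_error(compute_ecv_map(delta, 0, 0.4), "positive")
  expect_error(compute_ecv_map(delta, 100, 1), "hematocrit")
  # percent hematocrit accepted with a warning
  expect_warning(m2 <- compute_ecv_map(delta, 100, 40), "percent")
  expect_equal(m2$ecv[1, 1, 1], 18)
})

test_that("ECV is invariant under common scaling and vanishes as hct -> 1", {
  ph <- noiseless_phantom()
  delta <- compute_delta_hu(ph$pair)
  da <- blood_pool_delta(delta, ph$aorta_mask)
  base <- compute_ecv_map(delta, da, 0.4)
  scaled <- compute_ecv_map(3 * delta, 3 * da, 0.4)
  expect_equal(scaled$ecv, base$ecv, tolerance = 1e-12)
  near1 <- compute_ecv_map(delta, da, 1 - 1e-9)
  expect_lt(max(abs(near1$ecv)), 1e-5)
})

test_that("noiseless phantom round trip recovers ground truth exactly", {
  ph <- noiseless_phantom()
  expect_equal(recover_voi_mean(ph), ph$truth$ecv_tumor, tolerance = 1e-9)
  # per-voxel recovery too
  delta <- compute_delta_hu(ph$pair)
  da <- blood_pool_delta(delta, ph$aorta_mask)
  map <- compute_ecv_map(delta, da, ph$spec$hematocrit)
  expect_equal(map$ecv[ph$tumor_mask > 0],
               ph$truth$ecv_map[ph$tumor_mask > 0], tolerance = 1e-9)
})

test_that("VOI mean is a plain arithmetic mean, order-invariant", {
  m <- array(0, dim = c(2, 2, 1)); m[1, 1, 1] <- 10; m[2, 1, 1] <- 20
  voi <- array(0L, dim = c(2, 2, 1)); voi[1:2, 1, 1] <- 1L
  map <- structure(list(ecv = m, delta_aorta = 100, hematocrit = 0.4,
                        flags = array(FALSE, dim = dim(m)), n_flagged = 0),
                   class = "ecv_map")
  expect_equal(mean_ecv_in_voi(map, voi), 15)
  expect_error(mean_ecv_in_voi(map, array(0L, dim = dim(m))), "empty")
})

test_that("reader averaging is the arithmetic mean with identity at one reader", {
  expect_equal(average_reader_values(c(18, 20)), 19)
  expect_equal(average_reader_values(15.9), 15.9)
  expect_equal(average_reader_values(c(15.9, 15.9)), 15.9)
  expect_error(average_reader_values(numeric(0)), "at least one")
})

test_that("Dice coefficient: identity, disjoint, symmetry, half overlap", {
  a <- array(0L, dim = c(4, 2, 1)); a[1:4, 1, 1] <- 1L
  b <- array(0L, dim = c(4, 2, 1)); b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)           # |A|=|B|=4, overlap 2
  expect_equal(dice(a, b), dice(b, a))
  disj <- array(0L, dim = c(4, 2, 1)); disj[1:4, 2, 1] <- 1L
  expect_equal(dice(a, disj), 0)
  empty <- array(0L, dim = c(4, 2, 1))
  expect_error(dice(empty, empty), "empty")
})

test_that("DSC agreement categories follow the reporting rule", {
  expect_equal(agreement_thresholds(0.84), "satisfactory")
  expect_equal(agreement_thresholds(0.80), "acceptable")   # strictly > 0.80
  expect_equal(agreement_thresholds(0.65), "acceptable")
  expect_equal(agreement_thresholds(0.49), "consensus-required")
  expect_error(agreement_thresholds(1.2), "\\[0, 1\\]")
})

test_that("NIfTI round trip preserves volumes, masks and the ECV sidecar", {
  ph <- noiseless_phantom()
  d <- withr::local_tempdir()
  un <- file.path(d, "unenh.nii.gz"); pv <- file.path(d, "pvp.nii.gz")
  tm <- file.path(d, "tumor.nii.gz")
  write_volume_nifti(ph$pair$unenhanced, un)
  write_volume_nifti(ph$pair$pvp, pv)
  write_volume_nifti(ph$tumor_mask, tm)
  pair <- read_phase_pair(un, pv)
  expect_equal(pair$pvp, ph$pair$pvp, tolerance = 1e-6, ignore_attr = TRUE)
  voi <- read_mask(tm)
  expect_equal(sum(voi), sum(ph$tumor_mask))
  delta <- compute_delta_hu(pair)
  map <- compute_ecv_map(delta, blood_pool_delta(delta, read_mask(tm) * 0 + ph$aorta_mask),
                         ph$spec$hematocrit)
  out <- file.path(d, "ecv.nii.gz")
  side <- write_ecv_nifti(map, out, voi = voi)
  expect_equal(side$voi_mean_ecv, 18, tolerance = 1e-6)
  expect_true(file.exists(paste0(out, ".json")))
})
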