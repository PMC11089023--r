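#' Paired unenhanced / portal-venous-phase CT volumes
#'
#' Container for the two aligned attenuation volumes the ECV computation
#' needs. The two phases must share grid shape and voxel spacing; alignment
#' (registration) is assumed to have happened upstream — this constructor
#' only refuses mismatched metadata.
#'
#' @param unenhanced,pvp 3-D numeric arrays of CT attenuation (HU) on the
#'   same grid.
#' @param spacing voxel spacing in mm per axis.
#' @return An object of class `phase_volume_pair`.
#' @export
phase_volume_pair <- function(unenhanced, pvp, spacing = c(1, 1, 1)) {
  if (!is.array(unenhanced) || !is.array(pvp)) abort("volumes must be arrays")
  if (!identical(dim(unenhanced), dim(pvp))) {
    abort("unenhanced and PVP volumes must share the same grid shape")
  }
  if (anyNA(unenhanced) || anyNA(pvp) ||
      !all(is.finite(unenhanced)) || !all(is.finite(pvp))) {
    abort("attenuation values must be finite")
  }
  if (length(spacing) != length(dim(unenhanced))) {
    abort("spacing must give one value per axis")
  }
  structure(list(unenhanced = unenhanced, pvp = pvp, spacing = spacing),
            class = "phase_volume_pair")
}

#' Voxel-wise enhancement between phases
#'
#' The enhancement map \eqn{\Delta HU} = PVP − unenhanced, the numerator (per
#' voxel) and, averaged over the aorta mask, the denominator of the ECV
#' formula.
#'
#' @param pair a [phase_volume_pair()].
#' @return 3-D numeric array of \eqn{\Delta HU}.
#' @export
compute_delta_hu <- function(pair) {
  stopifnot(inherits(pair, "phase_volume_pair"))
  pair$pvp - pair$unenhanced
}

#' Blood-pool enhancement scalar
#'
#' Summarises \eqn{\Delta HU} over the aorta mask. The blood pool must
#' enhance: a non-positive summary indicates a protocol or masking failure
#' and raises an error rather than propagating a sign flip into the ECV map.
#'
#' @param delta \eqn{\Delta HU} array from [compute_delta_hu()].
#' @param aorta_mask 0/1 array on the same grid with at least one positive voxel.
#' @param method `"mean"` (default) or `"median"` over the mask.
#' @return Scalar \eqn{\Delta HU_{aorta}} in HU.
#' @export
blood_pool_delta <- function(delta, aorta_mask, method = c("mean", "median")) {
  method <- match.arg(method)
  check_mask(aorta_mask, dim(delta))
  vals <- delta[aorta_mask > 0]
  out <- if (method == "mean") mean(vals) else stats::median(vals)
  if (!is.finite(out) || out <= 0) {
    abort("blood-pool enhancement must be positive; check phases and aorta mask")
  }
  out
}

#' Per-voxel extracellular volume fraction map
#'
#' Applies
#' \deqn{ECV = (1 - hct)\,\frac{\Delta HU_{tumor}}{\Delta HU_{aorta}} \times 100\%}
#' voxel by voxel. Values are deliberately not clipped: voxels outside
#' `[0, 100]` (noise, vessels, mask spill) are flagged so they can be audited,
#' never silently altered.
#'
#' @param delta \eqn{\Delta HU} array.
#' @param delta_aorta positive blood-pool enhancement scalar (HU).
#' @param hematocrit fraction in `[0, 1)`; `(1, 100]` accepted as percent with
#'   a warning.
#' @return An object of class `ecv_map`: list with `ecv` (percent, per voxel),
#'   `delta_aorta`, `hematocrit`, `flags` (logical array marking out-of-range
#'   voxels) and `n_flagged`.
#' @export
compute_ecv_map <- function(delta, delta_aorta, hematocrit) {
  if (!is.numeric(delta_aorta) || length(delta_aorta) != 1L || delta_aorta <= 0) {
    abort("delta_aorta must be a single positive number")
  }
  hematocrit <- normalize_hematocrit(hematocrit)
  ecv <- (1 - hematocrit) * (delta / delta_aorta) * 100
  flags <- ecv < 0 | ecv > 100
  structure(list(ecv = ecv, delta_aorta = delta_aorta,
                 hematocrit = hematocrit, flags = flags,
                 n_flagged = sum(flags)),
            class = "ecv_map")
}

#' Mean ECV inside a volume of interest
#'
#' @param map an `ecv_map` from [compute_ecv_map()].
#' @param voi 0/1 tumor mask on the same grid, non-empty.
#' @return Mean ECV (percent) over the VOI voxels.
#' @export
mean_ecv_in_voi <- function(map, voi) {
  stopifnot(inherits(map, "ecv_map"))
  check_mask(voi, dim(map$ecv))
  mean(map$ecv[voi > 0])
}

#' Average measurements across readers
#'
#' Readings (e.g. each radiologist's VOI-mean ECV) are combined by the
#' arithmetic mean before entering downstream analysis.
#'
#' @param values numeric vector, length at least 1.
#' @return Scalar mean.
#' @export
average_reader_values <- function(values) {
  if (length(values) < 1L || !is.numeric(values)) abort("need at least one reading")
  mean(values)
}

#' Dice similarity coefficient between two segmentations
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks,
#' 0 for disjoint masks. Undefined (error) when both masks are empty.
#'
#' @param a,b 0/1 arrays on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("masks must share the same grid")
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0L) abort("Dice undefined: both masks are empty")
  2 * sum(a > 0 & b > 0) / (na + nb)
}

#' Classify segmentation agreement from a Dice coefficient
#'
#' Overlap above 0.80 counts as satisfactory reproducibility; below 0.50 the
#' segmentations disagree enough that a consensus reading is required;
#' anything in between is acceptable.
#'
#' @param dsc scalar in `[0, 1]`.
#' @return One of `"satisfactory"`, `"acceptable"`, `"consensus-required"`.
#' @export
agreement_thresholds <- function(dsc) {
  if (!is.numeric(dsc) || length(dsc) != 1L || !is.finite(dsc) || dsc < 0 || dsc > 1) {
    abort("dsc must be a single value in [0, 1]")
  }
  if (dsc > 0.80) "satisfactory"
  else if (dsc < 0.50) "consensus-required"
  else "acceptable"
}

check_mask <- function(mask, dims) {
  if (!identical(dim(mask), dims)) abort("mask grid does not match volume grid")
  if (!any(mask > 0)) abort("mask is empty")
  invisible(TRUE)
}

#' Read a paired-phase study from NIfTI files
#'
#' @param unenhanced_path,pvp_path paths to NIfTI volumes on the same grid.
#' @return A [phase_volume_pair()].
#' @export
read_phase_pair <- function(unenhanced_path, pvp_path) {
  n <- RNifti::readNifti(unenhanced_path)
  p <- RNifti::readNifti(pvp_path)
  spacing <- RNifti::pixdim(n)
  phase_volume_pair(array(as.numeric(n), dim = dim(n)),
                    array(as.numeric(p), dim = dim(p)),
                    spacing = spacing)
}

#' Read a 0/1 mask from a NIfTI file
#' @param path NIfTI path; any non-zero voxel is treated as inside.
#' @return Integer 0/1 array.
#' @export
read_mask <- function(path) {
  m <- RNifti::readNifti(path)
  array(as.integer(as.numeric(m) != 0), dim = dim(m))
}

#' Write an ECV map (and JSON sidecar) to disk
#'
#' Writes the per-voxel ECV percent volume as NIfTI plus a JSON sidecar with
#' the blood-pool enhancement, hematocrit, flagged-voxel count and, when a
#' VOI is supplied, the VOI-mean ECV.
#'
#' @param map an `ecv_map`.
#' @param path output NIfTI path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param voi optional tumor mask for the sidecar's VOI-mean.
#' @param spacing voxel spacing in mm.
#' @return Invisibly, the sidecar list.
#' @export
write_ecv_nifti <- function(map, path, voi = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(map, "ecv_map"))
  img <- RNifti::asNifti(map$ecv, pixdim = spacing)
  RNifti::writeNifti(img, path)
  sidecar <- list(delta_hu_aorta = map$delta_aorta,
                  hematocrit = map$hematocrit,
                  n_flagged = map$n_flagged)
  if (!is.null(voi)) sidecar$voi_mean_ecv <- mean_ecv_in_voi(map, voi)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write a volume or mask as NIfTI
#' @param volume numeric or integer array.
#' @param path output path.
#' @param spacing voxel spacing in mm.
#' @export
write_volume_nifti <- function(volume, path, spacing = c(1, 1, 1)) {
  RNifti::writeNifti(RNifti::asNifti(volume, pixdim = spacing), path)
  invisible(path)
}
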