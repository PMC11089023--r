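#' Specify a CT phantom with known ground-truth ECV
#'
#' Describes a synthetic paired-phase CT volume: a homogeneous background, a
#' spherical "tumor" and a cylindrical "aorta" (axis along the third
#' dimension), each enhancing by a fixed Hounsfield-unit increment between the
#' unenhanced and portal-venous phases. Because the enhancements are known,
#' the extracellular volume fraction
#' \eqn{ECV = (1 - hct)\,(\Delta HU_{tumor}/\Delta HU_{aorta}) \times 100}
#' is known analytically in every voxel, which makes the phantom an exact
#' oracle for the imaging pipeline.
#'
#' @param shape integer vector of length 3, grid size in voxels.
#' @param tumor_center,tumor_radius sphere geometry, voxel units.
#' @param aorta_center,aorta_radius cylinder geometry (center/radius in the
#'   first two dimensions; the cylinder spans the full third axis), voxel units.
#' @param background_hu background attenuation in HU.
#' @param delta_hu_tumor,delta_hu_aorta enhancement increments in HU;
#'   `delta_hu_aorta` must be positive (blood pool must enhance).
#' @param hematocrit fraction in `[0, 1)`; values in `(1, 100]` are read as
#'   percent with a warning.
#' @param noise_sd standard deviation of additive Gaussian noise (HU) applied
#'   to the portal-venous phase; 0 gives a noiseless phantom.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param spacing voxel spacing in mm per axis.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(32L, 32L, 16L),
                         tumor_center = c(10, 16, 8), tumor_radius = 5,
                         aorta_center = c(24, 16), aorta_radius = 4,
                         background_hu = 40,
                         delta_hu_tumor = 30, delta_hu_aorta = 100,
                         hematocrit = 0.40,
                         noise_sd = 0, seed = 1L,
                         spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort("shape must be 3 positive integers")
  if (delta_hu_aorta <= 0) abort("delta_hu_aorta must be positive")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  hematocrit <- normalize_hematocrit(hematocrit)
  spec <- structure(list(
    shape = shape,
    tumor_center = tumor_center, tumor_radius = tumor_radius,
    aorta_center = aorta_center, aorta_radius = aorta_radius,
    background_hu = background_hu,
    delta_hu_tumor = delta_hu_tumor, delta_hu_aorta = delta_hu_aorta,
    hematocrit = hematocrit, noise_sd = noise_sd, seed = seed,
    spacing = spacing
  ), class = "phantom_spec")
  masks <- phantom_masks(spec)
  if (any(masks$tumor & masks$aorta)) abort("tumor and aorta regions overlap")
  if (!any(masks$tumor) || !any(masks$aorta)) {
    abort("tumor and aorta regions must each contain at least one voxel inside the grid")
  }
  spec
}

# Region masks implied by a phantom_spec (sphere + full-height cylinder).
phantom_masks <- function(spec) {
  d <- spec$shape
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  tum <- (ix - spec$tumor_center[1])^2 + (iy - spec$tumor_center[2])^2 +
    (iz - spec$tumor_center[3])^2 <= spec$tumor_radius^2
  aor <- (ix - spec$aorta_center[1])^2 + (iy - spec$aorta_center[2])^2 <=
    spec$aorta_radius^2
  list(tumor = tum, aorta = aor)
}

#' Generate a paired-phase CT phantom with analytic ground truth
#'
#' Builds the unenhanced volume (uniform background), the portal-venous-phase
#' volume (background plus per-region enhancement plus optional Gaussian
#' noise), the tumor and aorta masks, and the analytically known per-voxel ECV
#' map. With `noise_sd = 0` the imaging module recovers the ground truth
#' exactly.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pair` (a [phase_volume_pair()]),
#'   `tumor_mask`, `aorta_mask` (0/1 integer arrays), `truth` (list with
#'   per-voxel `ecv_map`, scalar `ecv_tumor`, `ecv_blood`) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' ph$truth$ecv_tumor  # (1 - 0.40) * (30 / 100) * 100 = 18
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set_seed_if_given(spec$seed)
  masks <- phantom_masks(spec)
  unenh <- array(spec$background_hu, dim = spec$shape)
  pvp <- unenh
  pvp[masks$tumor] <- pvp[masks$tumor] + spec$delta_hu_tumor
  pvp[masks$aorta] <- pvp[masks$aorta] + spec$delta_hu_aorta
  if (spec$noise_sd > 0) {
    pvp <- pvp + array(stats::rnorm(prod(spec$shape), 0, spec$noise_sd),
                       dim = spec$shape)
  }
  ecv_tumor <- (1 - spec$hematocrit) * (spec$delta_hu_tumor / spec$delta_hu_aorta) * 100
  ecv_blood <- (1 - spec$hematocrit) * 100
  truth_map <- array(0, dim = spec$shape)
  truth_map[masks$tumor] <- ecv_tumor
  truth_map[masks$aorta] <- ecv_blood
  list(
    pair = phase_volume_pair(unenh, pvp, spacing = spec$spacing),
    tumor_mask = array(as.integer(masks$tumor), dim = spec$shape),
    aorta_mask = array(as.integer(masks$aorta), dim = spec$shape),
    truth = list(ecv_map = truth_map, ecv_tumor = ecv_tumor, ecv_blood = ecv_blood),
    spec = spec
  )
}

#' Translate a volume by whole voxels
#'
#' Rigid integer-voxel translation, padding vacated voxels with a fill value.
#' Intended as a misregistration perturbation for sensitivity analyses: the
#' ECV formula assumes the two phases are voxel-aligned, and shifting one
#' phase quantifies how phase mismatch corrupts the recovered ECV.
#'
#' @param volume 3-D numeric array.
#' @param shift integer vector of length 3, voxel offsets per axis (positive
#'   shifts move content toward higher indices).
#' @param fill pad value for vacated voxels (typically the background HU).
#' @return The shifted array; `shift = c(0, 0, 0)` is the identity.
#' @export
apply_misregistration <- function(volume, shift, fill = 0) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  shift <- as.integer(shift)
  if (length(shift) != 3L) abort("shift must have one offset per axis")
  d <- dim(volume)
  if (any(abs(shift) >= d)) abort("shift exceeds grid extent")
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s)
      dst[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      src[[ax]] <- seq_len(d[ax] + s) - s
      dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- volume[src[[1]], src[[2]], src[[3]]]
  out
}
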