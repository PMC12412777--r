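#' Patch sampling and augmentation specification
#'
#' Describes how training patches are drawn and augmented: patch shape in
#' voxels, the Gaussian spread of the patch centre around the PTV centre of
#' mass (per-axis, voxels), and independent probabilities of applying one
#' in-plane axis flip and one in-plane rotation restricted to
#' 90/180/270 degrees. `angle_mode = "conditional"` reads the 50% rotation
#' probability as P(apply a non-identity rotation) with the angle uniform
#' over `rotation_angles`; `"uniform"` instead draws uniformly over
#' {0, 90, 180, 270} whenever a rotation is triggered.
#'
#' @param patch_shape Integer length-3, voxels (default 96 x 96 x 64).
#' @param translation_sigma Numeric length-3, voxels (default 5).
#' @param flip_prob,rotation_prob Probabilities in `[0, 1]`.
#' @param rotation_angles Subset of `c(90, 180, 270)` degrees.
#' @param angle_mode `"conditional"` (default) or `"uniform"`.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(patch_shape = c(96, 96, 64),
                       translation_sigma = c(5, 5, 5),
                       flip_prob = 0.5, rotation_prob = 0.5,
                       rotation_angles = c(90, 180, 270),
                       angle_mode = c("conditional", "uniform")) {
  angle_mode <- match.arg(angle_mode)
  patch_shape <- as.integer(rep_len(patch_shape, 3L))
  if (any(patch_shape <= 0)) fail_validation("patch_shape must be positive")
  if (flip_prob < 0 || flip_prob > 1 || rotation_prob < 0 || rotation_prob > 1) {
    fail_validation("probabilities must lie in [0, 1]")
  }
  if (!all(rotation_angles %in% c(90, 180, 270))) {
    fail_validation("rotation_angles must be a subset of {90, 180, 270}")
  }
  structure(
    list(
      patch_shape = patch_shape,
      translation_sigma = rep_len(as.numeric(translation_sigma), 3L),
      flip_prob = flip_prob, rotation_prob = rotation_prob,
      rotation_angles = rotation_angles, angle_mode = angle_mode
    ),
    class = "patch_spec"
  )
}

#' Draw a patch centre near the PTV centre of mass
#'
#' Samples the patch centre from a Gaussian centred on the centre of mass of
#' the PTV prescription map (per-axis `translation_sigma`, in voxels), then
#' clamps it so the patch fits inside the volume where possible (volumes
#' smaller than the patch fall back to the volume centre and are zero-padded
#' at extraction). Uses R's global RNG; seed the stream for determinism.
#'
#' @param ptv_map 3D array with positive values inside the PTV.
#' @param spec A [patch_spec()].
#' @return Integer length-3 voxel index of the patch centre.
#' @export
sample_patch_center <- function(ptv_map, spec = patch_spec()) {
  d <- vol_dim(ptv_map)
  idx <- which(ptv_map > 0, arr.ind = TRUE)
  if (!nrow(idx)) fail_validation("sample_patch_center: empty PTV map")
  com <- colMeans(idx)
  center <- round(com + rnorm(3) * spec$translation_sigma)
  p <- spec$patch_shape
  half_lo <- p %/% 2L
  lo_min <- 1L + half_lo
  lo_max <- d - p + 1L + half_lo  # keeps the patch start in [1, d - p + 1]
  for (ax in 1:3) {
    if (d[ax] <= p[ax]) center[ax] <- ceiling(d[ax] / 2)
    else center[ax] <- clamp(center[ax], lo_min[ax], lo_max[ax])
  }
  as.integer(center)
}

#' Extract a (zero-padded) patch around a centre
#'
#' Crops a `spec$patch_shape` patch centred at `center` from a 4D
#' channel-last array (or 3D volume), zero-padding symmetrically where the
#' volume is smaller than the patch.
#'
#' @param x 3D volume or 4D (x, y, z, channel) array.
#' @param center Integer length-3 voxel index.
#' @param patch_shape Integer length-3.
#' @return Array with spatial dims `patch_shape` (channels preserved).
#' @export
extract_patch <- function(x, center, patch_shape) {
  was3d <- length(dim(x)) == 3L
  if (was3d) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  p <- as.integer(rep_len(patch_shape, 3L))
  start <- as.integer(center) - p %/% 2L  # 1-based corner; may be <= 0
  out <- .crop_patch_cpp(x, d, start - 1L, p)
  if (was3d) dim(out) <- p
  out
}

#' Geometric patch transforms
#'
#' Pure in-plane permutations of voxels used by the augmentation: an axis
#' flip along x or y, and a rotation by `k * 90` degrees in the axial (x, y)
#' plane. 90/270-degree rotations require a square in-plane patch.
#'
#' @param x 3D or 4D (channel-last) array.
#' @param axis Flip axis, 1 (x) or 2 (y).
#' @param k Number of 90-degree rotations (1, 2 or 3).
#' @return Transformed array of the same shape (transposed in-plane for odd `k`).
#' @export
patch_flip <- function(x, axis) {
  stopifnot(axis %in% 1:2)
  was3d <- length(dim(x)) == 3L
  if (was3d) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  out <- .flip4d_cpp(x, d, axis)
  if (was3d) dim(out) <- d[1:3]
  out
}

#' @rdname patch_flip
#' @export
patch_rotate <- function(x, k) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(x)
  was3d <- length(dim(x)) == 3L
  if (was3d) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (k %% 2L == 1L && d[1] != d[2]) {
    fail_validation("90/270-degree rotation requires a square in-plane patch")
  }
  out <- .rot90_cpp(x, d, k)
  if (was3d) dim(out) <- d[1:3]
  out
}

#' Jointly augment input channels and target
#'
#' Applies the drawn geometric transform — with probability `flip_prob` one
#' axis flip (axis uniform over x/y), and independently with probability
#' `rotation_prob` one in-plane rotation — identically to every input channel
#' and to the target, so their registration is preserved. Transforms are pure
#' voxel permutations: no values are created or destroyed.
#'
#' @param input 4D (x, y, z, channel) array (the patch of network inputs).
#' @param target 3D array (dose patch) sharing the spatial shape.
#' @param spec A [patch_spec()].
#' @return List with `input`, `target` and `transform` (the drawn flip axis
#'   and rotation, `NA` where not applied).
#' @export
augment_patch <- function(input, target, spec = patch_spec()) {
  if (!identical(dim(input)[1:3], vol_dim(target))) {
    fail_validation("augment_patch: input and target spatial shapes differ")
  }
  tr <- draw_patch_transform(spec)
  list(input = apply_patch_transform(input, tr),
       target = apply_patch_transform(target, tr),
       transform = tr)
}

# Draw one joint geometric transform from the augmentation distribution.
draw_patch_transform <- function(spec) {
  flip_axis <- NA_integer_
  rot_k <- NA_integer_
  if (runif(1) < spec$flip_prob) flip_axis <- sample(1:2, 1)
  if (runif(1) < spec$rotation_prob) {
    angles <- if (spec$angle_mode == "uniform") c(0, spec$rotation_angles) else spec$rotation_angles
    rot_k <- sample(angles, 1) / 90
  }
  list(flip_axis = flip_axis, rotation_k = rot_k)
}

apply_patch_transform <- function(x, tr) {
  if (!is.na(tr$flip_axis)) x <- patch_flip(x, tr$flip_axis)
  if (!is.na(tr$rotation_k) && tr$rotation_k > 0) x <- patch_rotate(x, tr$rotation_k)
  x
}
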