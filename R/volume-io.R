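#' Construct a validated treatment-session container
#'
#' A plan session bundles everything one treatment session contributes: the CT
#' volume (HU), the named binary OAR masks, the merged PTV prescription map
#' (Gy per voxel), optionally the planned dose (Gy), and the voxel spacing in
#' mm. All volumes must live on one grid; mask names must belong to the
#' canonical roster ([oar_roster()]). Roster structures that were never
#' contoured are simply absent from `oar_masks` — they are materialized as
#' zero channels only at assembly time, so absence stays distinguishable from
#' an empty contour.
#'
#' @param ct 3D numeric array, CT in Hounsfield units.
#' @param oar_masks Named list of 3D binary arrays (values 0/1).
#' @param ptv_map 3D numeric array, per-voxel prescription level in Gy
#'   (0 outside all PTVs); see [merge_ptvs()].
#' @param spacing Numeric length-3, voxel spacing in mm (x, y, z).
#' @param session_kind `"pretreatment"` or `"adaptive"`.
#' @param dose Optional 3D numeric array, planned dose in Gy.
#' @param patient_id Character identifier.
#' @return An object of class `plan_session`.
#' @export
plan_session <- function(ct, oar_masks, ptv_map, spacing,
                         session_kind = c("adaptive", "pretreatment"),
                         dose = NULL, patient_id = "P000") {
  session_kind <- match.arg(session_kind)
  s <- structure(
    list(
      ct = ct, oar_masks = oar_masks, ptv_map = ptv_map, dose = dose,
      spacing = as.numeric(spacing), session_kind = session_kind,
      patient_id = patient_id
    ),
    class = "plan_session"
  )
  validate_session(s)
  s
}

#' Validate plan-session invariants
#'
#' Checks the container invariants: shared grid and spacing across all
#' volumes, binary masks, non-negative PTV map and dose, and roster-member
#' structure names. Errors name the offending volume.
#'
#' @param s A `plan_session`.
#' @return `s`, invisibly, if valid.
#' @export
validate_session <- function(s) {
  d <- vol_dim(s$ct)
  if (length(s$spacing) != 3L || any(!is.finite(s$spacing)) || any(s$spacing <= 0)) {
    fail_validation("spacing must be 3 positive finite values (mm)")
  }
  if (!identical(vol_dim(s$ptv_map), d)) fail_validation("ptv_map: shape differs from ct")
  if (any(s$ptv_map < 0)) fail_validation("ptv_map: negative prescription values")
  if (!is.null(s$dose)) {
    if (!identical(vol_dim(s$dose), d)) fail_validation("dose: shape differs from ct")
    if (any(s$dose < 0)) fail_validation("dose: negative values")
  }
  if (length(s$oar_masks)) {
    if (is.null(names(s$oar_masks)) || any(!nzchar(names(s$oar_masks)))) {
      fail_validation("oar_masks must be a named list")
    }
    roster_index(names(s$oar_masks))
    for (nm in names(s$oar_masks)) {
      m <- s$oar_masks[[nm]]
      if (!identical(vol_dim(m), d)) {
        fail_validation(paste0("mask '", nm, "': shape differs from ct"))
      }
      if (!is_binary(m)) fail_validation(paste0("mask '", nm, "': values outside {0, 1}"))
    }
  }
  if (!s$session_kind %in% c("pretreatment", "adaptive")) {
    fail_validation("session_kind must be 'pretreatment' or 'adaptive'")
  }
  invisible(s)
}

#' @export
print.plan_session <- function(x, ...) {
  d <- dim(x$ct)
  cat(sprintf(
    "<plan_session> %s [%s]  grid %dx%dx%d @ %s mm  %d structure(s)%s\n",
    x$patient_id, x$session_kind, d[1], d[2], d[3],
    paste(x$spacing, collapse = "x"), length(x$oar_masks),
    if (is.null(x$dose)) "" else "  + dose"
  ))
  invisible(x)
}

write_volume_nifti <- function(arr, spacing, file, datatype) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, file, datatype = datatype)
}

#' Write a plan session as a NIfTI bundle
#'
#' Persists the session as a directory of `.nii.gz` volumes plus a
#' `manifest.json` naming each structure file, the spacing, the session kind
#' and the patient id. Scalar volumes are stored as float64 so a save/load
#' round trip is bit-exact; masks are stored as uint8.
#'
#' @param s A `plan_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_session <- function(s, path) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(s$ct, s$spacing, file.path(path, "ct.nii.gz"), "double")
  write_volume_nifti(s$ptv_map, s$spacing, file.path(path, "ptv.nii.gz"), "double")
  if (!is.null(s$dose)) {
    write_volume_nifti(s$dose, s$spacing, file.path(path, "dose.nii.gz"), "double")
  }
  structures <- names(s$oar_masks)
  files <- character(0)
  for (nm in structures) {
    f <- paste0("mask_", nm, ".nii.gz")
    write_volume_nifti(s$oar_masks[[nm]], s$spacing, file.path(path, f), "uint8")
    files <- c(files, f)
  }
  manifest <- list(
    patient_id = s$patient_id,
    session_kind = s$session_kind,
    spacing = s$spacing,
    shape = dim(s$ct),
    has_dose = !is.null(s$dose),
    structures = as.list(stats::setNames(files, structures))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_volume_nifti <- function(file) {
  im <- RNifti::readNifti(file)
  array(as.double(im), dim = dim(im)[1:3])  # strip NIfTI attributes
}

#' Read a plan session bundle
#'
#' Reads either a directory written by [save_session()] (NIfTI volumes plus
#' JSON manifest) or a single `.rds` bundle written by [save_session_bundle()].
#' The loaded session is re-validated; unknown structure names or malformed
#' volumes raise a validation error naming the offender.
#'
#' @param path Bundle directory or `.rds` file.
#' @return A `plan_session`.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.rds$", path)) return(load_session_bundle(path))
    fail_validation(paste0("no session bundle at ", path))
  }
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) fail_validation("malformed bundle: manifest.json missing")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  masks <- list()
  for (nm in names(manifest$structures)) {
    masks[[nm]] <- read_volume_nifti(file.path(path, manifest$structures[[nm]]))
  }
  dose <- NULL
  if (isTRUE(manifest$has_dose)) dose <- read_volume_nifti(file.path(path, "dose.nii.gz"))
  plan_session(
    ct = read_volume_nifti(file.path(path, "ct.nii.gz")),
    oar_masks = masks,
    ptv_map = read_volume_nifti(file.path(path, "ptv.nii.gz")),
    spacing = as.numeric(manifest$spacing),
    session_kind = manifest$session_kind,
    dose = dose,
    patient_id = manifest$patient_id
  )
}

#' Single-file session bundles
#'
#' Alternative to the NIfTI-directory layout: the whole session in one
#' serialized `.rds` file. `adaptdose convert` switches between the layouts.
#'
#' @param s A `plan_session`.
#' @param file Path ending in `.rds`.
#' @return `file` (save) or a `plan_session` (load).
#' @export
save_session_bundle <- function(s, file) {
  validate_session(s)
  saveRDS(s, file)
  invisible(file)
}

#' @rdname save_session_bundle
#' @export
load_session_bundle <- function(file) {
  s <- readRDS(file)
  if (!inherits(s, "plan_session")) fail_validation("file is not a plan_session bundle")
  validate_session(s)
  s
}

# ---- resampling ---------------------------------------------------------

# Per-axis interpolation matrix from an input axis (n_in samples, spacing
# s_in, voxel centers at (i-1)*s_in) to an output axis (n_out, s_out).
# mode "linear" gives rows with two weights; "nearest" one-hot rows.
axis_resample_matrix <- function(n_in, s_in, n_out, s_out, mode) {
  pos <- ((seq_len(n_out) - 1) * s_out) / s_in + 1  # continuous input index
  pos <- clamp(pos, 1, n_in)
  A <- matrix(0, n_out, n_in)
  if (mode == "nearest") {
    A[cbind(seq_len(n_out), round(pos))] <- 1
  } else {
    lo <- pmin(floor(pos), n_in - ifelse(n_in > 1, 1, 0))
    w <- pos - lo
    if (n_in == 1) { lo <- rep(1, n_out); w <- rep(0, n_out) }
    for (i in seq_len(n_out)) {
      A[i, lo[i]] <- A[i, lo[i]] + (1 - w[i])
      if (w[i] > 0) A[i, lo[i] + 1] <- A[i, lo[i] + 1] + w[i]
    }
  }
  A
}

# Apply a per-axis matrix along the given axis of a 3D array.
apply_axis_matrix <- function(x, A, axis) {
  if (axis != 1) {
    perm <- switch(axis, NULL, c(2, 1, 3), c(3, 2, 1))
    x <- aperm(x, perm)
  }
  d <- dim(x)
  out <- A %*% matrix(x, d[1], d[2] * d[3])
  dim(out) <- c(nrow(A), d[2], d[3])
  if (axis != 1) out <- aperm(out, switch(axis, NULL, c(2, 1, 3), c(3, 2, 1)))
  out
}

resample_volume <- function(x, spacing, target_spacing, mode) {
  d <- vol_dim(x)
  out_d <- as.integer(ceiling(d * spacing / target_spacing))
  for (ax in 1:3) {
    A <- axis_resample_matrix(d[ax], spacing[ax], out_d[ax], target_spacing[ax], mode)
    x <- apply_axis_matrix(x, A, ax)
  }
  x
}

#' Resample a session to a new voxel grid
#'
#' Brings every volume of the session to `target_spacing` (mm). The output
#' grid has shape `ceiling(shape * spacing / target_spacing)`; voxel centers
#' sit at `(index - 1) * spacing` mm, shared across input and output. Masks
#' and the PTV prescription map use nearest-neighbour interpolation (labels
#' and prescription levels are categorical), CT and dose use trilinear
#' interpolation. Resampling is deterministic.
#'
#' @param s A `plan_session`.
#' @param target_spacing Numeric length-3 (or scalar, recycled), mm.
#' @return A resampled `plan_session`.
#' @export
resample_session <- function(s, target_spacing) {
  validate_session(s)
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    fail_validation("target_spacing must be positive")
  }
  if (isTRUE(all.equal(target_spacing, s$spacing))) return(s)
  masks <- lapply(s$oar_masks, resample_volume,
                  spacing = s$spacing, target_spacing = target_spacing, mode = "nearest")
  dose <- if (is.null(s$dose)) NULL else {
    resample_volume(s$dose, s$spacing, target_spacing, "linear")
  }
  plan_session(
    ct = resample_volume(s$ct, s$spacing, target_spacing, "linear"),
    oar_masks = masks,
    ptv_map = resample_volume(s$ptv_map, s$spacing, target_spacing, "nearest"),
    spacing = target_spacing,
    session_kind = s$session_kind,
    dose = dose,
    patient_id = s$patient_id
  )
}

#' Link a pre-treatment and an adaptive session for one patient
#'
#' @param pre `plan_session` with `session_kind = "pretreatment"`; must carry
#'   its approved dose (the conditioning signal).
#' @param adaptive `plan_session` with `session_kind = "adaptive"`; must carry
#'   dose when used as ground truth (`require_adaptive_dose`).
#' @param require_adaptive_dose Require the adaptive dose to be present.
#' @return An object of class `plan_pair`.
#' @export
plan_pair <- function(pre, adaptive, require_adaptive_dose = TRUE) {
  if (pre$session_kind != "pretreatment") fail_validation("pre: session_kind must be 'pretreatment'")
  if (adaptive$session_kind != "adaptive") fail_validation("adaptive: session_kind must be 'adaptive'")
  if (is.null(pre$dose)) fail_validation("pre: dose is required for a plan pair")
  if (require_adaptive_dose && is.null(adaptive$dose)) {
    fail_validation("adaptive: dose required when used as ground truth")
  }
  if (!identical(dim(pre$ct), dim(adaptive$ct)) ||
      !isTRUE(all.equal(pre$spacing, adaptive$spacing))) {
    fail_validation("pre and adaptive sessions must share one resampled grid")
  }
  if (!identical(pre$patient_id, adaptive$patient_id)) {
    fail_validation("pre and adaptive sessions must share patient_id")
  }
  structure(list(pre = pre, adaptive = adaptive, patient_id = pre$patient_id),
            class = "plan_pair")
}

#' @export
print.plan_pair <- function(x, ...) {
  cat(sprintf("<plan_pair> %s\n", x$patient_id))
  print(x$pre); print(x$adaptive)
  invisible(x)
}
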