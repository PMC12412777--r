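#' Merge PTV contours into one prescription map
#'
#' Collapses the (possibly overlapping, e.g. nested boost) planning target
#' volumes into a single scalar map in Gy: each voxel takes the highest
#' prescription among the PTVs covering it, and 0 where no PTV covers it.
#'
#' @param ptv_masks List of 3D binary arrays, one per PTV.
#' @param prescriptions Numeric vector of prescription doses (Gy), one per mask.
#' @return 3D numeric array in Gy.
#' @examples
#' m <- array(1, c(2, 2, 2))
#' merge_ptvs(list(m, m), c(54, 70))[1, 1, 1] # 70
#' @export
merge_ptvs <- function(ptv_masks, prescriptions) {
  if (!length(ptv_masks)) fail_validation("merge_ptvs: empty PTV list")
  if (length(prescriptions) != length(ptv_masks)) {
    fail_validation("merge_ptvs: one prescription per mask required")
  }
  if (any(prescriptions <= 0)) fail_validation("merge_ptvs: prescriptions must be > 0")
  d <- vol_dim(ptv_masks[[1]])
  out <- array(0, d)
  for (i in seq_along(ptv_masks)) {
    m <- ptv_masks[[i]]
    if (!identical(vol_dim(m), d)) fail_validation("merge_ptvs: mismatched grids")
    if (!is_binary(m)) fail_validation("merge_ptvs: masks must be binary")
    out <- pmax(out, m * prescriptions[i])
  }
  out
}

#' Distance-map specification
#'
#' Controls how structure distance maps are computed. In `surface` mode the
#' map is `exp(-d / tau)` with `d` the exact Euclidean distance (mm) to the
#' nearest in-structure voxel, so voxels inside the structure are exactly 1.0
#' and values decay toward 0 with distance. In `isocenter` mode `d` is
#' measured to the structure's centre of mass and the map is clamped to 1.0
#' inside the structure.
#'
#' @param mode `"surface"` (default) or `"isocenter"`.
#' @param tau Decay scale in mm (> 0); the map falls to `exp(-1)` at `tau` mm.
#' @return An object of class `distance_map_spec`.
#' @export
distance_map_spec <- function(mode = c("surface", "isocenter"), tau = 50) {
  mode <- match.arg(mode)
  if (!is.finite(tau) || tau <= 0) fail_validation("tau must be > 0")
  structure(list(mode = mode, tau = tau), class = "distance_map_spec")
}

#' Exact Euclidean distance (mm) to the nearest in-structure voxel
#'
#' Anisotropic 3D distance transform (separable lower-envelope algorithm).
#' Inside voxels get 0. An empty mask returns all-`Inf`.
#'
#' @param mask 3D binary array.
#' @param spacing Voxel spacing in mm (length 3 or scalar).
#' @return 3D numeric array of distances in mm.
#' @export
euclidean_distance_mm <- function(mask, spacing) {
  d <- vol_dim(mask)
  spacing <- rep_len(as.numeric(spacing), 3L)
  out <- .edt_squared_mm(as.numeric(mask), as.integer(d), spacing)
  dim(out) <- d
  sqrt(out)
}

#' Normalized structure distance map
#'
#' Produces the per-structure distance channel in `[0, 1]`: 1.0 on voxels
#' inside the structure, decaying toward 0 with distance (see
#' [distance_map_spec()]). An empty mask yields an all-zero map, the
#' convention used for absent roster structures.
#'
#' @param mask 3D binary array.
#' @param spec A [distance_map_spec()].
#' @param spacing Voxel spacing in mm.
#' @return 3D numeric array in `[0, 1]`.
#' @export
structure_distance_map <- function(mask, spec = distance_map_spec(), spacing = c(5, 5, 5)) {
  if (!is_binary(mask)) fail_validation("structure_distance_map: mask must be binary")
  if (!inherits(spec, "distance_map_spec")) fail_validation("spec must be a distance_map_spec")
  if (sum(mask) == 0) return(array(0, vol_dim(mask)))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (spec$mode == "surface") {
    d <- euclidean_distance_mm(mask, spacing)
    return(exp(-d / spec$tau))
  }
  # isocenter mode: distance to the structure's center of mass (mm)
  dims <- vol_dim(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  com <- colMeans(idx)
  ax <- ((seq_len(dims[1]) - com[1]) * spacing[1])^2
  ay <- ((seq_len(dims[2]) - com[2]) * spacing[2])^2
  az <- ((seq_len(dims[3]) - com[3]) * spacing[3])^2
  d <- sqrt(outer(outer(ax, ay, "+"), az, "+"))
  out <- exp(-d / spec$tau)
  out[mask == 1] <- 1
  out
}

#' Assemble the multi-channel network input for one session
#'
#' Builds the fixed-order channel stack the networks consume. The manifest
#' order is: 44 OAR masks (roster order), 44 OAR distance maps (roster
#' order), the merged PTV prescription map, the CT, and — for the secondary
#' (pre-treatment) head only — the planned dose. Roster structures absent
#' from the session become all-zero mask and distance-map channels, so the
#' primary head always sees exactly 90 channels and the secondary head 91.
#' CT is affinely rescaled as `(HU + 1000) / 2000` clipped to `[0, 1]`; the
#' PTV map and dose are divided by `dose_norm` Gy.
#'
#' @param s A `plan_session`, already resampled to the working grid.
#' @param head `"primary"` (adaptive anatomy, 90 channels) or `"secondary"`
#'   (pre-treatment plan including dose, 91 channels).
#' @param spec A [distance_map_spec()].
#' @param dose_norm Normalization constant in Gy (cohort maximum
#'   prescription; default 72).
#' @param roster Structure roster (fixed; exposed for inspection only).
#' @return An object of class `channel_assembly`: list with `tensor`
#'   (4D array, x-y-z-channel), `manifest` (channel labels), `head`,
#'   `spacing`, `dose_norm` and session identifiers.
#' @export
assemble_channels <- function(s, head = c("primary", "secondary"),
                              spec = distance_map_spec(), dose_norm = 72,
                              roster = oar_roster()) {
  head <- match.arg(head)
  validate_session(s)
  if (head == "secondary" && is.null(s$dose)) {
    fail_validation("secondary head requires the session dose")
  }
  d <- dim(s$ct)
  n_ch <- 2L * length(roster) + 2L + (head == "secondary")
  tensor <- array(0, c(d, n_ch))
  manifest <- character(n_ch)
  zero <- array(0, d)
  for (i in seq_along(roster)) {
    nm <- roster[i]
    m <- s$oar_masks[[nm]]
    manifest[i] <- paste0("mask_", nm)
    manifest[length(roster) + i] <- paste0("dmap_", nm)
    if (!is.null(m)) {
      tensor[, , , i] <- m
      tensor[, , , length(roster) + i] <- structure_distance_map(m, spec, s$spacing)
    }
  }
  k <- 2L * length(roster)
  tensor[, , , k + 1L] <- s$ptv_map / dose_norm
  manifest[k + 1L] <- "ptv"
  tensor[, , , k + 2L] <- clamp((s$ct + 1000) / 2000, 0, 1)
  manifest[k + 2L] <- "ct"
  if (head == "secondary") {
    tensor[, , , k + 3L] <- s$dose / dose_norm
    manifest[k + 3L] <- "dose"
  }
  structure(
    list(
      tensor = tensor, manifest = manifest, head = head,
      spacing = s$spacing, dose_norm = dose_norm,
      patient_id = s$patient_id, session_kind = s$session_kind
    ),
    class = "channel_assembly"
  )
}

#' @export
print.channel_assembly <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<channel_assembly> %s head, %d channels, grid %dx%dx%d (%s, %s)\n",
              x$head, d[4], d[1], d[2], d[3], x$patient_id, x$session_kind))
  invisible(x)
}

#' Persist a channel assembly
#'
#' Assemblies are written as a single serialized bundle embedding the tensor
#' and its channel manifest.
#'
#' @param a A `channel_assembly`.
#' @param file Path ending in `.rds`.
#' @return `file` (save) or a `channel_assembly` (load).
#' @export
save_assembly <- function(a, file) {
  stopifnot(inherits(a, "channel_assembly"))
  saveRDS(a, file)
  invisible(file)
}

#' @rdname save_assembly
#' @export
load_assembly <- function(file) {
  a <- readRDS(file)
  if (!inherits(a, "channel_assembly")) fail_validation("not a channel_assembly bundle")
  a
}
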