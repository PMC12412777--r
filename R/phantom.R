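#' Phantom cohort configuration
#'
#' Parameters of the synthetic head-and-neck phantom used to emulate paired
#' pre-treatment/adaptive plan data: an ellipsoidal body, 1-5 ellipsoidal
#' PTVs with prescriptions in 42.5-72 Gy, a small set of analytically placed
#' OARs (cord-like tubes, paired gland blobs), a distance-kernel dose model
#' with multiplicative per-OAR sparing, and a session-to-session deformation
#' (PTV shrinkage, structure shifts, gland volume loss). The per-patient
#' sparing profile is constant across that patient's sessions — it is the
#' latent clinical intent that only the pre-treatment dose reveals.
#'
#' @param grid_shape Voxel grid (default 64 x 64 x 48).
#' @param spacing Isotropic voxel spacing in mm (default 5).
#' @param n_ptv_range Integer range of PTVs per patient (default 1-5).
#' @param prescription_range Prescription sampling range in Gy.
#' @param oar_set Roster structures the phantom places (placement priors are
#'   built in for the default set).
#' @param falloff_scale Dose falloff length lambda in mm (default 20): dose
#'   outside the PTV decays as `exp(-d / lambda)`.
#' @param sparing_range Per-OAR sparing strength range (default 0-0.6).
#' @param ptv_shrink_range Session-to-session PTV volume shrink factor range.
#' @param shift_sigma Per-structure Gaussian shift SD in mm.
#' @param gland_shrink_range Gland volume reduction factor range.
#' @param noise_amplitude SD of the smooth zero-mean dose noise in Gy.
#' @param max_attempts Deformation retries before erroring when a structure
#'   would leave the body.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 48), spacing = 5,
                           n_ptv_range = c(1L, 5L),
                           prescription_range = c(42.5, 72),
                           oar_set = c("spinal_cord", "spinal_canal", "brainstem",
                                       "larynx", "esophagus", "oral_cavity",
                                       "parotid_left", "parotid_right",
                                       "submandibular_left", "submandibular_right"),
                           falloff_scale = 20, sparing_range = c(0, 0.6),
                           ptv_shrink_range = c(0.7, 0.95), shift_sigma = 3,
                           gland_shrink_range = c(0.75, 0.95),
                           noise_amplitude = 0.8, max_attempts = 10L) {
  roster_index(oar_set)
  if (any(prescription_range <= 0)) fail_validation("prescriptions must be > 0")
  if (any(ptv_shrink_range <= 0) || any(ptv_shrink_range > 1)) {
    fail_validation("ptv_shrink_range must lie in (0, 1]")
  }
  structure(
    list(grid_shape = as.integer(rep_len(grid_shape, 3L)),
         spacing = rep_len(as.numeric(spacing), 3L),
         n_ptv_range = as.integer(n_ptv_range),
         prescription_range = prescription_range, oar_set = oar_set,
         falloff_scale = falloff_scale, sparing_range = sparing_range,
         ptv_shrink_range = ptv_shrink_range, shift_sigma = shift_sigma,
         gland_shrink_range = gland_shrink_range,
         noise_amplitude = noise_amplitude,
         max_attempts = as.integer(max_attempts)),
    class = "phantom_config"
  )
}

# ---- analytic geometry ---------------------------------------------------

# Structures are kept analytic (ellipsoids; z-limited tubes are ellipsoids
# with a long z radius clipped to a z range) and re-rasterized after
# deformation, so deformed ground truth is exact rather than voxel-warped.

rasterize_ellipsoid <- function(center, radii, grid, spacing, zlim = NULL) {
  ax <- (((seq_len(grid[1]) - 1) * spacing[1] - center[1]) / radii[1])^2
  ay <- (((seq_len(grid[2]) - 1) * spacing[2] - center[2]) / radii[2])^2
  az <- (((seq_len(grid[3]) - 1) * spacing[3] - center[3]) / radii[3])^2
  m <- outer(outer(ax, ay, "+"), az, "+") <= 1
  if (!is.null(zlim)) {
    z <- (seq_len(grid[3]) - 1) * spacing[3]
    keep <- z >= zlim[1] & z <= zlim[2]
    m <- m & rep(rep(keep, each = grid[1] * grid[2]), times = 1)
  }
  array(as.numeric(m), grid)
}

rasterize_structure <- function(st, grid, spacing) {
  rasterize_ellipsoid(st$center, st$radii, grid, spacing, st$zlim)
}

# Placement priors for the default OAR set, in mm relative to the body
# ellipsoid (center bc, radii br). Posterior is +y, superior is +z.
phantom_geometry <- function(cfg) {
  g <- cfg$grid_shape; sp <- cfg$spacing
  ext <- (g - 1) * sp
  bc <- ext / 2
  br <- 0.45 * ext
  geom <- list(body = list(name = "body", center = bc, radii = br, zlim = NULL))

  n_ptv <- sample(seq(cfg$n_ptv_range[1], cfg$n_ptv_range[2]), 1)
  prescs <- sort(runif(n_ptv, cfg$prescription_range[1], cfg$prescription_range[2]),
                 decreasing = TRUE)
  ptvs <- list()
  base_center <- bc + c(runif(1, -0.15, 0.15) * br[1],
                        runif(1, -0.2, 0.05) * br[2],
                        runif(1, -0.15, 0.15) * br[3])
  base_r <- runif(1, 12, 25)
  for (i in seq_len(n_ptv)) {
    center <- base_center + if (i == 1) 0 else rnorm(3, sd = 6)
    radii <- pmax(6, base_r * runif(3, 0.55, 1.15) * (if (i == 1) 1 else runif(1, 0.6, 1)))
    ptvs[[i]] <- list(name = paste0("ptv", i), center = center, radii = radii,
                      zlim = NULL, prescription = prescs[i])
  }

  place <- list(
    spinal_cord = list(center = bc + c(0, 0.55 * br[2], 0), radii = c(5, 5, 2 * ext[3]),
                       zlim = c(0, ext[3])),
    spinal_canal = list(center = bc + c(0, 0.55 * br[2], 0), radii = c(9, 9, 2 * ext[3]),
                        zlim = c(0, ext[3])),
    brainstem = list(center = bc + c(0, 0.35 * br[2], 0.75 * br[3]),
                     radii = c(9, 9, 16), zlim = NULL),
    larynx = list(center = bc + c(0, -0.45 * br[2], -0.25 * br[3]),
                  radii = c(9, 9, 13), zlim = NULL),
    esophagus = list(center = bc + c(0, 0.35 * br[2], -0.6 * br[3]),
                     radii = c(6, 6, 0.5 * ext[3]), zlim = c(0, bc[3])),
    oral_cavity = list(center = bc + c(0, -0.5 * br[2], 0.2 * br[3]),
                       radii = c(16, 13, 11), zlim = NULL),
    parotid_left = list(center = bc + c(-0.6 * br[1], 0.1 * br[2], 0.25 * br[3]),
                        radii = c(10, 12, 15), zlim = NULL),
    parotid_right = list(center = bc + c(0.6 * br[1], 0.1 * br[2], 0.25 * br[3]),
                         radii = c(10, 12, 15), zlim = NULL),
    submandibular_left = list(center = bc + c(-0.4 * br[1], -0.3 * br[2], -0.2 * br[3]),
                              radii = c(8, 8, 9), zlim = NULL),
    submandibular_right = list(center = bc + c(0.4 * br[1], -0.3 * br[2], -0.2 * br[3]),
                               radii = c(8, 8, 9), zlim = NULL)
  )
  oars <- list()
  for (nm in cfg$oar_set) {
    if (nm == "body") next
    pr <- place[[nm]]
    if (is.null(pr)) {
      # structures without a built-in prior get a small jittered central blob
      pr <- list(center = bc + rnorm(3, sd = 0.2 * br), radii = c(8, 8, 8), zlim = NULL)
    }
    pr$center <- pr$center + rnorm(3, sd = 2)
    pr$name <- nm
    oars[[nm]] <- pr
  }
  list(body = geom$body, ptvs = ptvs, oars = oars,
       grid = g, spacing = sp, noise_seed = sample.int(2^31 - 2, 1))
}

smooth_noise_field <- function(grid, amplitude, seed) {
  if (amplitude <= 0) return(array(0, grid))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  coarse_dim <- pmax(2L, as.integer(ceiling(grid / 4)))
  z <- array(rnorm(prod(coarse_dim), sd = 1), c(coarse_dim, 1L))
  z <- upsample2_forward(upsample2_forward(z, "linear"), "linear")
  z <- z[seq_len(grid[1]), seq_len(grid[2]), seq_len(grid[3]), 1]
  amplitude * z / sd(z)
}

geometry_to_session <- function(geom, cfg, session_kind, patient_id, dose = NULL) {
  g <- geom$grid; sp <- geom$spacing
  body <- rasterize_structure(geom$body, g, sp)
  ptv_masks <- lapply(geom$ptvs, rasterize_structure, grid = g, spacing = sp)
  ptv_masks <- lapply(ptv_masks, function(m) m * body)
  ptv_merged <- merge_ptvs(ptv_masks, vapply(geom$ptvs, `[[`, numeric(1), "prescription"))
  ptv_any <- as.numeric(ptv_merged > 0)
  masks <- list(body = body)
  for (nm in names(geom$oars)) {
    m <- rasterize_structure(geom$oars[[nm]], g, sp) * body * (1 - ptv_any)
    masks[[nm]] <- m
  }
  # simple tissue-density CT: air outside the body, soft tissue inside,
  # bone-like canal, with smooth texture noise
  ct <- array(-1000, g)
  ct[body == 1] <- 40
  if (!is.null(masks$spinal_canal)) {
    ring <- masks$spinal_canal * (1 - (masks$spinal_cord %||% 0))
    ct[ring == 1] <- 700
  }
  ct <- ct + smooth_noise_field(g, 20, geom$noise_seed + 1L) * body
  plan_session(ct = ct, oar_masks = masks, ptv_map = ptv_merged, spacing = sp,
               session_kind = session_kind, dose = dose, patient_id = patient_id)
}

#' Generate a synthetic anatomy (no dose)
#'
#' Samples a patient's analytic geometry (body, PTVs with prescriptions,
#' OARs placed by their priors, none overlapping the PTV) and rasterizes it
#' into a `plan_session` without dose. Deterministic given the RNG state.
#'
#' @param cfg A [phantom_config()].
#' @param session_kind Session label for the result.
#' @param patient_id Identifier.
#' @return A `plan_session` (dose absent) with the analytic geometry
#'   attached as attribute `"geometry"`.
#' @export
generate_anatomy <- function(cfg = phantom_config(), session_kind = "adaptive",
                             patient_id = "P000") {
  min_mm <- min((cfg$grid_shape - 1) * cfg$spacing)
  if (min_mm < 80) fail_validation("grid too small for the requested structures")
  geom <- phantom_geometry(cfg)
  s <- geometry_to_session(geom, cfg, session_kind, patient_id)
  attr(s, "geometry") <- geom
  s
}

#' Sample a per-patient sparing profile
#'
#' One sparing strength per placed OAR (uniform over `sparing_range`),
#' constant across the patient's sessions: the latent organ-sparing intent
#' the secondary head can recover from the pre-treatment dose.
#'
#' @param cfg A [phantom_config()].
#' @return Named numeric vector of class `sparing_profile`.
#' @export
sparing_profile <- function(cfg = phantom_config()) {
  oars <- setdiff(cfg$oar_set, "body")
  structure(stats::setNames(runif(length(oars), cfg$sparing_range[1],
                                  cfg$sparing_range[2]), oars),
            class = "sparing_profile")
}

#' Synthesize a planned dose for an anatomy
#'
#' Distance-kernel dose model: inside each PTV the dose equals its
#' prescription; outside, each PTV contributes its prescription decayed as
#' `exp(-d / lambda)` with `d` the Euclidean distance (mm) to that PTV, and
#' voxels take the maximum contribution (so the nearest/hottest PTV
#' dominates). The field is then multiplied, for every spared OAR `o`, by
#' `1 - sigma_o * exp(-d_o / lambda)` — a dose valley of depth `sigma_o`
#' centred on the structure — masked to the body, and perturbed by smooth
#' zero-mean noise clipped at 0. This is a statistical test harness
#' (persistent physician intent + changing anatomy), not a beam-physics
#' simulator.
#'
#' @param anatomy A `plan_session` carrying its `"geometry"` attribute.
#' @param profile A [sparing_profile()].
#' @param cfg A [phantom_config()].
#' @param noise Apply the smooth noise field (default `TRUE`).
#' @return 3D dose array in Gy.
#' @export
synthesize_dose <- function(anatomy, profile, cfg = phantom_config(), noise = TRUE) {
  geom <- attr(anatomy, "geometry")
  if (is.null(geom)) fail_validation("synthesize_dose: anatomy lacks geometry")
  if (!length(geom$ptvs)) fail_validation("synthesize_dose: anatomy has no PTV")
  g <- geom$grid; sp <- geom$spacing
  body <- anatomy$oar_masks$body
  dose <- array(0, g)
  for (p in geom$ptvs) {
    m <- rasterize_structure(p, g, sp) * body
    if (sum(m) == 0) next
    d <- euclidean_distance_mm(m, sp)
    dose <- pmax(dose, p$prescription * exp(-d / cfg$falloff_scale))
  }
  for (nm in names(profile)) {
    sig <- profile[[nm]]
    if (sig <= 0) next
    m <- anatomy$oar_masks[[nm]]
    if (is.null(m) || sum(m) == 0) next
    d <- euclidean_distance_mm(m, sp)
    dose <- dose * (1 - sig * exp(-d / cfg$falloff_scale))
  }
  if (noise && cfg$noise_amplitude > 0) {
    dose <- dose + smooth_noise_field(g, cfg$noise_amplitude, geom$noise_seed)
  }
  pmax(dose, 0) * body
}

deform_geometry <- function(geom, cfg, body_mask) {
  g <- geom$grid; sp <- geom$spacing
  shrink <- runif(1, cfg$ptv_shrink_range[1], cfg$ptv_shrink_range[2])
  new <- geom
  for (i in seq_along(new$ptvs)) {
    new$ptvs[[i]]$radii <- new$ptvs[[i]]$radii * shrink^(1 / 3)
    new$ptvs[[i]]$center <- new$ptvs[[i]]$center + rnorm(3, sd = cfg$shift_sigma)
  }
  glands <- grep("parotid|submandibular|lacrimal", names(new$oars), value = TRUE)
  for (nm in names(new$oars)) {
    st <- new$oars[[nm]]
    m0 <- rasterize_structure(st, g, sp)
    n0 <- sum(m0 * body_mask)  # structures are clipped to the body at rasterization
    accepted <- FALSE
    for (attempt in seq_len(cfg$max_attempts)) {
      cand <- st
      cand$center <- st$center + rnorm(3, sd = cfg$shift_sigma)
      if (nm %in% glands) {
        gs <- runif(1, cfg$gland_shrink_range[1], cfg$gland_shrink_range[2])
        cand$radii <- st$radii * gs^(1 / 3)
      }
      m <- rasterize_structure(cand, g, sp)
      # accept unless the shift destroys most of the in-body volume
      if (sum(m * body_mask) >= 0.5 * n0 && sum(m * body_mask) > 0) {
        st <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      fail_validation(paste0("deformation pushed '", nm, "' outside the body"))
    }
    new$oars[[nm]] <- st
  }
  new$shrink_factor <- shrink
  new
}

#' Generate a linked pre-treatment/adaptive plan pair
#'
#' Samples one patient: a pre-treatment anatomy with a dose synthesized from
#' a sampled sparing profile, and an adaptive session whose anatomy is a
#' deformed copy (shrunken PTVs, Gaussian structure shifts, reduced gland
#' volumes) with ground-truth dose computed from the *same* sparing profile
#' on the new anatomy. The pre-treatment dose is therefore informative about
#' the adaptive dose beyond anatomy alone. With `deform = FALSE` the two
#' sessions are identical.
#'
#' @param cfg A [phantom_config()].
#' @param patient_id Identifier.
#' @param deform Apply the session-to-session deformation (default `TRUE`).
#' @return A `plan_pair`; the sparing profile is attached as attribute
#'   `"profile"` and the PTV shrink factor as `"shrink_factor"`.
#' @export
generate_plan_pair <- function(cfg = phantom_config(), patient_id = "P000",
                               deform = TRUE) {
  pre_anat <- generate_anatomy(cfg, "pretreatment", patient_id)
  geom <- attr(pre_anat, "geometry")
  profile <- sparing_profile(cfg)
  pre_dose <- synthesize_dose(pre_anat, profile, cfg)
  pre <- pre_anat
  pre$dose <- pre_dose
  validate_session(pre)

  if (deform) {
    ad_geom <- deform_geometry(geom, cfg, pre_anat$oar_masks$body)
  } else {
    ad_geom <- geom
  }
  ad_anat <- geometry_to_session(ad_geom, cfg, "adaptive", patient_id)
  attr(ad_anat, "geometry") <- ad_geom
  ad_dose <- synthesize_dose(ad_anat, profile, cfg)
  adaptive <- ad_anat
  adaptive$dose <- ad_dose
  validate_session(adaptive)

  pair <- plan_pair(pre, adaptive)
  attr(pair, "profile") <- profile
  attr(pair, "shrink_factor") <- if (deform) ad_geom$shrink_factor else 1
  pair
}

#' Generate a synthetic patient cohort
#'
#' Independent patients with per-patient derived seeds; regeneration from
#' the same seed is bit-identical.
#'
#' @param n_patients Number of patients (>= 1).
#' @param cfg A [phantom_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory: each patient's sessions are written as
#'   NIfTI bundles plus a cohort `manifest.json`.
#' @return List of `plan_pair` objects (invisibly also written to
#'   `out_dir` when given).
#' @export
generate_cohort <- function(n_patients, cfg = phantom_config(), seed = 1L,
                            out_dir = NULL) {
  if (n_patients < 1) fail_validation("n_patients must be >= 1")
  set.seed(seed)
  patient_seeds <- sample.int(2^31 - 2, n_patients)
  pairs <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(patient_seeds[i])
    pairs[[i]] <- generate_plan_pair(cfg, patient_id = sprintf("P%03d", i))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_patients)) {
      save_session(pairs[[i]]$pre, file.path(out_dir, sprintf("P%03d_pre", i)))
      save_session(pairs[[i]]$adaptive, file.path(out_dir, sprintf("P%03d_adaptive", i)))
    }
    jsonlite::write_json(
      list(n_patients = n_patients, seed = seed, patient_seeds = patient_seeds),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  pairs
}
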