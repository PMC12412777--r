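phantom_small <- function() phantom_config(grid_shape = c(32, 32, 32))

test_that("phantom generation is deterministic and respects invariants", {
  cfg <- phantom_small()
  set.seed(50); p1 <- generate_plan_pair(cfg, "P001")
  set.seed(50); p2 <- generate_plan_pair(cfg, "P001")
  expect_identical(p1$pre$dose, p2$pre$dose)
  expect_identical(p1$adaptive$oar_masks, p2$adaptive$oar_masks)

  validate_session(p1$pre)
  validate_session(p1$adaptive)
  body <- p1$adaptive$oar_masks$body
  for (nm in setdiff(names(p1$adaptive$oar_masks), "body")) {
    m <- p1$adaptive$oar_masks[[nm]]
    expect_true(is_binary(m))
    expect_true(all(m <= body))  # structures live inside the body
  }
  expect_identical(p1$pre$patient_id, p1$adaptive$patient_id)
  expect_identical(attr(p1, "profile"), attr(p1, "profile"))
})

test_that("PTV count stays in the configured range over many draws", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_ptv_range = c(1L, 3L))
  set.seed(51)
  counts <- replicate(30, {
    a <- generate_anatomy(cfg)
    length(attr(a, "geometry")$ptvs)
  })
  expect_true(all(counts >= 1 & counts <= 3))
  expect_gt(length(unique(counts)), 1)
})

test_that("dose equals the prescription deep inside the PTV (noise off)", {
  cfg <- phantom_small()
  # walk a fixed seed sequence until a draw has an interior PTV core (the
  # sampled PTV radius must exceed the core depth); deterministic by seeds
  core <- NULL
  for (seed in 52:70) {
    set.seed(seed)
    anatomy <- generate_anatomy(cfg)
    presc_map <- anatomy$ptv_map
    top <- max(presc_map)
    core_mask <- array(as.numeric(presc_map == top), dim(presc_map))
    dist_in <- euclidean_distance_mm(1 - core_mask, cfg$spacing)
    cand <- core_mask == 1 & dist_in > 1.5 * cfg$spacing[1]
    if (sum(cand) > 0) { core <- cand; break }
  }
  expect_gt(sum(core), 0)
  profile <- sparing_profile(cfg)
  profile[] <- 0
  dose <- synthesize_dose(anatomy, profile, cfg, noise = FALSE)
  expect_true(all(abs(dose[core] - top) < 1e-6))
})

test_that("the falloff field is monotone along rays leaving a single PTV", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_ptv_range = c(1L, 1L))
  set.seed(53)
  anatomy <- generate_anatomy(cfg)
  profile <- sparing_profile(cfg)
  profile[] <- 0
  dose <- synthesize_dose(anatomy, profile, cfg, noise = FALSE)
  com <- round(colMeans(which(anatomy$ptv_map > 0, arr.ind = TRUE)))
  body <- anatomy$oar_masks$body
  ray <- dose[com[1]:dim(dose)[1], com[2], com[3]]
  inside <- body[com[1]:dim(dose)[1], com[2], com[3]] == 1
  ray <- ray[inside]
  expect_true(all(diff(ray) <= 1e-9))
})

test_that("stronger sparing strictly lowers the mean dose in that organ", {
  cfg <- phantom_small()
  set.seed(54)
  anatomy <- generate_anatomy(cfg)
  profile <- sparing_profile(cfg)
  profile[] <- 0
  profile["parotid_left"] <- 0.25
  d1 <- synthesize_dose(anatomy, profile, cfg, noise = FALSE)
  profile["parotid_left"] <- 0.5
  d2 <- synthesize_dose(anatomy, profile, cfg, noise = FALSE)
  m <- anatomy$oar_masks$parotid_left
  expect_gt(sum(m), 0)
  expect_lt(mean(d2[m == 1]), mean(d1[m == 1]))
})

test_that("zero deformation reproduces the pre-treatment session exactly", {
  cfg <- phantom_small()
  set.seed(55)
  pair <- generate_plan_pair(cfg, "P001", deform = FALSE)
  expect_identical(pair$pre$ct, pair$adaptive$ct)
  expect_identical(pair$pre$oar_masks, pair$adaptive$oar_masks)
  expect_identical(pair$pre$ptv_map, pair$adaptive$ptv_map)
  expect_identical(pair$pre$dose, pair$adaptive$dose)
})

test_that("the sampled shrink factor shows up in the adaptive PTV volume", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), shift_sigma = 0,
                        n_ptv_range = c(1L, 1L))
  set.seed(56)
  ratios <- replicate(8, {
    pair <- generate_plan_pair(cfg, "P001")
    s <- attr(pair, "shrink_factor")
    ratio <- sum(pair$adaptive$ptv_map > 0) / sum(pair$pre$ptv_map > 0)
    ratio / s
  })
  # voxel-count ratio tracks the sampled factor up to discretization
  expect_true(all(abs(ratios - 1) < 0.35))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("cohorts have independent patients and regenerate bit-identically", {
  cfg <- phantom_small()
  c1 <- generate_cohort(3, cfg, seed = 60)
  c2 <- generate_cohort(3, cfg, seed = 60)
  expect_identical(c1[[2]]$adaptive$dose, c2[[2]]$adaptive$dose)
  expect_false(identical(c1[[1]]$pre$dose, c1[[2]]$pre$dose))
  expect_equal(vapply(c1, function(p) p$patient_id, character(1)),
               c("P001", "P002", "P003"))
})

test_that("synthetic doses pass DVH sanity: PTV D95 near prescription", {
  cfg <- phantom_small()
  set.seed(61)
  anatomy <- generate_anatomy(cfg)
  profile <- sparing_profile(cfg)
  profile[] <- 0
  dose <- synthesize_dose(anatomy, profile, cfg, noise = FALSE)
  top <- max(anatomy$ptv_map)
  mask <- array(as.numeric(anatomy$ptv_map == top), dim(dose))
  d95 <- dose_at_volume(dose[mask == 1], 95)
  expect_lt(abs(d95 - top), 2)
})

test_that("per-patient sparing intent is recoverable from the pre-treatment dose", {
  cfg <- phantom_small()
  set.seed(62)
  true_sigma <- c(); est_sigma <- c()
  for (i in 1:8) {
    pair <- generate_plan_pair(cfg, sprintf("P%03d", i))
    profile <- attr(pair, "profile")
    anatomy <- pair$pre
    zero <- profile; zero[] <- 0
    counterfactual <- synthesize_dose(anatomy, zero, cfg, noise = FALSE)
    for (nm in c("parotid_left", "parotid_right", "larynx")) {
      m <- anatomy$oar_masks[[nm]]
      if (is.null(m) || sum(m) < 10) next
      cf <- mean(counterfactual[m == 1])
      if (cf < 1) next
      true_sigma <- c(true_sigma, profile[[nm]])
      est_sigma <- c(est_sigma, 1 - mean(pair$pre$dose[m == 1]) / cf)
    }
  }
  expect_gt(length(true_sigma), 10)
  expect_gt(cor(true_sigma, est_sigma), 0.8)
})
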