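test_that("PTV merge takes the highest prescription and zero elsewhere", {
  d <- c(6, 6, 4)
  m1 <- array(0, d); m1[1:4, 1:4, ] <- 1
  m2 <- array(0, d); m2[3:6, 3:6, ] <- 1
  merged <- merge_ptvs(list(m1, m2), c(54, 70))
  expect_equal(merged[3, 3, 1], 70)   # overlap -> highest prescription
  expect_equal(merged[1, 1, 1], 54)
  expect_equal(merged[6, 1, 1], 0)    # no PTV -> zero

  single <- merge_ptvs(list(m1), 60)
  expect_true(all(single[m1 == 1] == 60))
  expect_true(all(single[m1 == 0] == 0))

  expect_error(merge_ptvs(list(), numeric(0)), "empty")
  expect_error(merge_ptvs(list(m1, array(0, c(2, 2, 2))), c(50, 50)), "grid")
  expect_error(merge_ptvs(list(m1), -3), "> 0")
})

test_that("surface distance maps match the all-pairs oracle on small grids", {
  set.seed(3)
  for (spacing in list(c(1, 1, 1), c(2, 3, 5))) {
    for (rep in 1:3) {
      d <- c(7, 6, 5)
      mask <- array(as.numeric(runif(prod(d)) < 0.12), d)
      if (sum(mask) == 0) mask[3, 3, 3] <- 1
      bf <- brute_force_edt(mask, spacing)
      expect_equal(euclidean_distance_mm(mask, spacing), bf, tolerance = 1e-12)
      tau <- 17
      dm <- structure_distance_map(mask, distance_map_spec(tau = tau), spacing)
      expect_equal(dm, exp(-bf / tau), tolerance = 1e-12)
      expect_true(all(dm[mask == 1] == 1))
      expect_true(all(dm >= 0 & dm <= 1))
    }
  }
})

test_that("distance maps decay as exp(-d/tau): exp(-1) one tau from the surface", {
  d <- c(21, 5, 5)
  mask <- array(0, d); mask[1, , ] <- 1
  tau <- 10
  dm <- structure_distance_map(mask, distance_map_spec(tau = tau), c(1, 1, 1))
  expect_equal(dm[11, 3, 3], exp(-1), tolerance = 1e-12)  # 10 mm = tau away
  expect_equal(dm[21, 3, 3], exp(-2), tolerance = 1e-12)
  # monotone non-increasing with distance along the axis
  expect_true(all(diff(dm[, 3, 3]) <= 0))
})

test_that("distance map edge cases: empty mask, isocenter mode, invalid input", {
  d <- c(5, 5, 5)
  expect_equal(structure_distance_map(array(0, d)), array(0, d))
  expect_error(structure_distance_map(array(2, d)), "binary")
  expect_error(distance_map_spec(tau = 0), "tau")

  mask <- array(0, d); mask[3, 3, 3] <- 1
  iso <- structure_distance_map(mask, distance_map_spec("isocenter", tau = 5), c(2, 2, 2))
  expect_equal(iso[3, 3, 3], 1)
  expect_equal(iso[5, 3, 3], exp(-4 / 5), tolerance = 1e-12)  # 2 voxels * 2 mm from COM
})

test_that("channel assembly has the fixed 90/91-channel manifest", {
  s <- make_session(d = c(8, 8, 8), with_dose = TRUE)
  a <- assemble_channels(s, "primary")
  expect_equal(dim(a$tensor)[4], 90L)
  expect_equal(length(a$manifest), 90L)
  expect_equal(a$manifest[1], "mask_body")
  expect_equal(a$manifest[45], "dmap_body")
  expect_equal(a$manifest[89:90], c("ptv", "ct"))

  b <- assemble_channels(s, "secondary")
  expect_equal(dim(b$tensor)[4], 91L)
  expect_equal(b$manifest[91], "dose")
  expect_equal(b$tensor[, , , 91], s$dose / 72, tolerance = 1e-12)

  s_nodose <- make_session(d = c(8, 8, 8), with_dose = FALSE)
  expect_error(assemble_channels(s_nodose, "secondary"), "dose")
})

test_that("absent roster structures become zero channels without changing the layout", {
  s <- make_session(d = c(8, 8, 8))
  a <- assemble_channels(s, "primary")
  roster <- oar_roster()
  absent <- setdiff(roster, names(s$oar_masks))
  for (nm in absent[1:5]) {
    i <- match(nm, roster)
    expect_true(all(a$tensor[, , , i] == 0))
    expect_true(all(a$tensor[, , , 44 + i] == 0))
  }
  present <- "spinal_cord"
  i <- match(present, roster)
  expect_equal(a$tensor[, , , i], s$oar_masks[[present]])
})

test_that("assembly is invariant to mask-list order and idempotent", {
  s <- make_session(d = c(8, 8, 8))
  a1 <- assemble_channels(s, "primary")
  s_perm <- s
  s_perm$oar_masks <- rev(s$oar_masks)
  a2 <- assemble_channels(s_perm, "primary")
  expect_identical(a1$tensor, a2$tensor)
  a3 <- assemble_channels(s, "primary")
  expect_identical(a1$tensor, a3$tensor)
})

test_that("CT and dose channels use the documented affine normalizations", {
  d <- c(4, 4, 4)
  ct <- array(0, d); ct[1, 1, 1] <- -2000; ct[2, 1, 1] <- 3000; ct[3, 1, 1] <- 0
  s <- plan_session(ct, list(), array(50, d), c(5, 5, 5), "adaptive")
  a <- assemble_channels(s, "primary", dose_norm = 72)
  ct_ch <- a$tensor[, , , 90]
  expect_equal(ct_ch[1, 1, 1], 0)   # clipped below
  expect_equal(ct_ch[2, 1, 1], 1)   # clipped above
  expect_equal(ct_ch[3, 1, 1], 0.5) # (0 + 1000) / 2000
  expect_equal(a$tensor[1, 1, 1, 89], 50 / 72, tolerance = 1e-12)
})
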