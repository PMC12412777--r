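test_that("depth-scaled dropout follows the power-law formula", {
  spec <- dropout_spec(max_rate = 0.05, power = 0.25, max_filters = 512)
  expect_equal(dropout_rate(512, spec), 0.05)
  # direct evaluation: 0.05 * (64/512)^0.25
  expect_equal(dropout_rate(64, spec), 0.05 * (1 / 8)^0.25, tolerance = 1e-12)
  expect_lt(dropout_rate(64, spec), dropout_rate(128, spec))
  expect_lt(dropout_rate(128, spec), dropout_rate(512, spec))
  expect_error(dropout_rate(0, spec), "> 0")
})

test_that("the full-scale architecture reproduces every printed tensor shape", {
  cfg <- network_config()  # base 64, four levels, 90/91 channels
  tab <- model_summary(cfg, input_shape = c(96, 96, 64), kind = "mhunet")
  get <- function(stage, head) dplyr::filter(tab, .data$stage == !!stage, .data$head == !!head)

  e1 <- get("enc1.conv", "primary")
  expect_equal(c(e1$channels, e1$nx, e1$ny, e1$nz), c(64, 96, 96, 64))
  s1 <- get("sec1.conv", "secondary")
  expect_equal(c(s1$channels, s1$nx, s1$ny, s1$nz), c(64, 96, 96, 64))
  d1 <- get("down1", "primary")
  expect_equal(c(d1$channels, d1$nx, d1$ny, d1$nz), c(128, 48, 48, 32))
  bn <- get("bottleneck", "merged")
  expect_equal(c(bn$channels, bn$nx, bn$ny, bn$nz), c(512, 12, 12, 8))
  out <- get("output", "decoder")
  expect_equal(c(out$channels, out$nx, out$ny, out$nz), c(1, 96, 96, 64))

  # per-level halving of spatial dims
  for (l in 1:3) {
    dl <- get(paste0("down", l), "primary")
    expect_equal(c(dl$nx, dl$ny, dl$nz), c(96, 96, 64) / 2^l)
  }

  utab <- model_summary(network_config(), kind = "unet")
  expect_equal(dplyr::filter(utab, stage == "down1")$channels, 128L)
  expect_equal(dplyr::filter(utab, stage == "bottleneck")$channels, 512L)
})

test_that("forward passes produce the contracted output shape and are finite", {
  cfg <- tiny_network_config(in_primary = 5L, in_secondary = 6L)
  unet <- build_unet(cfg, seed = 1)
  mhu <- build_mhunet(cfg, seed = 1)
  for (s in 1:5) {
    set.seed(100 + s)
    xp <- array(rnorm(8 * 8 * 8 * 5), c(8, 8, 8, 5))
    xs <- array(rnorm(8 * 8 * 8 * 6), c(8, 8, 8, 6))
    o1 <- net_forward(unet, xp)$out
    o2 <- net_forward(mhu, xp, xs)$out
    expect_equal(dim(o1), c(8, 8, 8))
    expect_equal(dim(o2), c(8, 8, 8))
    expect_true(all(is.finite(o1)) && all(is.finite(o2)))
    expect_true(all(o1 >= 0))  # output ReLU
  }
  # inference mode is deterministic (dropout disabled)
  xp <- array(rnorm(8 * 8 * 8 * 5), c(8, 8, 8, 5))
  expect_identical(net_forward(unet, xp)$out, net_forward(unet, xp)$out)
})

test_that("forward contracts reject bad inputs", {
  cfg <- tiny_network_config(in_primary = 5L, in_secondary = 6L)
  mhu <- build_mhunet(cfg, seed = 1)
  xp <- array(0, c(8, 8, 8, 5))
  expect_error(net_forward(mhu, xp), "secondary")
  expect_error(net_forward(mhu, array(0, c(8, 8, 8, 4)),
                           array(0, c(8, 8, 8, 6))), "channels")
  expect_error(net_forward(mhu, array(0, c(7, 8, 8, 5)),
                           array(0, c(7, 8, 8, 6))), "divisible")
})

test_that("MHU-Net has more parameters than the baseline at equal config", {
  cfg <- tiny_network_config()
  expect_gt(n_parameters(build_mhunet(cfg, seed = 1)),
            n_parameters(build_unet(cfg, seed = 1)))
  # width scaling: doubling base width doubles every level's conv width
  m1 <- build_unet(tiny_network_config(base_width = 4L), seed = 1)
  m2 <- build_unet(tiny_network_config(base_width = 8L), seed = 1)
  expect_equal(dim(m2$params[["enc1.c1.W"]])[5], 2L * dim(m1$params[["enc1.c1.W"]])[5])
  expect_equal(dim(m2$params[["enc2.c2.W"]])[5], 2L * dim(m1$params[["enc2.c2.W"]])[5])
})

test_that("zeroed secondary stream reduces MHU-Net to the matched U-Net", {
  cfg <- tiny_network_config(in_primary = 3L, in_secondary = 4L, n_levels = 3L,
                             dropout = dropout_spec(max_rate = 0))
  unet <- build_unet(cfg, seed = 5)
  mhu <- build_mhunet(cfg, seed = 6)
  w <- level_widths(cfg)
  # zero the secondary encoder entirely
  for (nm in grep("^sec", names(mhu$params), value = TRUE)) {
    mhu$params[[nm]] <- mhu$params[[nm]] * 0
  }
  # transplant the U-Net weights; cross-head weight slices set to zero
  for (nm in names(unet$params)) {
    if (nm %in% names(mhu$params) && identical(dim(mhu$params[[nm]]), dim(unet$params[[nm]]))) {
      mhu$params[[nm]] <- unet$params[[nm]]
    }
  }
  for (l in 2:cfg$n_levels) {
    nm <- paste0("enc", l, ".c1.W")
    np <- dim(unet$params[[nm]])[4]  # primary half of the fused input
    Wm <- mhu$params[[nm]] * 0
    Wm[, , , seq_len(np), ] <- unet$params[[nm]]
    mhu$params[[nm]] <- Wm
    mhu$params[[paste0("enc", l, ".c1.b")]] <- unet$params[[paste0("enc", l, ".c1.b")]]
    mhu$params[[paste0("enc", l, ".c1.g")]] <- unet$params[[paste0("enc", l, ".c1.g")]]
    mhu$params[[paste0("enc", l, ".c1.be")]] <- unet$params[[paste0("enc", l, ".c1.be")]]
  }
  set.seed(77)
  xp <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  xs <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  expect_equal(net_forward(mhu, xp, xs)$out, net_forward(unet, xp)$out,
               tolerance = 1e-6)
})

test_that("the optional bypass stream changes parameters but not the contract", {
  cfg_on <- tiny_network_config(bypass_stream = TRUE,
                                dropout = dropout_spec(max_rate = 0))
  cfg_off <- tiny_network_config(dropout = dropout_spec(max_rate = 0))
  m_on <- build_unet(cfg_on, seed = 2)
  m_off <- build_unet(cfg_off, seed = 2)
  expect_gt(n_parameters(m_on), n_parameters(m_off))
  xp <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  expect_equal(dim(net_forward(m_on, xp)$out), c(8, 8, 8))
})

test_that("runtime trace matches the symbolic shape table", {
  cfg <- tiny_network_config(in_primary = 5L, in_secondary = 6L, n_levels = 3L)
  mhu <- build_mhunet(cfg, seed = 3)
  xp <- array(rnorm(8 * 8 * 8 * 5), c(8, 8, 8, 5))
  xs <- array(rnorm(8 * 8 * 8 * 6), c(8, 8, 8, 6))
  trc <- net_forward(mhu, xp, xs, trace = TRUE)$trace
  tab <- model_summary(mhu, input_shape = c(8, 8, 8))
  for (stage in c("enc1.conv", "enc1.down", "fuse1", "enc2.conv", "bottleneck")) {
    row <- dplyr::filter(tab, .data$stage == !!sub("enc1.down", "down1", stage) |
                           .data$stage == !!stage)
    row <- row[1, ]
    expect_equal(unname(trc[[stage]][4]), row$channels,
                 label = paste("channels at", stage))
  }
})
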