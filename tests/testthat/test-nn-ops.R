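# The single-precision C++ kernels are checked against the all-double plain-R
# reference implementations, and the composed networks against central-
# difference gradients computed on the double reference path.

test_that("convolution kernels agree with the double-precision reference", {
  set.seed(10)
  cases <- list(
    list(d = c(8, 7, 6, 5), cout = 3, zero_ch = integer(0)),
    list(d = c(6, 6, 6, 10), cout = 4, zero_ch = c(2, 7, 8)),
    list(d = c(5, 5, 4, 2), cout = 6, zero_ch = 1)
  )
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    for (ch in cs$zero_ch) x[, , , ch] <- 0
    W <- array(rnorm(27 * cs$d[4] * cs$cout, sd = 0.2), c(3, 3, 3, cs$d[4], cs$cout))
    b <- rnorm(cs$cout)
    dout <- array(rnorm(prod(cs$d[1:3]) * cs$cout), c(cs$d[1:3], cs$cout))

    f_fast <- conv3_forward(x, W, b)
    f_ref <- conv3_forward_ref(x, W, b)
    expect_equal(f_fast$out, f_ref$out, tolerance = 1e-5)

    b_fast <- conv3_backward(f_fast$cache, W, dout)
    b_ref <- conv3_backward_ref(f_ref$cache, W, dout)
    expect_equal(b_fast$dW, b_ref$dW, tolerance = 1e-5)
    expect_equal(b_fast$db, b_ref$db, tolerance = 1e-8)
    expect_equal(b_fast$dx, b_ref$dx, tolerance = 1e-5)
  }
})

test_that("transposed convolution agrees with the double-precision reference", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 4 * 5), c(6, 6, 4, 5))
  W <- array(rnorm(8 * 5 * 5, sd = 0.2), c(2, 2, 2, 5, 5))
  b <- rnorm(5)
  t_fast <- tconv2_forward(x, W, b)
  t_ref <- tconv2_forward_ref(x, W, b)
  expect_equal(dim(t_fast$out), c(12, 12, 8, 5))
  expect_equal(t_fast$out, t_ref$out, tolerance = 1e-5)
  dout <- array(rnorm(12 * 12 * 8 * 5), c(12, 12, 8, 5))
  b_fast <- tconv2_backward(t_fast$cache, W, dout)
  b_ref <- tconv2_backward_ref(t_ref$cache, W, dout)
  expect_equal(b_fast$dW, b_ref$dW, tolerance = 1e-5)
  expect_equal(b_fast$dx, b_ref$dx, tolerance = 1e-5)
})

test_that("dual pooling concatenates max and average branches", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  p <- pool_dual_forward(x)
  expect_equal(dim(p$out), c(2, 2, 2, 4))
  # constant input: max branch equals average branch
  xc <- array(3.5, c(4, 4, 4, 1))
  pc <- pool_dual_forward(xc)
  expect_equal(pc$out[, , , 1], pc$out[, , , 2])
  # oracle on one block
  blk <- x[1:2, 1:2, 1:2, 1]
  expect_equal(p$out[1, 1, 1, 1], max(blk))
  expect_equal(p$out[1, 1, 1, 3], mean(blk))
  expect_error(pool_dual_forward(array(0, c(3, 4, 4, 1))), "even")
})

test_that("pooling backward matches central differences", {
  set.seed(14)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  p <- pool_dual_forward(x)
  dout <- array(rnorm(length(p$out)), dim(p$out))
  dx <- pool_dual_backward(p$cache, dout)
  eps <- 1e-6
  for (j in sample(length(x), 12)) {
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    num <- (sum(pool_dual_forward(xp)$out * dout) -
              sum(pool_dual_forward(xm)$out * dout)) / (2 * eps)
    expect_lt(abs(dx[j] - num), 1e-6 + 1e-5 * abs(num))
  }
})

test_that("nearest upsampling replicates voxels and trilinear preserves ramps", {
  x <- array(0, c(1, 1, 1, 1)); x[1] <- 7
  up <- upsample2_forward(x, "nearest")
  expect_equal(up, array(7, c(2, 2, 2, 1)))

  # trilinear: a linear ramp stays linear at interior points
  n <- 6
  ramp <- array(rep(seq_len(n), times = n * n), c(n, n, n, 1))
  up <- upsample2_forward(ramp, "linear")
  interior <- up[3:(2 * n - 2), 4, 4, 1]
  expect_equal(diff(interior), rep(0.5, length(interior) - 1), tolerance = 1e-12)

  # constant volumes are exactly preserved by both modes
  cst <- array(2.5, c(4, 4, 4, 2))
  expect_equal(upsample2_forward(cst, "linear"), array(2.5, c(8, 8, 8, 2)))
})

test_that("upsampling backward is the exact adjoint of forward", {
  set.seed(15)
  for (mode in c("nearest", "linear")) {
    x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
    y <- array(rnorm(10 * 8 * 6 * 2), c(10, 8, 6, 2))
    lhs <- sum(upsample2_forward(x, mode) * y)
    rhs <- sum(x * upsample2_backward(y, dim(x), mode))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("group normalization output is normalized and backward is exact", {
  set.seed(16)
  x <- array(rnorm(6 * 6 * 4 * 8, mean = 3, sd = 2), c(6, 6, 4, 8))
  gamma <- runif(8, 0.5, 1.5); beta <- rnorm(8)
  fw <- groupnorm_forward(x, gamma, beta, max_groups = 4)
  # per-group standardization before the affine transform
  xhat <- (fw$out - rep(beta, each = prod(dim(x)[1:3]))) /
    rep(gamma, each = prod(dim(x)[1:3]))
  dim(xhat) <- c(prod(dim(x)[1:3]) * 2, 4)
  expect_equal(colMeans(xhat), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(xhat, 2, sd), rep(1, 4), tolerance = 5e-3)

  dout <- array(rnorm(length(x)), dim(x))
  bw <- groupnorm_backward(fw$cache, dout)
  eps <- 1e-6
  for (j in sample(length(x), 10)) {
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    num <- (sum(groupnorm_forward(xp, gamma, beta, 4)$out * dout) -
              sum(groupnorm_forward(xm, gamma, beta, 4)$out * dout)) / (2 * eps)
    expect_lt(abs(bw$dx[j] - num), 1e-5 + 1e-4 * abs(num))
  }
})

test_that("the grouping rule always divides the channel count", {
  expect_equal(largest_divisor_leq(64, 32), 32L)
  expect_equal(largest_divisor_leq(6, 4), 3L)
  expect_equal(largest_divisor_leq(7, 4), 1L)
  expect_equal(largest_divisor_leq(8, 32), 8L)
  for (C in 1:40) expect_equal(C %% largest_divisor_leq(C, 32), 0L)
})

test_that("whole-network analytic gradients match central differences", {
  # all-double reference path: float noise would otherwise swamp the check
  withr::local_options(adaptdose.conv_ref = TRUE)
  set.seed(42)
  cfg <- tiny_network_config(dropout = dropout_spec(max_rate = 0),
                             final_relu = FALSE)
  for (kind in c("unet", "mhunet")) {
    model <- if (kind == "unet") build_unet(cfg, seed = 7) else build_mhunet(cfg, seed = 7)
    # nudge biases off zero so no pre-activation sits exactly on a ReLU kink
    for (nm in grep("\\.b$", names(model$params), value = TRUE)) {
      model$params[[nm]] <- rnorm(length(model$params[[nm]]), sd = 0.05)
    }
    xp <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
    xs <- if (kind == "mhunet") array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
    tgt <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
    fw <- net_forward(model, xp, xs, train = FALSE, keep = TRUE)
    dout <- 2 * (fw$out - tgt) / length(tgt)
    G <- net_backward(model, fw$tape, dout)
    eps <- 1e-5
    for (nm in sample(names(G), 12)) {
      p <- model$params[[nm]]
      for (j in sample(length(p), 2)) {
        m2 <- model
        m2$params[[nm]][j] <- p[j] + eps
        lp <- mse_loss(net_forward(m2, xp, xs, keep = FALSE)$out, tgt)
        m2$params[[nm]][j] <- p[j] - eps
        lm <- mse_loss(net_forward(m2, xp, xs, keep = FALSE)$out, tgt)
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(G[[nm]][j] - num), 1e-7 + 1e-3 * abs(num))
      }
    }
  }
})
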