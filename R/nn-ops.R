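# Volumetric network primitives with hand-derived backward passes.
#
# Tensors are 4D arrays (x, y, z, channel), batch size 1 implicit (the
# training protocol uses batch 1 throughout). Convolutions are evaluated as
# a sum over kernel offsets of dense matrix products (voxels x in-channels)
# %*% (in-channels x out-channels), which routes the arithmetic through
# BLAS. Input channels that are identically zero (absent roster structures)
# are skipped in the forward product and weight gradient; their weight
# gradients are exactly zero, so this is lossless.

nn_pad3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1:3] + 2L * p, d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

# ---- 3D convolution (stride 1, "same" padding) --------------------------

conv3_forward <- function(x, W, b, keep_cache = TRUE) {
  if (isTRUE(getOption("adaptdose.conv_ref"))) {
    return(conv3_forward_ref(x, W, b, keep_cache))
  }
  k <- dim(W)[1]
  cin <- dim(W)[4]; cout <- dim(W)[5]
  d <- dim(x)
  if (d[4] != cin) fail_validation(sprintf("conv3: input has %d channels, weights expect %d", d[4], cin))
  n <- prod(d[1:3])
  nz <- .nonzero_channels(x, n, cin)
  if (k == 1L) {
    xm <- x; dim(xm) <- c(n, cin)
    out <- xm[, nz, drop = FALSE] %*% matrix(W[1, 1, 1, nz, ], length(nz), cout)
    out <- out + rep(b, each = n)
    dim(out) <- c(d[1:3], cout)
    return(list(out = out, cache = if (keep_cache) list(xm = xm, nz = nz, d = d, k = 1L)))
  }
  res <- .conv3_fwd_cpp(x, d[1:3], k, W, dim(W), nz, b, keep_cache)
  list(out = res$out, cache = if (keep_cache) list(ptr = res$ptr, nz = nz, d = d, k = k))
}

conv3_backward <- function(cache, W, dout, need_dx = TRUE) {
  if (!is.null(cache$ref)) return(conv3_backward_ref(cache, W, dout, need_dx))
  d <- cache$d; k <- cache$k; nz <- cache$nz
  cin <- dim(W)[4]; cout <- dim(W)[5]
  n <- prod(d[1:3])
  if (k == 1L) {
    dm <- dout; dim(dm) <- c(n, cout)
    dW <- array(0, dim(W))
    db <- .colSums(dm, n, cout)
    dW[1, 1, 1, nz, ] <- crossprod(cache$xm[, nz, drop = FALSE], dm)
    dx <- NULL
    if (need_dx) {
      dx <- dm %*% t(matrix(W[1, 1, 1, , ], cin, cout))
      dim(dx) <- c(d[1:3], cin)
    }
    return(list(dx = dx, dW = dW, db = db))
  }
  res <- .conv3_bwd_cpp(cache$ptr, d[1:3], k, W, dim(W), nz, dout, need_dx)
  list(dx = if (need_dx) res$dx, dW = res$dW, db = res$db)
}

# All-double reference convolution (offset-GEMM in plain R). Selected with
# options(adaptdose.conv_ref = TRUE); used by tests as the independent
# oracle for the single-precision C++ kernels and for exact numeric
# gradient checks.
conv3_forward_ref <- function(x, W, b, keep_cache = TRUE) {
  k <- dim(W)[1]
  cin <- dim(W)[4]; cout <- dim(W)[5]
  d <- dim(x)
  if (d[4] != cin) fail_validation("conv3: channel mismatch")
  n <- prod(d[1:3])
  p <- (k - 1L) %/% 2L
  xp <- nn_pad3(x, p)
  acc <- matrix(0, n, cout)
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
    sl <- xp[a:(a + d[1] - 1L), bb:(bb + d[2] - 1L), cc:(cc + d[3] - 1L), , drop = FALSE]
    dim(sl) <- c(n, cin)
    acc <- acc + sl %*% matrix(W[a, bb, cc, , ], cin, cout)
  }
  acc <- acc + rep(b, each = n)
  dim(acc) <- c(d[1:3], cout)
  list(out = acc, cache = if (keep_cache) list(xp = xp, d = d, k = k, ref = TRUE))
}

conv3_backward_ref <- function(cache, W, dout, need_dx = TRUE) {
  d <- cache$d; k <- cache$k
  cin <- dim(W)[4]; cout <- dim(W)[5]
  n <- prod(d[1:3])
  p <- (k - 1L) %/% 2L
  dm <- dout; dim(dm) <- c(n, cout)
  dW <- array(0, dim(W))
  db <- .colSums(dm, n, cout)
  xp <- cache$xp
  dxp <- if (need_dx) array(0, c(d[1:3] + 2L * p, cin))
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
    sl <- xp[a:(a + d[1] - 1L), bb:(bb + d[2] - 1L), cc:(cc + d[3] - 1L), , drop = FALSE]
    dim(sl) <- c(n, cin)
    dW[a, bb, cc, , ] <- crossprod(sl, dm)
    if (need_dx) {
      g <- dm %*% t(matrix(W[a, bb, cc, , ], cin, cout))
      dim(g) <- c(d[1:3], cin)
      ia <- a:(a + d[1] - 1L); ib <- bb:(bb + d[2] - 1L); ic <- cc:(cc + d[3] - 1L)
      dxp[ia, ib, ic, ] <- dxp[ia, ib, ic, , drop = FALSE] + g
    }
  }
  dx <- NULL
  if (need_dx) {
    dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- group normalization ------------------------------------------------

groupnorm_forward <- function(x, gamma, beta, max_groups = 32L, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]; n <- prod(d[1:3])
  g <- largest_divisor_leq(C, max_groups)
  res <- .gn_fwd_cpp(x, n, C, g, gamma, beta, eps)
  list(out = res$out,
       cache = list(x = x, mu = res$mu, istd = res$istd, d = d, g = g,
                    gamma = gamma))
}

groupnorm_backward <- function(cache, dout) {
  d <- cache$d
  C <- d[4]; n <- prod(d[1:3])
  res <- .gn_bwd_cpp(cache$x, cache$mu, cache$istd, cache$gamma, dout,
                     n, C, cache$g)
  list(dx = res$dx, dgamma = res$dgamma, dbeta = res$dbeta)
}

# ---- ReLU and dropout ---------------------------------------------------

relu_forward <- function(x) {
  out <- .relu_fwd_cpp(x)
  list(out = out, cache = out)  # out > 0 recovers the mask exactly
}

relu_backward <- function(cache, dout) .relu_bwd_cpp(cache, dout)

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  res <- .dropout_fwd_cpp(x, rate)
  list(out = res$out, cache = res$mask)
}

dropout_backward <- function(cache, dout) {
  if (is.null(cache)) return(dout)
  .mul_cpp(dout, cache)
}

# ---- dual max/average pooling (2x2x2, stride 2) -------------------------

# Downsampling concatenates a 2x2x2 max-pool branch and a 2x2x2 average-pool
# branch, halving each spatial dimension and doubling the channel count
# (max channels first, then average).
pool_dual_forward <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) fail_validation("pooling requires even spatial dimensions")
  res <- .pool_dual_fwd_cpp(x, d)
  list(out = res$out, cache = list(best = res$best, d = d))
}

pool_dual_backward <- function(cache, dout) {
  .pool_dual_bwd_cpp(dout, cache$best, cache$d)
}

# ---- x2 upsampling (nearest, trilinear) ---------------------------------

# Nearest-neighbour doubling and half-voxel trilinear doubling, with their
# exact adjoints for the backward pass.
upsample2_forward <- function(x, mode) {
  d <- dim(x)
  if (mode == "nearest") .up2_nn_fwd_cpp(x, d) else .up2_lin_fwd_cpp(x, d)
}

upsample2_backward <- function(dout, in_dims, mode) {
  if (mode == "nearest") .up2_nn_bwd_cpp(dout, in_dims) else .up2_lin_bwd_cpp(dout, in_dims)
}

# ---- transposed convolution (2x2x2 kernel, stride 2) --------------------

tconv2_forward <- function(x, W, b) {
  if (isTRUE(getOption("adaptdose.conv_ref"))) return(tconv2_forward_ref(x, W, b))
  d <- dim(x)
  list(out = .tconv2_fwd_cpp(x, d, W, b), cache = list(x = x, d = d))
}

tconv2_backward <- function(cache, W, dout, need_dx = TRUE) {
  if (!is.null(cache$ref)) return(tconv2_backward_ref(cache, W, dout, need_dx))
  res <- .tconv2_bwd_cpp(cache$x, cache$d, W, dout, need_dx)
  list(dx = if (need_dx) res$dx, dW = res$dW, db = res$db)
}

# all-double reference transposed convolution (test oracle)
tconv2_forward_ref <- function(x, W, b) {
  d <- dim(x)
  cin <- dim(W)[4]; cout <- dim(W)[5]
  n <- prod(d[1:3])
  xm <- x; dim(xm) <- c(n, cin)
  out <- array(0, c(2L * d[1:3], cout))
  for (a in 1:2) for (bb in 1:2) for (cc in 1:2) {
    sub <- xm %*% matrix(W[a, bb, cc, , ], cin, cout) + rep(b, each = n)
    dim(sub) <- c(d[1:3], cout)
    out[seq(a, 2L * d[1], 2L), seq(bb, 2L * d[2], 2L), seq(cc, 2L * d[3], 2L), ] <- sub
  }
  list(out = out, cache = list(xm = xm, d = d, ref = TRUE))
}

tconv2_backward_ref <- function(cache, W, dout, need_dx = TRUE) {
  d <- cache$d
  cin <- dim(W)[4]; cout <- dim(W)[5]
  n <- prod(d[1:3])
  dW <- array(0, dim(W))
  db <- numeric(cout)
  dxm <- if (need_dx) matrix(0, n, cin)
  for (a in 1:2) for (bb in 1:2) for (cc in 1:2) {
    sub <- dout[seq(a, 2L * d[1], 2L), seq(bb, 2L * d[2], 2L), seq(cc, 2L * d[3], 2L), , drop = FALSE]
    dim(sub) <- c(n, cout)
    dW[a, bb, cc, , ] <- crossprod(cache$xm, sub)
    db <- db + .colSums(sub, n, cout)
    if (need_dx) dxm <- dxm + sub %*% t(matrix(W[a, bb, cc, , ], cin, cout))
  }
  dx <- NULL
  if (need_dx) { dx <- dxm; dim(dx) <- c(d[1:3], cin) }
  list(dx = dx, dW = dW, db = db)
}

concat_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:3]
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  out <- do.call(c, parts)  # channel blocks are contiguous (channel-last)
  dim(out) <- c(d, sum(cs))
  out
}

split_channels <- function(dout, sizes) {
  d <- dim(dout)
  n <- prod(d[1:3])
  at <- 0L
  lapply(sizes, function(sz) {
    res <- dout[(at * n + 1L):((at + sz) * n)]
    at <<- at + sz
    dim(res) <- c(d[1:3], sz)
    res
  })
}
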