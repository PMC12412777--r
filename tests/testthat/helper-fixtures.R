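# Shared fixture builders. Everything is generated in code at test time.

# A small valid session with a few contoured structures.
make_session <- function(d = c(10, 8, 6), spacing = c(5, 5, 5),
                         kind = "adaptive", with_dose = FALSE, seed = 42) {
  set.seed(seed)
  ct <- array(rnorm(prod(d), mean = 30, sd = 100), d)
  body <- array(1, d)
  cord <- array(0, d)
  cord[4:6, 4:5, ] <- 1
  parotid <- array(0, d)
  parotid[1:3, 1:3, 2:4] <- 1
  ptv <- array(0, d)
  ptv[5:8, 3:6, 2:5] <- 60
  dose <- NULL
  if (with_dose) dose <- array(abs(rnorm(prod(d), 30, 10)), d)
  plan_session(
    ct = ct,
    oar_masks = list(body = body, spinal_cord = cord, parotid_left = parotid),
    ptv_map = ptv, spacing = spacing, session_kind = kind,
    dose = dose, patient_id = "PTEST"
  )
}

# Brute-force all-pairs Euclidean distance (mm) to the nearest mask voxel.
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- sqrt(((i - idx[, 1]) * spacing[1])^2 +
                 ((j - idx[, 2]) * spacing[2])^2 +
                 ((k - idx[, 3]) * spacing[3])^2)
    out[i, j, k] <- min(dd)
  }
  out
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Small random dose/mask fixture for dosimetry properties.
random_dose_fixture <- function(n_vox = 50, max_dose = 70) {
  list(dose = runif(n_vox, 0, max_dose))
}

tiny_network_config <- function(base_width = 4L, n_levels = 2L,
                                in_primary = 3L, in_secondary = 4L, ...) {
  network_config(
    in_channels_primary = in_primary, in_channels_secondary = in_secondary,
    base_width = base_width, n_levels = n_levels, norm_groups = 4L, ...
  )
}
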