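#' Depth-scaled dropout specification
#'
#' Block dropout whose rate grows with layer width, giving stronger
#' regularization in deeper (wider) layers:
#' `rate = max_rate * (num_filters / max_filters)^power`.
#'
#' @param max_rate Maximum dropout rate (at the widest layer); default 0.05.
#' @param power Exponent of the width ratio; default 0.25.
#' @param max_filters Width of the deepest level; if `NULL`, derived from the
#'   network config as `base_width * 2^(n_levels - 1)`.
#' @return An object of class `dropout_spec`.
#' @export
dropout_spec <- function(max_rate = 0.05, power = 0.25, max_filters = NULL) {
  if (max_rate < 0 || max_rate > 1) fail_validation("max_rate must be in [0, 1]")
  structure(list(max_rate = max_rate, power = power, max_filters = max_filters),
            class = "dropout_spec")
}

#' Width-dependent dropout rate
#'
#' @param num_filters Number of filters of the layer (> 0).
#' @param spec A [dropout_spec()] with `max_filters` set.
#' @return The dropout probability for that layer.
#' @examples
#' dropout_rate(512, dropout_spec(max_filters = 512)) # 0.05
#' @export
dropout_rate <- function(num_filters, spec) {
  if (num_filters <= 0) fail_validation("num_filters must be > 0")
  if (is.null(spec$max_filters)) fail_validation("dropout_spec has no max_filters")
  spec$max_rate * (num_filters / spec$max_filters)^spec$power
}

#' Network architecture configuration
#'
#' Hyperparameters shared by the baseline U-Net and MHU-Net. Defaults follow
#' the full-scale architecture: 90 primary input channels (44 OAR masks +
#' 44 distance maps + PTV + CT), 91 secondary channels (adds the
#' pre-treatment dose), base width 64 doubling over 4 levels, group
#' normalization with up to 32 groups (the effective group count is the
#' largest divisor of the channel count not exceeding `norm_groups`, so
#' reduced test-scale widths normalize cleanly), 3x3x3 convolutions and a
#' 1x1x1 output head.
#'
#' @param in_channels_primary,in_channels_secondary Input channel counts.
#' @param base_width Filters at the first level (doubles per level).
#' @param n_levels Number of encoder levels including the bottleneck (>= 2).
#' @param norm_groups Maximum group count for group normalization.
#' @param dropout A [dropout_spec()].
#' @param final_relu Apply ReLU after the 1x1x1 output convolution so the
#'   predicted dose is non-negative (default `TRUE`).
#' @param decoder_norm Normalize decoder blocks as well as encoder blocks.
#' @param bypass_stream Add the optional skip-free upsampling stream from the
#'   bottleneck, merged before the output head (off by default).
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels_primary = 90L, in_channels_secondary = 91L,
                           base_width = 64L, n_levels = 4L, norm_groups = 32L,
                           dropout = dropout_spec(), final_relu = TRUE,
                           decoder_norm = TRUE, bypass_stream = FALSE) {
  if (n_levels < 2L) fail_validation("n_levels must be >= 2")
  if (base_width < 1L) fail_validation("base_width must be >= 1")
  if (is.null(dropout$max_filters)) {
    dropout$max_filters <- base_width * 2^(n_levels - 1L)
  }
  structure(
    list(
      in_channels_primary = as.integer(in_channels_primary),
      in_channels_secondary = as.integer(in_channels_secondary),
      base_width = as.integer(base_width), n_levels = as.integer(n_levels),
      norm_groups = as.integer(norm_groups), dropout = dropout,
      final_relu = isTRUE(final_relu), decoder_norm = isTRUE(decoder_norm),
      bypass_stream = isTRUE(bypass_stream)
    ),
    class = "network_config"
  )
}

level_widths <- function(cfg) cfg$base_width * 2^(seq_len(cfg$n_levels) - 1L)

# ---- parameter initialization -------------------------------------------

init_conv <- function(k, cin, cout) {
  list(W = array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))), c(k, k, k, cin, cout)),
       b = numeric(cout))
}

add_conv_block <- function(P, nm, k, cin, cout, norm = TRUE) {
  cv <- init_conv(k, cin, cout)
  P[[paste0(nm, ".W")]] <- cv$W
  P[[paste0(nm, ".b")]] <- cv$b
  if (norm) {
    P[[paste0(nm, ".g")]] <- rep(1, cout)
    P[[paste0(nm, ".be")]] <- rep(0, cout)
  }
  P
}

decoder_params <- function(P, cfg) {
  w <- level_widths(cfg)
  L <- cfg$n_levels
  for (l in seq(L - 1L, 1L)) {
    P[[paste0("dec", l, ".t.W")]] <- init_conv(2L, w[l + 1L], w[l + 1L])$W
    P[[paste0("dec", l, ".t.b")]] <- numeric(w[l + 1L])
    cat_in <- 3L * w[l + 1L] + w[l]
    P <- add_conv_block(P, paste0("dec", l, ".c1"), 3L, cat_in, w[l], cfg$decoder_norm)
    P <- add_conv_block(P, paste0("dec", l, ".c2"), 3L, w[l], w[l], cfg$decoder_norm)
  }
  if (cfg$bypass_stream) {
    for (l in seq(L - 1L, 1L)) {
      cin <- if (l == L - 1L) w[L] else w[l + 1L]
      P <- add_conv_block(P, paste0("byp", l), 1L, cin, w[l], norm = FALSE)
    }
  }
  final_in <- w[1L] * (1L + cfg$bypass_stream)
  P <- add_conv_block(P, "final", 1L, final_in, 1L, norm = FALSE)
  # start the output head active: with a ReLU output and a zero bias the
  # whole network can initialize dead (output identically zero gives a zero
  # gradient through the ReLU mask), so bias toward a small positive dose
  if (cfg$final_relu) P[["final.b"]] <- 0.1
  P
}

#' Build the baseline single-head 3D U-Net
#'
#' Single encoder (widths `base_width * 2^level`), downsampling by
#' concatenated 2x2x2 max and average pooling (channel count doubles),
#' bottleneck, and a decoder whose upsampling concatenates nearest-neighbour
#' interpolation, trilinear interpolation and a stride-2 transposed
#' convolution, merged with the encoder skip at the same level. A 1x1x1
#' convolution (optionally followed by ReLU) produces the single-channel
#' dose map at input resolution.
#'
#' @param config A [network_config()].
#' @param seed Optional integer; seeds the He-style (fan-in) initialization.
#' @return An object of class `dose_net` (`kind = "unet"`).
#' @export
build_unet <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- level_widths(config)
  P <- list()
  for (l in seq_len(config$n_levels)) {
    cin <- if (l == 1L) config$in_channels_primary else w[l]
    P <- add_conv_block(P, paste0("enc", l, ".c1"), 3L, cin, w[l])
    P <- add_conv_block(P, paste0("enc", l, ".c2"), 3L, w[l], w[l])
  }
  P <- decoder_params(P, config)
  structure(list(kind = "unet", config = config, params = P), class = "dose_net")
}

#' Build the dual-head MHU-Net
#'
#' Two parallel encoders: the primary head ingests the adaptive-session
#' assembly (90 channels) and the secondary head the pre-treatment plan
#' assembly (91 channels, including the approved dose). At each of the first
#' `n_levels - 1` levels the secondary head's downsampled feature maps are
#' copied and concatenated with the primary head's before the next primary
#' block, whose convolutions project back to the nominal level width; after
#' the last downsampling both streams merge into a single bottleneck. One
#' shared decoder with skip connections from the primary encoder mirrors
#' [build_unet()].
#'
#' @inheritParams build_unet
#' @return An object of class `dose_net` (`kind = "mhunet"`).
#' @export
build_mhunet <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- level_widths(config)
  L <- config$n_levels
  P <- list()
  for (l in seq_len(L - 1L)) {
    cin <- if (l == 1L) config$in_channels_secondary else w[l]
    P <- add_conv_block(P, paste0("sec", l, ".c1"), 3L, cin, w[l])
    P <- add_conv_block(P, paste0("sec", l, ".c2"), 3L, w[l], w[l])
  }
  for (l in seq_len(L)) {
    cin <- if (l == 1L) config$in_channels_primary else 2L * w[l]
    P <- add_conv_block(P, paste0("enc", l, ".c1"), 3L, cin, w[l])
    P <- add_conv_block(P, paste0("enc", l, ".c2"), 3L, w[l], w[l])
  }
  P <- decoder_params(P, config)
  structure(list(kind = "mhunet", config = config, params = P), class = "dose_net")
}

#' @export
print.dose_net <- function(x, ...) {
  cat(sprintf("<dose_net> %s  base_width %d, %d levels, %s parameters\n",
              x$kind, x$config$base_width, x$config$n_levels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `dose_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, numeric(1)))

# ---- composite blocks ----------------------------------------------------

cbr_fwd <- function(x, P, nm, cfg, rate, train, norm = TRUE, keep = TRUE) {
  cv <- conv3_forward(x, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]], keep_cache = keep)
  h <- cv$out
  gn <- NULL
  if (norm) {
    gn <- groupnorm_forward(h, P[[paste0(nm, ".g")]], P[[paste0(nm, ".be")]], cfg$norm_groups)
    h <- gn$out
  }
  rl <- relu_forward(h)
  dp <- dropout_forward(rl$out, rate, train)
  list(out = dp$out,
       cache = if (keep) list(cv = cv$cache, gn = gn$cache, rl = rl$cache,
                              dp = dp$cache, norm = norm, nm = nm))
}

acc_grad <- function(gr, name, val) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

cbr_bwd <- function(cache, P, dout, gr, need_dx = TRUE) {
  nm <- cache$nm
  dout <- dropout_backward(cache$dp, dout)
  dout <- relu_backward(cache$rl, dout)
  if (cache$norm) {
    gb <- groupnorm_backward(cache$gn, dout)
    acc_grad(gr, paste0(nm, ".g"), gb$dgamma)
    acc_grad(gr, paste0(nm, ".be"), gb$dbeta)
    dout <- gb$dx
  }
  cb <- conv3_backward(cache$cv, P[[paste0(nm, ".W")]], dout, need_dx = need_dx)
  acc_grad(gr, paste0(nm, ".W"), cb$dW)
  acc_grad(gr, paste0(nm, ".b"), cb$db)
  cb$dx
}

enc_level_fwd <- function(x, P, nm, cfg, rate, train, keep = TRUE) {
  b1 <- cbr_fwd(x, P, paste0(nm, ".c1"), cfg, rate, train, keep = keep)
  b2 <- cbr_fwd(b1$out, P, paste0(nm, ".c2"), cfg, rate, train, keep = keep)
  list(out = b2$out, cache = if (keep) list(b1 = b1$cache, b2 = b2$cache))
}

enc_level_bwd <- function(cache, P, dout, gr, need_dx = TRUE) {
  dout <- cbr_bwd(cache$b2, P, dout, gr, need_dx = TRUE)
  cbr_bwd(cache$b1, P, dout, gr, need_dx = need_dx)
}

# upsample (3 branches) + skip concat + two conv blocks
dec_level_fwd <- function(x, skip, P, l, cfg, rate, train, keep = TRUE) {
  nmt <- paste0("dec", l, ".t")
  nn_up <- upsample2_forward(x, "nearest")
  tri_up <- upsample2_forward(x, "linear")
  tc <- tconv2_forward(x, P[[paste0(nmt, ".W")]], P[[paste0(nmt, ".b")]])
  cat_in <- concat_channels(nn_up, tri_up, tc$out, skip)
  b1 <- cbr_fwd(cat_in, P, paste0("dec", l, ".c1"), cfg, rate, train,
                norm = cfg$decoder_norm, keep = keep)
  b2 <- cbr_fwd(b1$out, P, paste0("dec", l, ".c2"), cfg, rate, train,
                norm = cfg$decoder_norm, keep = keep)
  list(out = b2$out,
       cache = if (keep) list(b1 = b1$cache, b2 = b2$cache, tc = tc$cache,
                              in_dims = dim(x), skip_c = dim(skip)[4], l = l))
}

# returns list(dx = gradient wrt the upsampled input, dskip = skip gradient)
dec_level_bwd <- function(cache, P, dout, gr) {
  dout <- cbr_bwd(cache$b2, P, dout, gr, need_dx = TRUE)
  dcat <- cbr_bwd(cache$b1, P, dout, gr, need_dx = TRUE)
  cu <- cache$in_dims[4]
  parts <- split_channels(dcat, c(cu, cu, cu, cache$skip_c))
  nmt <- paste0("dec", cache$l, ".t")
  tb <- tconv2_backward(cache$tc, P[[paste0(nmt, ".W")]], parts[[3]], need_dx = TRUE)
  acc_grad(gr, paste0(nmt, ".W"), tb$dW)
  acc_grad(gr, paste0(nmt, ".b"), tb$db)
  dx <- upsample2_backward(parts[[1]], cache$in_dims, "nearest") +
    upsample2_backward(parts[[2]], cache$in_dims, "linear") +
    tb$dx
  list(dx = dx, dskip = parts[[4]])
}

final_fwd <- function(x, P, cfg, keep = TRUE) {
  cv <- conv3_forward(x, P[["final.W"]], P[["final.b"]], keep_cache = keep)
  if (cfg$final_relu) {
    rl <- relu_forward(cv$out)
    list(out = rl$out, cache = if (keep) list(cv = cv$cache, rl = rl$cache))
  } else {
    list(out = cv$out, cache = if (keep) list(cv = cv$cache, rl = NULL))
  }
}

final_bwd <- function(cache, P, dout, gr) {
  if (!is.null(cache$rl)) dout <- relu_backward(cache$rl, dout)
  cb <- conv3_backward(cache$cv, P[["final.W"]], dout, need_dx = TRUE)
  acc_grad(gr, "final.W", cb$dW)
  acc_grad(gr, "final.b", cb$db)
  cb$dx
}

bypass_fwd <- function(bottleneck, P, cfg, rate_fun, train, keep = TRUE) {
  L <- cfg$n_levels
  z <- bottleneck
  caches <- list()
  for (l in seq(L - 1L, 1L)) {
    in_dims <- dim(z)
    z <- upsample2_forward(z, "linear")
    b <- cbr_fwd(z, P, paste0("byp", l), cfg, rate_fun(l), train, norm = FALSE, keep = keep)
    z <- b$out
    caches[[as.character(l)]] <- list(b = b$cache, in_dims = in_dims)
  }
  list(out = z, cache = if (keep) caches)
}

bypass_bwd <- function(cache, P, dout, gr) {
  L <- length(cache) + 1L
  for (l in seq_len(L - 1L)) {
    cc <- cache[[as.character(l)]]
    dout <- cbr_bwd(cc$b, P, dout, gr, need_dx = TRUE)
    dout <- upsample2_backward(dout, cc$in_dims, "linear")
  }
  dout
}

check_spatial <- function(dims, cfg) {
  f <- 2^(cfg$n_levels - 1L)
  if (any(dims[1:3] %% f != 0)) {
    fail_validation(sprintf(
      "spatial dims (%s) must be divisible by %d for %d levels",
      paste(dims[1:3], collapse = "x"), f, cfg$n_levels))
  }
}

# ---- whole-network forward / backward -----------------------------------

net_forward <- function(model, primary, secondary = NULL, train = FALSE,
                        keep = FALSE, trace = FALSE) {
  cfg <- model$config
  P <- model$params
  check_spatial(dim(primary), cfg)
  L <- cfg$n_levels
  w <- level_widths(cfg)
  rate <- function(l) dropout_rate(w[l], cfg$dropout)
  tape <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  trc <- if (trace) list()
  tr <- function(stage, x) {
    if (trace) trc[[stage]] <<- dim(x)
    invisible(NULL)
  }

  if (model$kind == "mhunet") {
    if (is.null(secondary)) fail_validation("mhunet forward requires the secondary input")
    s_pool <- list()
    s_cur <- secondary
    tape$sec <- list(); tape$sec_pool <- list()
    for (l in seq_len(L - 1L)) {
      sl <- enc_level_fwd(s_cur, P, paste0("sec", l), cfg, rate(l), train, keep)
      tr(paste0("sec", l, ".conv"), sl$out)
      pl <- pool_dual_forward(sl$out)
      tr(paste0("sec", l, ".down"), pl$out)
      s_pool[[l]] <- pl$out
      s_cur <- pl$out
      if (keep) { tape$sec[[l]] <- sl$cache; tape$sec_pool[[l]] <- pl$cache }
    }
  }

  cur <- primary
  for (l in seq_len(L)) {
    if (l > 1L) {
      pl <- pool_dual_forward(skips[[l - 1L]])
      tr(paste0("enc", l - 1L, ".down"), pl$out)
      if (keep) tape$pool[[l - 1L]] <- pl$cache
      cur <- if (model$kind == "mhunet") {
        fused <- concat_channels(pl$out, s_pool[[l - 1L]])
        tr(paste0("fuse", l - 1L), fused)
        fused
      } else pl$out
    }
    el <- enc_level_fwd(cur, P, paste0("enc", l), cfg, rate(l), train, keep)
    tr(paste0("enc", l, ".conv"), el$out)
    if (keep) tape$enc[[l]] <- el$cache
    if (l < L) skips[[l]] <- el$out else cur <- el$out
  }
  bottleneck <- cur
  tr("bottleneck", bottleneck)

  for (l in seq(L - 1L, 1L)) {
    dl <- dec_level_fwd(cur, skips[[l]], P, l, cfg, rate(l), train, keep)
    tr(paste0("dec", l, ".conv"), dl$out)
    if (keep) tape$dec[[l]] <- dl$cache
    cur <- dl$out
  }

  if (cfg$bypass_stream) {
    bp <- bypass_fwd(bottleneck, P, cfg, rate, train, keep)
    if (keep) tape$bypass <- bp$cache
    cur <- concat_channels(cur, bp$out)
  }
  fv <- final_fwd(cur, P, cfg, keep)
  if (keep) tape$final <- fv$cache
  out <- fv$out
  tr("output", out)
  dim(out) <- dim(out)[1:3]
  list(out = out, tape = if (keep) tape, trace = if (trace) trc)
}

net_backward <- function(model, tape, dout) {
  cfg <- model$config
  P <- model$params
  L <- cfg$n_levels
  w <- level_widths(cfg)
  gr <- new.env(parent = emptyenv())
  dim(dout) <- c(dim(dout), 1L)

  dcur <- final_bwd(tape$final, P, dout, gr)
  if (cfg$bypass_stream) {
    parts <- split_channels(dcur, c(w[1L], w[1L]))
    dcur <- parts[[1]]
    dbottleneck_bp <- bypass_bwd(tape$bypass, P, parts[[2]], gr)
  }

  dskips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    db <- dec_level_bwd(tape$dec[[l]], P, dcur, gr)
    dskips[[l]] <- db$dskip
    dcur <- db$dx
  }
  # dcur is now the gradient at the bottleneck output
  if (cfg$bypass_stream) dcur <- dcur + dbottleneck_bp

  ds_pool <- if (model$kind == "mhunet") vector("list", L - 1L)
  for (l in seq(L, 1L)) {
    need_dx <- l > 1L
    din <- enc_level_bwd(tape$enc[[l]], P, dcur, gr, need_dx = need_dx)
    if (l > 1L) {
      if (model$kind == "mhunet") {
        np <- 2L * w[l - 1L]
        parts <- split_channels(din, c(np, np))
        dpool <- parts[[1]]
        ds_pool[[l - 1L]] <- parts[[2]]
      } else dpool <- din
      dprev <- pool_dual_backward(tape$pool[[l - 1L]], dpool)
      dcur <- dprev + dskips[[l - 1L]]
    }
  }

  if (model$kind == "mhunet") {
    dnext <- NULL  # gradient flowing from sec level l+1 into s_pool[l]
    for (l in seq(L - 1L, 1L)) {
      dsp <- ds_pool[[l]]
      if (!is.null(dnext)) dsp <- dsp + dnext
      dsl <- pool_dual_backward(tape$sec_pool[[l]], dsp)
      dnext <- enc_level_bwd(tape$sec[[l]], P, dsl, gr, need_dx = l > 1L)
    }
  }
  as.list(gr)
}

# ---- shape audit ---------------------------------------------------------

#' Per-level shape table for a network
#'
#' Symbolically audits the architecture: for each stage reports the channel
#' count and spatial dimensions of the feature map a forward pass produces on
#' an input of `input_shape`. This is the table used to check the printed
#' tensor shapes (e.g. 64 channels at full resolution after the first
#' encoder level, 128 after the first dual-pooling downsampling, a
#' 512-channel bottleneck at 1/8 resolution, and a 1-channel output at input
#' resolution for the full-scale configuration).
#'
#' @param model A `dose_net`, or a `network_config` plus `kind`.
#' @param input_shape Spatial input shape (default `c(96, 96, 64)`).
#' @param kind Used when `model` is a `network_config`.
#' @return A tibble with columns `stage`, `head`, `channels`, `nx`, `ny`, `nz`.
#' @export
model_summary <- function(model, input_shape = c(96, 96, 64), kind = NULL) {
  if (inherits(model, "network_config")) {
    cfg <- model
    kind <- kind %||% "mhunet"
  } else {
    cfg <- model$config
    kind <- model$kind
  }
  check_spatial(c(input_shape, 1L), cfg)
  L <- cfg$n_levels
  w <- level_widths(cfg)
  rows <- list()
  add <- function(stage, head, ch, sp) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = stage, head = head, channels = as.integer(ch),
      nx = as.integer(sp[1]), ny = as.integer(sp[2]), nz = as.integer(sp[3]))
  }
  sp <- input_shape
  add("input", "primary", cfg$in_channels_primary, sp)
  if (kind == "mhunet") add("input", "secondary", cfg$in_channels_secondary, sp)
  for (l in seq_len(L)) {
    if (l > 1L) {
      sp <- sp / 2
      add(paste0("down", l - 1L), "primary", 2L * w[l - 1L], sp)
      if (kind == "mhunet") {
        add(paste0("down", l - 1L), "secondary", 2L * w[l - 1L], sp)
        add(paste0("fuse", l - 1L), "merged", 4L * w[l - 1L], sp)
      }
    }
    add(paste0("enc", l, ".conv"), "primary", w[l], sp)
    if (kind == "mhunet" && l < L) add(paste0("sec", l, ".conv"), "secondary", w[l], sp)
  }
  add("bottleneck", "merged", w[L], sp)
  for (l in seq(L - 1L, 1L)) {
    sp <- sp * 2
    add(paste0("dec", l, ".upcat"), "decoder", 3L * w[l + 1L] + w[l], sp)
    add(paste0("dec", l, ".conv"), "decoder", w[l], sp)
  }
  add("output", "decoder", 1L, input_shape)
  dplyr::bind_rows(rows)
}

#' Runtime shape audit of a network
#'
#' Runs a real (traced) forward pass on synthetic inputs matching the
#' model's channel contract and returns the recorded per-stage tensor
#' shapes, for comparison against [model_summary()]'s symbolic table.
#' Channel counts are independent of the spatial extent, so a reduced
#' spatial size audits the full-scale channel schedule cheaply.
#'
#' @param model A `dose_net`.
#' @param input_shape Spatial input size (divisible by `2^(n_levels - 1)`).
#' @return A tibble with columns `stage`, `channels`, `nx`, `ny`, `nz`.
#' @export
audit_shapes <- function(model, input_shape = c(24, 24, 16)) {
  cfg <- model$config
  sp <- as.integer(rep_len(input_shape, 3L))
  primary <- array(runif(prod(sp) * cfg$in_channels_primary),
                   c(sp, cfg$in_channels_primary))
  secondary <- if (model$kind == "mhunet") {
    array(runif(prod(sp) * cfg$in_channels_secondary),
          c(sp, cfg$in_channels_secondary))
  }
  trc <- net_forward(model, primary, secondary, trace = TRUE)$trace
  dplyr::bind_rows(lapply(names(trc), function(st) {
    d <- trc[[st]]
    tibble::tibble(stage = st, channels = as.integer(d[4]),
                   nx = as.integer(d[1]), ny = as.integer(d[2]),
                   nz = as.integer(d[3]))
  }))
}
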