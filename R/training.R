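#' Mean-squared-error loss
#'
#' Sum of squared voxel-wise differences divided by the voxel count.
#'
#' @param predicted,target Arrays of identical shape.
#' @return Scalar loss.
#' @export
mse_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target)) {
    fail_validation("mse_loss: shape mismatch")
  }
  mean((predicted - target)^2)
}

#' Training configuration
#'
#' @param learning_rate Constant Adam learning rate (default 1e-4).
#' @param epochs Number of epochs (>= 1). One epoch draws one random patch
#'   from each training plan, in shuffled order, at batch size 1.
#' @param seed Integer seed; the whole run (initial patches, augmentation,
#'   dropout) is reproducible from it.
#' @param patch A [patch_spec()].
#' @param dose_norm Dose normalization constant in Gy (see
#'   [assemble_channels()]); losses are computed in normalized units.
#' @param dmap A [distance_map_spec()] used when assembling inputs.
#' @param include_pretreatment For MHU-Net, additionally use each
#'   pre-treatment plan as a self-conditioned training sample (the pre
#'   session feeds both heads and its own dose is the target). Default
#'   `TRUE` for MHU-Net, ignored for the baseline.
#' @param validate_every Compute the whole-volume validation loss every this
#'   many epochs (the final epoch is always validated); checkpoint selection
#'   considers validated epochs only.
#' @param checkpoint_dir Optional directory; the best-validation parameters
#'   are saved there as `best_checkpoint.rds`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 10L, seed = 1L,
                            patch = patch_spec(), dose_norm = 72,
                            dmap = distance_map_spec(),
                            include_pretreatment = TRUE,
                            validate_every = 1L,
                            checkpoint_dir = NULL) {
  if (learning_rate < 0) fail_validation("learning_rate must be >= 0")
  if (epochs < 1) fail_validation("epochs must be >= 1")
  if (validate_every < 1) fail_validation("validate_every must be >= 1")
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         seed = as.integer(seed), patch = patch, dose_norm = dose_norm,
         dmap = dmap, include_pretreatment = isTRUE(include_pretreatment),
         validate_every = as.integer(validate_every),
         checkpoint_dir = checkpoint_dir),
    class = "training_config"
  )
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0),  # zeros with the parameter's shape
       v = lapply(P, function(p) p * 0),
       t = 0L)
}

adam_step <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(G)) {
    g <- G[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(P = P, st = st)
}

# ---- sample preparation --------------------------------------------------

# Cached assemblies are stored packed: only the channels that are not
# identically zero (absent roster structures contribute 0-channels) are
# kept, cutting resident memory by ~4x for typical structure sets. Patches
# and tiles are expanded back to the full channel layout on extraction.
pack_channels <- function(x) {
  d <- dim(x)
  nz <- .nonzero_channels(x, prod(d[1:3]), d[4])
  structure(list(data = x[, , , nz, drop = FALSE], nz = nz,
                 dim = d), class = "packed_channels")
}

unpack_window <- function(pk, ix, iy, iz) {
  out <- array(0, c(length(ix), length(iy), length(iz), pk$dim[4]))
  out[, , , pk$nz] <- pk$data[ix, iy, iz, , drop = FALSE]
  out
}

extract_patch_packed <- function(pk, center, p) {
  crop <- extract_patch(pk$data, center, p)
  out <- array(0, c(p, pk$dim[4]))
  out[, , , pk$nz] <- crop
  out
}

as_sample <- function(primary, secondary, target_gy, ptv_map, dose_norm) {
  list(primary = pack_channels(primary$tensor),
       secondary = if (!is.null(secondary)) pack_channels(secondary$tensor),
       target = target_gy / dose_norm,
       ptv_map = ptv_map)
}

build_samples <- function(pairs, kind, cfg, include_pre) {
  samples <- list()
  for (pr in pairs) {
    prim <- assemble_channels(pr$adaptive, "primary", cfg$dmap, cfg$dose_norm)
    sec <- if (kind == "mhunet") {
      assemble_channels(pr$pre, "secondary", cfg$dmap, cfg$dose_norm)
    }
    samples[[length(samples) + 1L]] <-
      as_sample(prim, sec, pr$adaptive$dose, pr$adaptive$ptv_map, cfg$dose_norm)
    if (include_pre && kind == "mhunet") {
      pre_prim <- assemble_channels(pr$pre, "primary", cfg$dmap, cfg$dose_norm)
      samples[[length(samples) + 1L]] <-
        as_sample(pre_prim, sec, pr$pre$dose, pr$pre$ptv_map, cfg$dose_norm)
    }
  }
  samples
}

draw_patch <- function(sample, spec) {
  center <- sample_patch_center(sample$ptv_map, spec)
  p <- spec$patch_shape
  prim <- extract_patch_packed(sample$primary, center, p)
  sec <- if (!is.null(sample$secondary)) extract_patch_packed(sample$secondary, center, p)
  tgt <- extract_patch(sample$target, center, p)
  # one joint geometric transform across every input channel and the target
  tr <- draw_patch_transform(spec)
  list(primary = apply_patch_transform(prim, tr),
       secondary = if (!is.null(sec)) apply_patch_transform(sec, tr),
       target = apply_patch_transform(tgt, tr))
}

# ---- sliding-window inference (normalized units) ------------------------

tile_starts <- function(n, p) {
  if (n <= p) return(1L)
  st <- seq.int(1L, n - p + 1L, by = max(1L, p %/% 2L))
  sort(unique(c(st, n - p + 1L)))
}

pad_to <- function(x, target) {
  d <- dim(x)
  if (all(d[1:3] >= target)) return(x)
  out <- array(0, c(pmax(d[1:3], target), d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
  out
}

predict_norm <- function(model, primary, secondary, patch_shape) {
  if (!inherits(primary, "packed_channels")) primary <- pack_channels(primary)
  if (!is.null(secondary) && !inherits(secondary, "packed_channels")) {
    secondary <- pack_channels(secondary)
  }
  d0 <- primary$dim[1:3]
  p <- as.integer(rep_len(patch_shape, 3L))
  primary$data <- pad_to(primary$data, p)
  primary$dim[1:3] <- pmax(d0, p)
  if (!is.null(secondary)) {
    secondary$data <- pad_to(secondary$data, p)
    secondary$dim[1:3] <- pmax(d0, p)
  }
  d <- primary$dim[1:3]
  acc <- array(0, d)
  cnt <- array(0, d)
  for (sx in tile_starts(d[1], p[1]))
    for (sy in tile_starts(d[2], p[2]))
      for (sz in tile_starts(d[3], p[3])) {
        ix <- sx:(sx + p[1] - 1L); iy <- sy:(sy + p[2] - 1L); iz <- sz:(sz + p[3] - 1L)
        pf <- unpack_window(primary, ix, iy, iz)
        sf <- if (!is.null(secondary)) unpack_window(secondary, ix, iy, iz)
        fw <- net_forward(model, pf, sf, train = FALSE, keep = FALSE)
        acc[ix, iy, iz] <- acc[ix, iy, iz] + fw$out
        cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
      }
  out <- acc / cnt
  out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

#' Predict a dose volume
#'
#' Inference-mode forward pass (dropout disabled). Volumes larger than
#' `patch_shape` are predicted by sliding-window tiling with half-patch
#' stride and overlap averaging; a volume equal to the patch is a single
#' forward pass. The output is rescaled from normalized units to Gy and is
#' non-negative when the output-head ReLU is enabled.
#'
#' @param object A `dose_fit` (uses the best-validation parameters) or a
#'   `dose_net`.
#' @param primary `channel_assembly` (or raw 4D array) for the primary head.
#' @param secondary `channel_assembly`/array for the secondary head
#'   (required for MHU-Net).
#' @param patch_shape Tiling patch; defaults to the training patch for a
#'   `dose_fit`, or to the full volume for a bare model.
#' @param dose_norm Gy rescale constant; taken from the assembly/fit when
#'   available.
#' @return 3D dose array in Gy.
#' @export
predict_dose <- function(object, primary, secondary = NULL,
                         patch_shape = NULL, dose_norm = NULL) {
  if (inherits(object, "dose_fit")) {
    model <- object$model
    model$params <- object$best_params
    patch_shape <- patch_shape %||% object$config$patch$patch_shape
    dose_norm <- dose_norm %||% object$config$dose_norm
  } else if (inherits(object, "dose_net")) {
    model <- object
  } else fail_validation("predict_dose: need a dose_fit or dose_net")
  if (inherits(primary, "channel_assembly")) {
    dose_norm <- dose_norm %||% primary$dose_norm
    primary <- primary$tensor
  }
  if (inherits(secondary, "channel_assembly")) secondary <- secondary$tensor
  if (model$kind == "mhunet" && is.null(secondary)) {
    fail_validation("predict_dose: MHU-Net requires the secondary assembly")
  }
  dose_norm <- dose_norm %||% 72
  patch_shape <- patch_shape %||% dim(primary)[1:3]
  predict_norm(model, primary, secondary, patch_shape) * dose_norm
}

# ---- training loop -------------------------------------------------------

#' Train a dose-prediction network
#'
#' Adam at a constant learning rate, MSE loss, batch size 1, one random
#' augmented patch per training plan per epoch. Validation loss is computed
#' after every epoch on whole stitched volumes (deterministic, dropout off),
#' and the parameters with the lowest validation loss are retained as the
#' best checkpoint. The run is fully reproducible from `cfg$seed`.
#'
#' @param model A `dose_net` from [build_unet()] or [build_mhunet()].
#' @param train_pairs,val_pairs Lists of `plan_pair` objects (adaptive dose
#'   present; pre-treatment dose present for MHU-Net).
#' @param cfg A [training_config()].
#' @return An object of class `dose_fit`: the trained model, the
#'   best-validation parameters and epoch, and a per-epoch history tibble.
#' @export
train_model <- function(model, train_pairs, val_pairs, cfg = training_config()) {
  if (!length(train_pairs)) fail_validation("train_model: empty training set")
  set.seed(cfg$seed)
  include_pre <- cfg$include_pretreatment && model$kind == "mhunet"
  train_samples <- build_samples(train_pairs, model$kind, cfg, include_pre)
  val_samples <- build_samples(val_pairs, model$kind, cfg, include_pre = FALSE)

  P <- model$params
  st <- adam_init(P)
  history <- vector("list", cfg$epochs)
  best_val <- Inf
  best_params <- P
  best_epoch <- NA_integer_
  wm <- model

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_samples))
    losses <- numeric(length(ord))
    for (i in seq_along(ord)) {
      s <- train_samples[[ord[i]]]
      pt <- draw_patch(s, cfg$patch)
      wm$params <- P
      fw <- net_forward(wm, pt$primary, pt$secondary, train = TRUE, keep = TRUE)
      loss <- mse_loss(fw$out, pt$target)
      if (!is.finite(loss)) {
        abort(sprintf("train_model: non-finite loss at epoch %d step %d", ep, i))
      }
      losses[i] <- loss
      dout <- 2 * (fw$out - pt$target) / length(pt$target)
      G <- net_backward(wm, fw$tape, dout)
      upd <- adam_step(P, G, st, cfg$learning_rate)
      P <- upd$P
      st <- upd$st
    }
    wm$params <- P
    do_val <- length(val_samples) > 0 &&
      (ep %% cfg$validate_every == 0L || ep == cfg$epochs)
    val_loss <- if (do_val) {
      mean(vapply(val_samples, function(s) {
        mse_loss(predict_norm(wm, s$primary, s$secondary, cfg$patch$patch_shape),
                 s$target)
      }, numeric(1)))
    } else NA_real_
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(losses), val_loss = val_loss)
    if (is.finite(val_loss) && val_loss < best_val) {
      best_val <- val_loss
      best_params <- P
      best_epoch <- ep
    }
  }
  if (!is.finite(best_val)) { best_params <- P; best_epoch <- cfg$epochs }

  model$params <- P
  fit <- structure(
    list(model = model, best_params = best_params, best_epoch = best_epoch,
         best_val_loss = if (is.finite(best_val)) best_val else NA_real_,
         history = dplyr::bind_rows(history), config = cfg),
    class = "dose_fit"
  )
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(fit, file.path(cfg$checkpoint_dir, "best_checkpoint.rds"))
  }
  fit
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("<dose_fit> %s  %d epoch(s), best epoch %s (val loss %s)\n",
              x$model$kind, nrow(x$history), x$best_epoch,
              format(x$best_val_loss, digits = 4)))
  invisible(x)
}
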