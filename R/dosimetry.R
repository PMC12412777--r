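#' Cumulative dose-volume histogram
#'
#' For the voxels inside `mask`, computes the fraction of the structure
#' volume receiving at least each dose level, on a uniform grid from 0 to
#' the in-structure maximum. The curve starts at 1.0 at dose 0, is monotone
#' non-increasing, and reaches 0 above the structure maximum.
#'
#' @param dose 3D dose array (Gy).
#' @param mask 3D binary array, non-empty.
#' @param n_bins Number of uniform grid intervals (default 1000).
#' @param structure Optional structure name carried into the result.
#' @return A tibble of class `dvh_curve` with columns `dose_Gy` and
#'   `volume_fraction`, plus `structure` and `voxel_count` attributes.
#' @export
dvh <- function(dose, mask, n_bins = 1000L, structure = NA_character_) {
  if (!identical(vol_dim(dose), vol_dim(mask))) fail_validation("dvh: shape mismatch")
  if (!is_binary(mask)) fail_validation("dvh: mask must be binary")
  voxels <- dose[mask == 1]
  if (!length(voxels)) fail_validation("dvh: empty mask")
  top <- max(voxels)
  grid <- seq(0, max(top, .Machine$double.eps), length.out = n_bins + 1L)
  sorted <- sort(voxels)
  # fraction receiving >= t  =  1 - (# voxels with dose < t) / N
  frac <- 1 - findInterval(grid, sorted, left.open = TRUE) / length(sorted)
  out <- tibble::tibble(dose_Gy = grid, volume_fraction = frac)
  attr(out, "structure") <- structure
  attr(out, "voxel_count") <- length(voxels)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Dose at volume (Dx%)
#'
#' The minimum dose received by the hottest `x`% of the structure volume:
#' the largest dose `d` such that at least `x`% of voxels receive `>= d`.
#' Computed from the sorted voxel doses as the `(1 - x/100)` order statistic
#' with linear interpolation between adjacent sorted doses
#' (`stats::quantile` type 7); `D100%` is the structure minimum. Can also be
#' read off a [dvh()] curve, in which case the grid point whose volume
#' fraction first drops below `x`% bounds the answer within one bin.
#'
#' @param x A numeric vector of in-structure voxel doses, or a `dvh_curve`.
#' @param volume_pct Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(x, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100) {
    fail_validation("dose_at_volume: volume_pct must be in (0, 100]")
  }
  if (inherits(x, "dvh_curve")) {
    ok <- x$volume_fraction >= volume_pct / 100
    if (!any(ok)) return(x$dose_Gy[1])
    return(max(x$dose_Gy[ok]))
  }
  unname(quantile(as.numeric(x), probs = 1 - volume_pct / 100, type = 7))
}

#' Dose homogeneity index
#'
#' `(D2% - D98%) / D50%`: 0 for a perfectly uniform target dose, larger for
#' more heterogeneous coverage; invariant under dose rescaling.
#'
#' @param d2,d98,d50 Dose metrics in Gy (`d50 > 0`).
#' @return Dimensionless homogeneity index.
#' @export
homogeneity <- function(d2, d98, d50) {
  if (any(d50 <= 0)) fail_validation("homogeneity: D50% must be > 0")
  (d2 - d98) / d50
}

#' Prescription-normalized absolute percent error
#'
#' `|gt - pred| / highest_prescription * 100`, where the highest prescription
#' is the maximum prescribed dose within the patient's plan. Symmetric in
#' its first two arguments.
#'
#' @param gt,pred Dose metrics in Gy.
#' @param highest_prescription Patient's maximum prescription in Gy (> 0).
#' @return Percent error.
#' @export
percent_error <- function(gt, pred, highest_prescription) {
  if (any(highest_prescription <= 0)) {
    fail_validation("percent_error: highest_prescription must be > 0")
  }
  abs(gt - pred) / highest_prescription * 100
}

#' Per-structure dose metrics
#'
#' Computes Dmean, Dmax (maximum voxel dose), D99%, D98%, D95%, D50%, D2%
#' and the homogeneity index for each named structure mask. Structures with
#' empty masks are dropped.
#'
#' @param dose 3D dose array (Gy).
#' @param masks Named list of 3D binary masks.
#' @return A tibble with one row per structure.
#' @export
dose_metrics <- function(dose, masks) {
  rows <- purrr::imap(masks, function(m, nm) {
    v <- dose[m == 1]
    if (!length(v)) return(NULL)
    d2 <- dose_at_volume(v, 2); d98 <- dose_at_volume(v, 98); d50 <- dose_at_volume(v, 50)
    tibble::tibble(
      structure = nm, voxels = length(v),
      Dmean = mean(v), Dmax = max(v),
      D99 = dose_at_volume(v, 99), D98 = d98, D95 = dose_at_volume(v, 95),
      D50 = d50, D2 = d2,
      homogeneity = if (d50 > 0) (d2 - d98) / d50 else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Paired dosimetric comparison of two models
#'
#' For each structure, compares the prescription-normalized absolute percent
#' errors of Dmean and Dmax between two models against the common ground
#' truth, paired by patient: reports mean +/- SD of each model's errors and
#' the two-tailed Wilcoxon signed-rank p-value on the per-patient error
#' differences (zero differences dropped, the standard signed-rank
#' handling). When every difference is zero the comparison is degenerate and
#' p is reported as 1.
#'
#' @param gt_doses,pred_a,pred_b Lists of 3D dose arrays (Gy), one per
#'   patient, index-paired.
#' @param masks List (per patient) of named lists of binary masks.
#' @param prescriptions Numeric vector, each patient's highest prescription (Gy).
#' @param structures Structure names to compare (default: all appearing in
#'   every patient's mask list).
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `dose_comparison`: one row per structure and
#'   metric with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`,
#'   `significant` and `degenerate`.
#' @export
compare_plans <- function(gt_doses, pred_a, pred_b, masks, prescriptions,
                          structures = NULL, alpha = 0.05) {
  n <- length(gt_doses)
  if (length(pred_a) != n || length(pred_b) != n || length(masks) != n ||
      length(prescriptions) != n) {
    fail_validation("compare_plans: inputs must be paired by patient")
  }
  if (is.null(structures)) {
    structures <- Reduce(intersect, lapply(masks, names))
  }
  err <- list()
  for (i in seq_len(n)) {
    for (s in structures) {
      m <- masks[[i]][[s]]
      if (is.null(m) || sum(m) == 0) next
      v_gt <- gt_doses[[i]][m == 1]
      v_a <- pred_a[[i]][m == 1]
      v_b <- pred_b[[i]][m == 1]
      for (metric in c("Dmean", "Dmax")) {
        f <- if (metric == "Dmean") mean else max
        err[[length(err) + 1L]] <- tibble::tibble(
          patient = i, structure = s, metric = metric,
          err_a = percent_error(f(v_gt), f(v_a), prescriptions[i]),
          err_b = percent_error(f(v_gt), f(v_b), prescriptions[i])
        )
      }
    }
  }
  err <- dplyr::bind_rows(err)
  out <- err |>
    dplyr::group_by(.data$structure, .data$metric) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_a = mean(.data$err_a), sd_a = sd(.data$err_a),
      mean_b = mean(.data$err_b), sd_b = sd(.data$err_b),
      p_value = paired_wilcoxon_p(.data$err_a, .data$err_b),
      degenerate = all(.data$err_a == .data$err_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = .data$p_value < alpha & !.data$degenerate)
  class(out) <- c("dose_comparison", class(out))
  out
}

# Two-tailed paired Wilcoxon signed-rank p-value; zero differences dropped,
# ties mid-ranked. All-zero differences give the degenerate p = 1.
paired_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) return(1)
  res <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = length(d) <= 50)
  )
  unname(res$p.value)
}
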