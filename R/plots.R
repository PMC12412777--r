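# ggplot2 display methods and broom-style tidiers.

#' Plot a dose-volume histogram
#'
#' @param object A `dvh_curve` from [dvh()].
#' @param ... Further `dvh_curve` objects to overlay (named arguments become
#'   curve labels).
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(object), extra[vapply(extra, inherits, logical(1), "dvh_curve")])
  labels <- vapply(seq_along(curves), function(i) {
    nm <- if (i == 1) attr(object, "structure") else names(extra)[i - 1]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) paste0("curve", i) else nm
  }, character(1))
  df <- purrr::map2_dfr(curves, labels, function(cv, lb) {
    tibble::tibble(dose_Gy = cv$dose_Gy, volume_fraction = cv$volume_fraction,
                   structure = lb)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_Gy, .data$volume_fraction,
                                   colour = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume fraction ≥ dose",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot training and validation loss curves
#'
#' @param object A `dose_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dose_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "MSE (normalized dose)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a paired model comparison
#'
#' Mean absolute percent error (with SD error bars) of Dmean/Dmax per
#' structure for the two compared models; significant Wilcoxon differences
#' are starred.
#'
#' @param object A `dose_comparison` from [compare_plans()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dose_comparison <- function(object, ...) {
  df <- tidy.dose_comparison(object)
  star <- dplyr::filter(df, .data$model == "A" & .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(.data$structure, .data$mean_error,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_error - .data$sd_error, 0),
                   ymax = .data$mean_error + .data$sd_error),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::geom_text(data = star, ggplot2::aes(y = 0, label = "*"),
                       vjust = 1.2, size = 5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Absolute percent error (% of prescription)",
                  fill = "Model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tidy a fitted model's history
#'
#' @param x A `dose_fit`.
#' @param ... Ignored.
#' @return The per-epoch history tibble.
#' @export
tidy.dose_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x A `dose_fit`.
#' @param ... Ignored.
#' @return Tibble with model kind, epochs, best epoch/validation loss and
#'   parameter count.
#' @export
glance.dose_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$model$kind, epochs = nrow(x$history),
    best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy a model comparison into long format
#'
#' @param x A `dose_comparison`.
#' @param ... Ignored.
#' @return Tibble with one row per structure, metric and model.
#' @export
tidy.dose_comparison <- function(x, ...) {
  a <- dplyr::transmute(x, .data$structure, .data$metric, model = "A",
                        mean_error = .data$mean_a, sd_error = .data$sd_a,
                        p_value = .data$p_value, significant = .data$significant)
  b <- dplyr::transmute(x, .data$structure, .data$metric, model = "B",
                        mean_error = .data$mean_b, sd_error = .data$sd_b,
                        p_value = .data$p_value, significant = .data$significant)
  dplyr::bind_rows(a, b)
}

#' Per-layer parameter table
#'
#' @param x A `dose_net`.
#' @param ... Ignored.
#' @return Tibble with one row per parameter array.
#' @export
tidy.dose_net <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    n = vapply(x$params, length, numeric(1)),
    shape = vapply(x$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1))
  )
}
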