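#' Plot a complex field
#'
#' Raster view of a field's intensity, phase or amplitude.
#'
#' @param object A [complex_field()].
#' @param what `"intensity"`, `"phase"`, or `"amplitude"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complex_field <- function(object, what = c("intensity", "phase", "amplitude"), ...) {
  what <- match.arg(what)
  v <- switch(what,
    intensity = Mod(object$values)^2,
    phase = Arg(object$values),
    amplitude = Mod(object$values)
  )
  df <- tidyr::expand_grid(
    row = seq_len(nrow(v)), col = seq_len(ncol(v))
  )
  df$value <- as.vector(t(v))[(df$row - 1) * ncol(v) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and per-layer temperature trajectories of a fit.
#'
#' @param object A `d2nn_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted: loss, temperature).
#' @export
autoplot.d2nn_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(
    h,
    cols = -"epoch", names_to = "series", values_to = "value"
  )
  long <- dplyr::filter(
    long, .data$series %in% c("task_loss", "total") |
      startsWith(.data$series, "tau_")
  )
  long$panel <- ifelse(startsWith(long$series, "tau_"), "temperature", "loss")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot an evaluation result
#'
#' For quantitative phase imaging: the binned mean-absolute-phase-error
#' curve. For classification: per-class accuracy bars.
#'
#' @param object A `d2nn_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.d2nn_eval <- function(object, ...) {
  if (object$task == "qpi") {
    ggplot2::ggplot(
      dplyr::filter(object$phase_error, !is.na(.data$mae)),
      ggplot2::aes(x = .data$phase_mid, y = .data$mae)
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "ground-truth phase (rad)",
        y = "mean |phase error| (rad)"
      ) +
      ggplot2::theme_minimal()
  } else {
    acc <- dplyr::summarise(
      dplyr::group_by(object$samples, .data$label),
      accuracy = mean(.data$pred == .data$label), .groups = "drop"
    )
    ggplot2::ggplot(acc, ggplot2::aes(x = factor(.data$label), y = .data$accuracy)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "class", y = "accuracy") +
      ggplot2::theme_minimal()
  }
}

#' Plot a layer's deploy-condition phase mask
#'
#' @param model A [d2nn()].
#' @param layer Layer index.
#' @return A ggplot object.
#' @export
plot_phase_mask <- function(model, layer = 1L) {
  stopifnot(inherits(model, "d2nn"))
  m <- effective_phases(model, mode = "deploy")[[layer]]
  f <- complex_field(exp(1i * m), model$geom$pitch, model$geom$wavelength)
  autoplot.complex_field(f, what = "phase") +
    ggplot2::labs(title = sprintf("layer %d phase mask", layer))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
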