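#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a voltage trace
#'
#' @param object a `vc_trace`.
#' @param events optional [event_train()] to draw as an onset rug
#'   (excitatory up, inhibitory down); defaults to the events attached to
#'   the trace.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.vc_trace <- function(object, events = NULL, ...) {
  events <- events %||% attr(object, "events")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rug(
      data = as_tibble(events),
      ggplot2::aes(x = .data$onset_ms,
                   colour = .data$polarity),
      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.02, "npc")) +
      ggplot2::scale_colour_manual(values = c(exc = "forestgreen", inh = "firebrick"))
  }
  p
}

#' Plot a training history
#'
#' @param object a `vc_history` tibble from [train_surrogate()].
#' @param ... unused.
#' @export
autoplot.vc_history <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  d$step <- seq_len(nrow(object))[match(interaction(d$stage, d$epoch),
                                        interaction(object$stage, object$epoch))]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$loss,
                                  colour = .data$series,
                                  linetype = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch (cumulative)", y = "loss") +
    ggplot2::theme_minimal()
}

#' Heatmaps of a connectivity/excitation sweep
#'
#' Mean instability and immediate response over the sweep grid, one tile
#' per (excitation scale, connection probability) cell.
#'
#' @param object a `vc_sweep` from [run_rett_sweep()].
#' @param metric `"instability"` or `"immediate"`.
#' @param ... unused.
#' @export
autoplot.vc_sweep <- function(object, metric = c("instability", "immediate"),
                              ...) {
  metric <- match.arg(metric)
  d <- dplyr::summarise(
    dplyr::group_by(object, .data$exc_scale, .data$p_uni),
    value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$exc_scale),
                                  y = factor(.data$p_uni),
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "excitatory drive scale", y = "recurrent connectivity") +
    ggplot2::theme_minimal()
}

#' Plot a firing-response fit
#'
#' Data points with the fitted linear and logistic curves.
#'
#' @param object a `vc_firing_fit`.
#' @param ... unused.
#' @export
autoplot.vc_firing_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  curves <- tibble(x = xs,
                   linear = predict(object$linear, data.frame(x = xs)))
  if (!is.null(object$logistic)) {
    curves$logistic <- predict(object$logistic, data.frame(x = xs))
  }
  curves <- tidyr::pivot_longer(curves, -"x", names_to = "model",
                                values_to = "y")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, ggplot2::aes(colour = .data$model)) +
    ggplot2::labs(x = "input rate", y = "output rate") +
    ggplot2::theme_minimal()
}
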