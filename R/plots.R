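# ggplot2 views of traces, session logs, resistance series and fits.

#' Plot a current-clamp sweep
#'
#' Voltage and command current stacked as facets on the shared time axis.
#'
#' @param object A `cc_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cc_trace
#' @export
autoplot.cc_trace <- function(object, ...) {
  long <- tibble(
    time = rep(object$time, 2),
    value = c(object$voltage, object$current),
    channel = rep(c("voltage (mV)", "current (nA)"),
                  each = nrow(object))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y", switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a session log with its events
#'
#' The voltage/current log with ground-truth events (if attached) marked
#' as vertical lines.
#'
#' @param object A `cc_session`.
#' @param events Optional event tibble to mark (defaults to the attached
#'   ground truth).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cc_session
#' @export
autoplot.cc_session <- function(object, events = truth_events(object),
                                ...) {
  p <- autoplot.cc_trace(object)
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(time = events$time, kind = events$kind),
      ggplot2::aes(xintercept = .data$time, colour = .data$kind),
      linetype = "dashed", alpha = 0.8) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Plot a passive fit over its sweep
#'
#' The sweep around the step onset with the steady-state window, the
#' pre-step cubic extrapolation point, and the fitted exponential overlay.
#'
#' @param object An accepted `passive_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot passive_fit
#' @export
autoplot.passive_fit <- function(object, ...) {
  tr <- object$trace
  proto <- attr(tr, "protocol")
  p <- ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)") +
    ggplot2::theme_minimal()
  if (isTRUE(object$accepted)) {
    tt <- tr$time[tr$time >= proto$onset &
                    tr$time <= proto$onset + proto$duration]
    amp0 <- object$v_ss - object$v_rest - object$amplitude *
      object$r_a_error
    fit_v <- object$v_ss - amp0 * exp(-(tt - proto$onset) /
                                        (object$tau0 / 1000))
    p <- p +
      ggplot2::geom_line(data = tibble(time = tt, voltage = fit_v),
                         colour = "firebrick", linewidth = 0.4) +
      ggplot2::annotate("point", x = proto$onset, y = object$v_o,
                        colour = "steelblue", size = 2)
  }
  p
}

#' Plot a per-pulse resistance series
#'
#' @param series Output of [pulse_resistance_series()].
#' @param events Optional event tibble to mark.
#' @param log_y Log-scale the resistance axis (useful across seal
#'   formation).
#' @return A ggplot.
#' @export
plot_resistance <- function(series, events = NULL, log_y = TRUE) {
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$time, .data$r_total)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "total resistance (MOhm)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(time = events$time, kind = events$kind),
      ggplot2::aes(xintercept = .data$time, colour = .data$kind),
      linetype = "dashed") +
      ggplot2::labs(colour = "event")
  }
  p
}
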