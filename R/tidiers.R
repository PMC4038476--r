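# broom-style tidiers for the fitted objects.

#' Tidy a passive fit
#'
#' @param x A `passive_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter (`term`,
#'   `estimate`, `unit`).
#' @method tidy passive_fit
#' @export
tidy.passive_fit <- function(x, ...) {
  tibble(
    term = c("v_rest", "v_ss", "v_o", "tau0", "tau0_first", "r_a_error",
             "r_in"),
    estimate = c(x$v_rest, x$v_ss, x$v_o, x$tau0, x$tau0_first,
                 x$r_a_error, x$r_in),
    unit = c("mV", "mV", "mV", "ms", "ms", "MOhm", "MOhm")
  )
}

#' Fit-level summary of a passive fit
#'
#' @param x A `passive_fit`.
#' @param ... Unused.
#' @return One-row tibble with acceptance state, window, point count,
#'   log-fit r-squared, polarity and flags.
#' @method glance passive_fit
#' @export
glance.passive_fit <- function(x, ...) {
  tibble(accepted = x$accepted, reason = x$reason,
         fit_start = x$fit_window[1], fit_stop = x$fit_window[2],
         n_points = x$n_points, r2_log_fit = x$r2_log_fit,
         fast_membrane = x$fast_membrane, polarity = x$polarity,
         amplitude = x$amplitude)
}

#' @rdname tidy.passive_fit
#' @method tidy cell_passive
#' @export
tidy.cell_passive <- function(x, ...) {
  tibble(
    term = c("v_rest", "v_ss", "tau0", "r_a_error", "r_in"),
    estimate = c(x$v_rest, x$v_ss, x$tau0, x$r_a_error, x$r_in),
    unit = c("mV", "mV", "ms", "MOhm", "MOhm")
  )
}

#' @rdname glance.passive_fit
#' @method glance cell_passive
#' @export
glance.cell_passive <- function(x, ...) {
  tibble(n_traces = x$n_traces,
         n_depolarizing = sum(x$polarities["depolarizing"], na.rm = TRUE),
         n_hyperpolarizing = sum(x$polarities["hyperpolarizing"],
                                 na.rm = TRUE))
}

#' @rdname tidy.passive_fit
#' @method tidy ra_trend
#' @export
tidy.ra_trend <- function(x, ...) {
  tibble(term = c("ra_mean", "dra_dt"),
         estimate = c(x$ra_mean, x$dra_dt),
         std.error = c(NA_real_, x$slope_se),
         unit = c("MOhm", "MOhm/min"))
}

#' @rdname glance.passive_fit
#' @method glance ra_trend
#' @export
glance.ra_trend <- function(x, ...) {
  tibble(n = x$n)
}
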