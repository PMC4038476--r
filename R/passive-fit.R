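# Heuristic extraction of linear cell parameters from current-clamp step
# responses. The fast electrode artifact is discounted by ignoring the
# first part of the response rather than modeled: the log-linear membrane
# fit starts 0.5 ms after stimulus onset (second pass: onset + 20% of the
# first tau estimate), is extrapolated back to onset, and the gap to the
# pre-step voltage gives the residual access-resistance error.

#' Resting potential from pre-stimulus baselines
#'
#' Averages the pre-stimulus baseline of each trace, rejecting baselines
#' that contain spontaneous spikes (samples more than 20 mV above the
#' baseline median with a local slope above 10 mV/ms).
#'
#' @param traces A `cc_trace` or list of them; each needs at least
#'   `min_baseline_s` of pre-stimulus data.
#' @param min_baseline_s Minimum usable baseline length (s).
#' @return Resting potential (mV).
#' @export
estimate_v_rest <- function(traces, min_baseline_s = 0.05) {
  if (inherits(traces, "cc_trace")) traces <- list(traces)
  vals <- purrr::map_dbl(traces, function(tr) {
    proto <- attr(tr, "protocol")
    base <- tr[tr$time < proto$onset, ]
    if (nrow(base) < 2 || max(base$time) < min_baseline_s) {
      return(NA_real_)
    }
    dt_ms <- 1000 / sampling_rate(tr)
    dv <- c(0, diff(base$voltage)) / dt_ms
    med <- median(base$voltage)
    spiky <- base$voltage > med + 20 & dv > 10
    if (any(spiky)) return(NA_real_)
    mean(base$voltage)
  })
  vals <- vals[is.finite(vals)]
  if (!length(vals)) abort("all baseline windows rejected")
  mean(vals)
}

#' Steady-state voltage of a step response
#'
#' Average voltage over the fixed window of 100 ms starting 100 ms after
#' stimulus onset.
#'
#' @param trace A `cc_trace`.
#' @param protocol The step protocol (defaults to the one attached to the
#'   trace); `duration` must be at least 200 ms.
#' @return Steady-state voltage (mV).
#' @export
estimate_v_ss <- function(trace, protocol = trace_protocol(trace)) {
  if (protocol$duration < 0.2) {
    abort("step shorter than 200 ms: steady-state window undefined")
  }
  w <- trace$time >= protocol$onset + 0.1 &
    trace$time < protocol$onset + 0.2
  mean(trace$voltage[w])
}

#' Pre-step voltage by cubic extrapolation
#'
#' Third-order polynomial least-squares fit to the 2 ms of voltage just
#' before stimulus onset, evaluated at onset; the polynomial absorbs rapid
#' membrane fluctuations that a plain mean would alias into the access
#' estimate.
#'
#' @param trace A `cc_trace`.
#' @param onset Stimulus onset (s); defaults to the attached protocol's.
#' @param min_points Minimum samples required in the window.
#' @return Voltage at onset (mV).
#' @export
estimate_v_o <- function(trace, onset = trace_protocol(trace)$onset,
                         min_points = 8) {
  w <- trace$time >= onset - 0.002 & trace$time < onset
  if (sum(w) < min_points) {
    abort(sprintf("fewer than %d samples in the 2 ms pre-onset window",
                  min_points))
  }
  x <- trace$time[w] - onset
  fit <- lm(trace$voltage[w] ~ poly(x, 3, raw = TRUE))
  unname(predict(fit, newdata = list(x = 0)))
}

#' Two-pass log-linear membrane time-constant fit
#'
#' The trace is folded to a decaying quantity `V' = V_ss - V` (depolarizing
#' steps) or `V - V_ss` (hyperpolarizing). A first log-linear regression of
#' `ln V'` against time runs from 0.5 ms after onset -- after most of the
#' electrode artifact has decayed -- until `V'` first falls to
#' `0.3 |V_ss - V_rest|`. A second pass re-fits with the start moved to
#' onset plus 20% of the first estimate, better isolating the membrane
#' component, and supplies the reported time constant and the onset
#' extrapolation used for the access-resistance error.
#'
#' Non-positive `V'` samples (noise crossing the asymptote) are excluded;
#' if more than 20% of a window is excluded the fit aborts. When the stop
#' threshold is already crossed at the window start (very fast membranes,
#' e.g. glia), the fit falls back to the first `min_points` samples from
#' the start and flags `fast_membrane = TRUE`; such estimates are biased by
#' the electrode artifact and should be read with care.
#'
#' @param trace A `cc_trace`.
#' @param protocol Step protocol (defaults to the attached one).
#' @param v_rest,v_ss Precomputed levels (mV); defaults computed from the
#'   trace.
#' @param min_points Minimum regression points per pass.
#' @return List: `tau0_first`, `tau0` (ms), `v_fit_onset` (the fit
#'   extrapolated to onset, mV), `fit_window` (s), `n_points`,
#'   `r2_log_fit`, `fast_membrane`.
#' @export
fit_tau <- function(trace, protocol = trace_protocol(trace),
                    v_rest = estimate_v_rest(trace),
                    v_ss = estimate_v_ss(trace, protocol),
                    min_points = 10) {
  depol <- protocol$amplitude > 0
  if (abs(v_ss - v_rest) < 1e-9) abort("flat response: polarity unknown")
  vprime <- if (depol) v_ss - trace$voltage else trace$voltage - v_ss
  thresh <- 0.3 * abs(v_ss - v_rest)

  # the stop criterion is evaluated on a short running mean of V' so that a
  # single noise dip does not truncate the regression window at random
  smooth_k <- 5L
  v_smooth <- as.numeric(stats::filter(vprime, rep(1 / smooth_k, smooth_k),
                                       sides = 2))
  v_smooth[is.na(v_smooth)] <- vprime[is.na(v_smooth)]

  one_pass <- function(start_s) {
    idx_all <- which(trace$time >= start_s &
                       trace$time < protocol$onset + protocol$duration)
    if (!length(idx_all)) abort("fit window empty")
    below <- v_smooth[idx_all] <= thresh
    stop_k <- which(below)[1]
    fast <- FALSE
    if (!is.na(stop_k) && stop_k <= 1) {
      # threshold already crossed at the window start: fast membrane
      idx <- idx_all[seq_len(min(min_points, length(idx_all)))]
      fast <- TRUE
    } else if (is.na(stop_k)) {
      abort("stop criterion never reached within the step")
    } else {
      idx <- idx_all[seq_len(stop_k)]
    }
    keep <- vprime[idx] > 0
    if (mean(!keep) > 0.2) {
      abort("more than 20% non-positive V' samples in the fit window")
    }
    idx <- idx[keep]
    if (length(idx) < min_points) {
      abort(sprintf("fewer than %d usable points in the log-linear window",
                    min_points))
    }
    tt <- trace$time[idx] - protocol$onset
    yy <- log(vprime[idx])
    fit <- lm(yy ~ tt)
    slope <- coef(fit)[["tt"]]
    if (slope >= 0) abort("non-decaying V': log-linear slope non-negative")
    list(tau_ms = -1000 / slope,
         intercept = coef(fit)[["(Intercept)"]],
         r2 = summary(fit)$r.squared,
         n = length(idx),
         window = c(min(trace$time[idx]), max(trace$time[idx])),
         fast = fast)
  }

  p1 <- one_pass(protocol$onset + 5e-4)
  p2 <- one_pass(protocol$onset + 0.2 * p1$tau_ms / 1000)
  sign <- if (depol) -1 else 1
  v_fit_onset <- v_ss + sign * exp(p2$intercept)
  list(tau0_first = p1$tau_ms, tau0 = p2$tau_ms,
       v_fit_onset = v_fit_onset, fit_window = p2$window,
       n_points = p2$n, r2_log_fit = p2$r2,
       fast_membrane = p1$fast || p2$fast)
}

screen_trace <- function(trace, protocol, v_rest, v_ss, tau0_first = NULL,
                         max_deflection_mv = 15) {
  if (abs(v_ss - v_rest) > max_deflection_mv) {
    return("steady state beyond the permitted deflection from rest")
  }
  dt_ms <- 1000 / sampling_rate(trace)
  step_w <- trace$time >= protocol$onset + 0.002 &
    trace$time < protocol$onset + protocol$duration
  v <- trace$voltage[step_w]
  dv <- c(0, diff(v)) / dt_ms
  env_top <- max(v_rest, v_ss)
  if (any(dv > 10 & v > env_top + 20)) return("spike")
  if (!is.null(tau0_first)) {
    late <- trace$time >= protocol$onset + 3 * tau0_first / 1000 &
      trace$time < protocol$onset + protocol$duration
    vv <- trace$voltage[late]
    if (length(vv) > 20) {
      sm <- stats::filter(vv, rep(1 / 11, 11), sides = 2)
      sm <- sm[!is.na(sm)]
      overshoot <- if (protocol$amplitude < 0) v_ss - min(sm) else
        max(sm) - v_ss
      if (isTRUE(overshoot > 2)) return("sag")
    }
  }
  NULL
}

#' Passive-parameter fit of one step response
#'
#' Runs the full per-trace heuristic: resting potential from the baseline,
#' steady state from the fixed 100-200 ms window, pre-step voltage by cubic
#' extrapolation, the two-pass log-linear time-constant fit, and from them
#' the residual access-resistance error and input resistance:
#' `R_a_error = (V_fit(onset) - V_O) / I`, then
#' `R_in = ((V_ss - I * R_a_error) - V_rest) / I`.
#'
#' Traces failing the acceptance screen (steady state too far from rest,
#' spikes or sag during the step) are returned as rejected fits with the
#' named reason rather than an error, so sweep sets can be processed
#' wholesale.
#'
#' @param trace A `cc_trace`.
#' @param protocol Step protocol (defaults to the attached one).
#' @param v_rest Optional externally supplied resting potential (e.g. the
#'   per-cell baseline estimate).
#' @param max_deflection_mv Acceptance screen on `|V_ss - V_rest|`.
#' @param min_points Minimum log-fit points.
#' @return A `passive_fit` object; see [tidy.passive_fit()] and
#'   [glance.passive_fit()].
#' @export
fit_step_response <- function(trace, protocol = trace_protocol(trace),
                              v_rest = NULL, max_deflection_mv = 15,
                              min_points = 10) {
  v_rest <- v_rest %||% estimate_v_rest(trace)
  v_ss <- estimate_v_ss(trace, protocol)
  v_o <- estimate_v_o(trace, protocol$onset)
  i_amp <- protocol$amplitude

  reason <- screen_trace(trace, protocol, v_rest, v_ss,
                         max_deflection_mv = max_deflection_mv)
  tau <- NULL
  if (is.null(reason)) {
    tau <- tryCatch(fit_tau(trace, protocol, v_rest, v_ss,
                            min_points = min_points),
                    error = function(e) conditionMessage(e))
    if (is.character(tau)) {
      reason <- tau
      tau <- NULL
    } else {
      reason <- screen_trace(trace, protocol, v_rest, v_ss,
                             tau0_first = tau$tau0_first,
                             max_deflection_mv = max_deflection_mv)
    }
  }

  if (!is.null(reason)) {
    out <- list(accepted = FALSE, reason = reason,
                v_rest = v_rest, v_ss = v_ss, v_o = v_o,
                tau0 = NA_real_, tau0_first = NA_real_,
                r_a_error = NA_real_, r_in = NA_real_,
                fit_window = c(NA_real_, NA_real_),
                n_points = NA_integer_, r2_log_fit = NA_real_,
                fast_membrane = NA, polarity = NA_character_,
                amplitude = i_amp, trace = trace)
    class(out) <- "passive_fit"
    return(out)
  }

  r_a_error <- (tau$v_fit_onset - v_o) / i_amp
  v_ss_adj <- v_ss - i_amp * r_a_error
  r_in <- (v_ss_adj - v_rest) / i_amp
  out <- list(accepted = TRUE, reason = NA_character_,
              v_rest = v_rest, v_ss = v_ss, v_o = v_o,
              tau0 = tau$tau0, tau0_first = tau$tau0_first,
              r_a_error = r_a_error, r_in = r_in,
              fit_window = tau$fit_window, n_points = tau$n_points,
              r2_log_fit = tau$r2_log_fit,
              fast_membrane = tau$fast_membrane,
              polarity = if (i_amp > 0) "depolarizing" else
                "hyperpolarizing",
              amplitude = i_amp, trace = trace)
  class(out) <- "passive_fit"
  out
}

#' @export
print.passive_fit <- function(x, ...) {
  if (!x$accepted) {
    cat("<passive_fit> rejected:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<passive_fit> V_rest %.1f mV, V_ss %.1f mV, tau0 %.2f ms, R_a error %.1f MOhm, R_in %.1f MOhm\n",
    x$v_rest, x$v_ss, x$tau0, x$r_a_error, x$r_in))
  invisible(x)
}

#' Average per-trace fits into cell-level values
#'
#' Linear parameters of the accepted traces are averaged, unweighted, to
#' give the cell values; the contributing count and polarity mix are
#' recorded.
#'
#' @param fits List of `passive_fit` objects (rejected ones are dropped).
#' @return A `cell_passive` object: means of `v_rest`, `v_ss`, `tau0`,
#'   `r_a_error`, `r_in`, plus `n_traces` and `polarities`.
#' @export
aggregate_cell <- function(fits) {
  if (inherits(fits, "passive_fit")) fits <- list(fits)
  acc <- purrr::keep(fits, ~ isTRUE(.x$accepted))
  if (!length(acc)) abort("no accepted traces to aggregate")
  take <- function(f) purrr::map_dbl(acc, ~ .x[[f]])
  out <- list(
    v_rest = mean(take("v_rest")), v_ss = mean(take("v_ss")),
    tau0 = mean(take("tau0")), r_a_error = mean(take("r_a_error")),
    r_in = mean(take("r_in")),
    n_traces = length(acc),
    polarities = table(purrr::map_chr(acc, "polarity")),
    fits = acc
  )
  class(out) <- "cell_passive"
  out
}

#' @export
print.cell_passive <- function(x, ...) {
  cat(sprintf(
    "<cell_passive> n = %d traces: tau0 %.2f ms, R_in %.1f MOhm, R_a error %.1f MOhm, V_rest %.1f mV\n",
    x$n_traces, x$tau0, x$r_in, x$r_a_error, x$v_rest))
  invisible(x)
}

#' Access-resistance trend over a recording
#'
#' Ordinary least-squares regression of repeated access-resistance
#' estimates against time. The reported mean is the regression-implied mean
#' at the mean time point, which for OLS equals the arithmetic mean; the
#' slope is expressed in MOhm per minute.
#'
#' @param estimates Tibble/data frame with columns `time_s` and `ra_mohm`
#'   (one row per estimate).
#' @return An `ra_trend` list: `ra_mean` (MOhm), `dra_dt` (MOhm/min, `NA`
#'   with a single point), `slope_se`, `n`.
#' @export
ra_trend <- function(estimates) {
  stopifnot(all(c("time_s", "ra_mohm") %in% names(estimates)))
  n <- nrow(estimates)
  if (n < 1) abort("no access-resistance estimates")
  if (n == 1) {
    out <- list(ra_mean = estimates$ra_mohm[1], dra_dt = NA_real_,
                slope_se = NA_real_, n = 1L)
    class(out) <- "ra_trend"
    return(out)
  }
  t_min <- estimates$time_s / 60
  if (length(unique(t_min)) == 1) {
    abort("all estimates share one timestamp: slope undefined")
  }
  fit <- lm(estimates$ra_mohm ~ t_min)
  out <- list(ra_mean = mean(estimates$ra_mohm),
              dra_dt = unname(coef(fit)[2]),
              slope_se = summary(fit)$coefficients[2, 2],
              n = as.integer(n))
  class(out) <- "ra_trend"
  out
}

#' Fit every sweep of a cell and aggregate
#'
#' Convenience wrapper: fits each trace with [fit_step_response()], using a
#' pooled resting-potential estimate across baselines, and aggregates the
#' accepted fits.
#'
#' @param traces List of `cc_trace` sweeps of one cell.
#' @param ... Passed to [fit_step_response()].
#' @return A `cell_passive`.
#' @export
fit_cell <- function(traces, ...) {
  v_rest <- estimate_v_rest(traces)
  fits <- purrr::map(traces, fit_step_response, v_rest = v_rest, ...)
  aggregate_cell(fits)
}
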