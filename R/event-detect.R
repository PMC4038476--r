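# Per-pulse resistance tracking through a session log, and detection of the
# access events: touch, electroporation zap(s), reseal, suction break.

pulse_windows <- function(log) {
  pulse <- attr(log, "pulse")
  if (is.null(pulse)) abort("session log carries no pulse-train annotation")
  if (pulse$amplitude == 0) abort("pulse-train amplitude is zero")
  empty <- tibble(pulse = integer(), on_start = numeric(),
                  on_stop = numeric(), off_len = numeric())
  if (!nrow(log)) return(empty)
  t0 <- max(pulse$start, min(log$time))
  t_end <- min(pulse$stop, max(log$time))
  period <- 1 / pulse$frequency
  off_length <- (1 - pulse$duty) * period
  n_pulses <- floor((t_end - t0) / period)
  if (n_pulses < 1) return(empty)
  k <- seq(0, n_pulses - 1)
  on_start <- t0 + k * period
  on_stop <- on_start + pulse$duty * period
  tibble(pulse = k + 1L, on_start = on_start, on_stop = on_stop,
         off_len = off_length)
}

#' Per-pulse total-resistance series from a session log
#'
#' For every monitoring pulse, the total instantaneous resistance seen by
#' the electrode is the baseline-to-plateau voltage deflection divided by
#' the pulse amplitude. The plateau is averaged over the last 25% of the
#' on-phase, the baseline over the last 25% of the preceding off-phase, and
#' the amplitude is measured from the command-current channel over the same
#' windows (so amplitude step-downs during the session are handled
#' transparently).
#'
#' @param log A `cc_session`.
#' @return A tibble with columns `time` (on-phase start, s), `r_total`
#'   (MOhm), `amplitude` (nA), `v_min` (most hyperpolarized sample of the
#'   on-phase, mV).
#' @export
pulse_resistance_series <- function(log) {
  stopifnot(inherits(log, "cc_session"))
  win <- pulse_windows(log)
  if (!nrow(win) || !nrow(log)) {
    return(tibble(time = numeric(), r_total = numeric(),
                  amplitude = numeric(), v_min = numeric()))
  }
  # uniform sampling lets every window be an integer index slice
  fs <- sampling_rate(log)
  t1 <- log$time[1]
  n <- nrow(log)
  idx_of <- function(tt) floor((tt - t1) * fs) + 1
  rows <- purrr::pmap(win, function(pulse, on_start, on_stop, off_len) {
    plat <- idx_of(on_stop - 0.25 * (on_stop - on_start)):
      (idx_of(on_stop) - 1L)
    base <- idx_of(on_start - 0.25 * off_len):(idx_of(on_start) - 1L)
    onw <- idx_of(on_start):(idx_of(on_stop) - 1L)
    plat <- plat[plat >= 1 & plat <= n]
    base <- base[base >= 1 & base <= n]
    onw <- onw[onw >= 1 & onw <= n]
    if (length(plat) < 3 || length(base) < 3) return(NULL)
    amp <- mean(log$current[plat]) - mean(log$current[base])
    if (abs(amp) < 1e-9) return(NULL)
    tibble(time = on_start,
           r_total = (mean(log$voltage[plat]) - mean(log$voltage[base])) /
             amp,
           amplitude = amp,
           v_min = min(log$voltage[onw]))
  })
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) {
    return(tibble(time = numeric(), r_total = numeric(),
                  amplitude = numeric(), v_min = numeric()))
  }
  res
}

#' Detect the membrane touch in a resistance series
#'
#' The touch is the first pulse whose resistance exceeds a rolling baseline
#' (median of the preceding `baseline_window` pulses) by at least
#' `rise_frac`, sustained for `sustain` consecutive pulses. If the
#' pre-candidate series fluctuates by `unstable_frac` or more
#' (peak-to-peak over median) the attempt is flagged unstable -- the
#' practical abort criterion for cardiac/movement artifacts -- and no touch
#' is returned.
#'
#' @param series Output of [pulse_resistance_series()].
#' @param baseline_window Rolling-baseline length (pulses); at least this
#'   many baseline pulses must precede a candidate.
#' @param rise_frac Fractional resistance rise that counts as contact
#'   (default 5%).
#' @param sustain Consecutive pulses the rise must persist.
#' @param unstable_frac Peak-to-peak fluctuation fraction that aborts the
#'   attempt (default 20%).
#' @return A tibble with 0 or 1 rows (`time`, `kind = "touch"`, `value` =
#'   resistance step in MOhm), with attribute `qc` containing `"unstable"`
#'   when the fluctuation rule fired.
#' @export
detect_touch <- function(series, baseline_window = 10, rise_frac = 0.05,
                         sustain = 3, unstable_frac = 0.2) {
  empty <- tibble(time = numeric(), kind = character(), value = numeric())
  if (nrow(series) < baseline_window + sustain) {
    return(structure(empty, qc = character()))
  }
  r <- series$r_total
  n <- length(r)
  exceed <- rep(FALSE, n)
  base <- rep(NA_real_, n)
  for (k in (baseline_window + 1):n) {
    base[k] <- median(r[max(1, k - baseline_window):(k - 1)])
    exceed[k] <- r[k] >= (1 + rise_frac) * base[k]
  }
  run <- rle(exceed)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= sustain)
  cand <- if (length(hit)) ends[hit[1]] - run$lengths[hit[1]] + 1L else NA
  pre <- if (is.na(cand)) seq_len(n) else seq_len(cand - 1L)
  fluct <- (max(r[pre]) - min(r[pre])) / median(r[pre])
  if (is.finite(fluct) && fluct >= unstable_frac) {
    return(structure(empty, qc = "unstable"))
  }
  if (is.na(cand)) return(structure(empty, qc = character()))
  structure(
    tibble(time = series$time[cand], kind = "touch",
           value = r[cand] - base[cand]),
    qc = character()
  )
}

#' Detect electroporation events ("zaps")
#'
#' A zap is an abrupt between-pulse drop of the total resistance, by at
#' least `drop_frac` relative to the recent pre-drop level, occurring while
#' the pulse voltage is at least as hyperpolarized as `v_thresh`. The zap
#' voltage is the most hyperpolarized voltage sample over the pulse
#' containing the drop and the one before it. At most `max_zaps` events are
#' returned; candidates within `dedup_s` seconds of a previous zap are
#' ascribed to the same event.
#'
#' The default drop fraction is 25%: a second zap 100-150 mV less
#' hyperpolarized than a first zap near -330 mV corresponds to a 30-45%
#' resistance drop at the first event, so a 40% rule would miss typical
#' first zaps of two-zap accesses.
#'
#' @param log A `cc_session`.
#' @param series Optional precomputed [pulse_resistance_series()].
#' @param drop_frac Minimal fractional resistance drop.
#' @param v_thresh Voltage gate (mV): the inspected window must reach at
#'   least this hyperpolarization.
#' @param max_zaps Maximum events reported.
#' @param dedup_s Candidates closer than this to the previous event are
#'   merged.
#' @return Tibble of events (`time`, `kind = "zap"`, `value` = zap voltage
#'   in mV).
#' @export
detect_zaps <- function(log, series = NULL, drop_frac = 0.25,
                        v_thresh = -150, max_zaps = 2, dedup_s = 1) {
  series <- series %||% pulse_resistance_series(log)
  empty <- tibble(time = numeric(), kind = character(), value = numeric())
  if (nrow(series) < 3) return(empty)
  win <- pulse_windows(log)
  win <- win[match(series$time, win$on_start), ]
  r <- series$r_total
  out <- list()
  last_t <- -Inf
  amp <- series$amplitude
  for (k in 3:length(r)) {
    ref <- max(r[k - 2], r[k - 1])
    if (!is.finite(ref) || ref <= 0) next
    # an amplitude change between pulses leaves a discharge transient in
    # the baseline window; resistance is not comparable across it
    if (max(abs(diff(amp[(k - 2):k]))) > 0.1 * abs(amp[k - 1])) next
    if (1 - r[k] / ref < drop_frac) next
    t_lo <- win$on_start[k - 1]
    t_hi <- win$on_stop[k]
    seg <- log$time >= t_lo & log$time < t_hi
    v_min <- min(log$voltage[seg])
    if (v_min > v_thresh) next
    t_zap <- log$time[seg][which.min(log$voltage[seg])]
    if (t_zap - last_t < dedup_s) next
    last_t <- t_zap
    out[[length(out) + 1]] <- tibble(time = t_zap, kind = "zap",
                                     value = v_min)
    if (length(out) >= max_zaps) break
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

#' Detect post-zap resealing
#'
#' After the last zap, a reseal is called when the resistance grows back to
#' at least `growth` times the post-zap level and stays there for
#' `sustain_s` seconds.
#'
#' @param series A [pulse_resistance_series()].
#' @param zaps Zap events from [detect_zaps()].
#' @param growth Growth factor over the post-zap level.
#' @param sustain_s Sustain requirement (s).
#' @return Tibble with 0 or 1 reseal events.
#' @export
detect_reseal <- function(series, zaps, growth = 3, sustain_s = 1) {
  empty <- tibble(time = numeric(), kind = character(), value = numeric())
  if (!nrow(zaps)) return(empty)
  t_zap <- max(zaps$time)
  post <- series[series$time > t_zap & series$time <= t_zap + 1, ]
  if (nrow(post) < 2) return(empty)
  level <- median(post$r_total)
  after <- series[series$time > t_zap + 1, ]
  if (!nrow(after)) return(empty)
  hi <- after$r_total >= growth * level
  for (k in which(hi)) {
    span <- after$time >= after$time[k] &
      after$time <= after$time[k] + sustain_s
    if (all(hi[span]) && sum(span) >= 2) {
      return(tibble(time = after$time[k], kind = "reseal",
                    value = after$r_total[k] / level))
    }
  }
  empty
}

#' Corroborate suction annotations with a resistance drop
#'
#' Suction breaks are experimenter actions: they are taken from the session
#' annotations, and accepted only when the resistance series shows a
#' corroborating drop (below `drop_to` times the pre-suction level) within
#' `window_s` of the annotated time.
#'
#' @param series A [pulse_resistance_series()].
#' @param ann Annotation tibble (`time`, `kind`, `value`).
#' @param drop_to Post/pre resistance ratio that counts as a break.
#' @param window_s Corroboration window (s).
#' @return Tibble of `suction_break` events.
#' @export
detect_suction_breaks <- function(series, ann, drop_to = 0.6,
                                  window_s = 0.5) {
  empty <- tibble(time = numeric(), kind = character(), value = numeric())
  if (is.null(ann) || !nrow(ann)) return(empty)
  suck <- ann$time[ann$kind == "suction"]
  out <- list()
  for (ts in suck) {
    k <- which(series$time >= ts - window_s & series$time <= ts + window_s)
    k <- k[k > 1]
    for (j in k) {
      if (series$r_total[j] <= drop_to * series$r_total[j - 1]) {
        out[[length(out) + 1]] <- tibble(time = series$time[j],
                                         kind = "suction_break",
                                         value = series$r_total[j])
        break
      }
    }
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

#' Run the full event-detection chain on a session log
#'
#' Computes the per-pulse resistance series, then detects touch, zaps,
#' reseal and suction breaks. Detection thresholds are taken from `config`
#' (see [detection_config()]).
#'
#' @param log A `cc_session`.
#' @param config Named list of thresholds, as [detection_config()].
#' @return A time-ordered event tibble (`time`, `kind`, `value`) with
#'   attributes `qc` (character flags, e.g. `"unstable"`) and `series` (the
#'   resistance series).
#' @export
detect_events <- function(log, config = detection_config()) {
  series <- pulse_resistance_series(log)
  touch <- detect_touch(series,
                        baseline_window = config$touch_baseline_pulses,
                        rise_frac = config$touch_rise_frac,
                        sustain = config$touch_sustain_pulses,
                        unstable_frac = config$unstable_frac)
  qc <- attr(touch, "qc")
  zaps <- detect_zaps(log, series, drop_frac = config$zap_drop_frac,
                      v_thresh = config$zap_v_thresh_mv,
                      max_zaps = config$max_zaps,
                      dedup_s = config$zap_dedup_s)
  reseal <- detect_reseal(series, zaps, growth = config$reseal_growth,
                          sustain_s = config$reseal_sustain_s)
  sucks <- detect_suction_breaks(series, annotations(log),
                                 drop_to = config$suction_drop_to,
                                 window_s = config$suction_window_s)
  ev <- dplyr::bind_rows(touch, zaps, reseal, sucks) |>
    dplyr::arrange(.data$time)
  structure(ev, qc = qc, series = series)
}

#' Default event-detection thresholds
#'
#' All thresholds of the detection chain in one overridable list; the
#' phenomena they quantify (an "abrupt" resistance drop, a "small"
#' deflection at touch, "about 20%" fluctuations) are described
#' qualitatively in practice, so the values here are calibrated against the
#' circuit simulator.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of thresholds.
#' @export
detection_config <- function(...) {
  cfg <- list(
    touch_baseline_pulses = 10, touch_rise_frac = 0.05,
    touch_sustain_pulses = 3, unstable_frac = 0.2,
    zap_drop_frac = 0.25, zap_v_thresh_mv = -150, max_zaps = 2,
    zap_dedup_s = 1,
    reseal_growth = 3, reseal_sustain_s = 1,
    suction_drop_to = 0.6, suction_window_s = 0.5
  )
  modifyList(cfg, list(...))
}

#' Zap delay relative to pressure release
#'
#' The zap delay is the time from the annotated pipette pressure release to
#' the first detected zap.
#'
#' @param events Event tibble containing zero or more `zap` rows.
#' @param ann Annotation tibble containing a `pressure_release` row.
#' @return Delay in seconds, or `NA` when there is no zap.
#' @export
measure_zap_timing <- function(events, ann) {
  rel <- ann$time[ann$kind == "pressure_release"]
  if (!length(rel)) abort("no `pressure_release` annotation")
  zaps <- events$time[events$kind == "zap"]
  if (!length(zaps)) return(NA_real_)
  if (min(zaps) < min(rel)) abort("ordering: zap precedes pressure release")
  min(zaps) - min(rel)
}

#' Classify the whole-cell access endpoint
#'
#' Endpoint rules: `TZ` -- one or two zaps, no reseal, no suction break;
#' `TZS` -- zap, then reseal, then suction break, in time order; `TS` -- no
#' zap, a touch followed by a suction break; anything else is `FAIL` with a
#' named reason.
#'
#' @param events Time-ordered event tibble.
#' @param ann Optional annotations; when they contain a `pressure_release`,
#'   the zap delay is included.
#' @return One-row tibble: `endpoint`, `n_zaps`, `v_zap` (first-zap voltage,
#'   mV), `t_zap` (s), `reason`.
#' @export
classify_endpoint <- function(events, ann = NULL) {
  events <- dplyr::arrange(events, .data$time)
  zaps <- events[events$kind == "zap", ]
  reseals <- events[events$kind == "reseal", ]
  sucks <- events[events$kind == "suction_break", ]
  touch <- events[events$kind == "touch", ]
  v_zap <- if (nrow(zaps)) zaps$value[1] else NA_real_
  t_zap <- if (!is.null(ann) && nrow(zaps) &&
               any(ann$kind == "pressure_release") &&
               min(zaps$time) >= min(ann$time[ann$kind ==
                                                "pressure_release"])) {
    measure_zap_timing(events, ann)
  } else NA_real_

  call <- function(endpoint, reason = NA_character_) {
    tibble(endpoint = endpoint, n_zaps = nrow(zaps), v_zap = v_zap,
           t_zap = t_zap, reason = reason)
  }
  if (nrow(touch) && nrow(sucks) && sucks$time[1] < touch$time[1]) {
    return(call("FAIL", "suction precedes touch"))
  }
  if (nrow(zaps) && !nrow(reseals) && !nrow(sucks)) return(call("TZ"))
  if (nrow(zaps) && nrow(reseals) && nrow(sucks) &&
      max(zaps$time) < reseals$time[1] &&
      reseals$time[1] < sucks$time[1]) {
    return(call("TZS"))
  }
  if (!nrow(zaps) && nrow(sucks) && nrow(touch)) return(call("TS"))
  call("FAIL", if (!nrow(events)) "no events" else "unrecognized sequence")
}
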