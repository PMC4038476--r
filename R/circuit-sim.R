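# Equivalent-circuit simulator: electrode (fast RC) in series with a passive
# cell (slow RC), driven by current-clamp step or pulse-train protocols.
# Units throughout: seconds, mV, nA, MOhm (so mV = nA * MOhm), ms for time
# constants where noted.

#' Electrode and cell equivalent-circuit parameters
#'
#' Ground-truth parameters for the simulator. The electrode is a single fast
#' RC stage (resistance `r_e`, time constant `tau_e`); the cell is a passive
#' RC membrane (`r_in`, `tau_m`) reached through the access resistance `r_a`.
#' `bridge_error` is the residual, uncompensated series resistance presented
#' to the analyst after on-line bridge balance: it is what the off-line
#' access-resistance estimate should recover.
#'
#' @param r_e Electrode resistance (MOhm).
#' @param tau_e Electrode time constant (ms). 0 means instantaneous.
#' @param r_a Access resistance after whole-cell access (MOhm).
#' @param r_in Cell input resistance (MOhm).
#' @param tau_m Membrane time constant (ms).
#' @param e_rest Resting potential (mV).
#' @param v_bd Membrane breakdown (electroporation) voltage (mV, below
#'   -100 mV).
#' @param noise_rms Gaussian voltage-noise standard deviation (mV).
#' @param bridge_error Residual series resistance seen by the analyst after
#'   on-line bridge compensation (MOhm). May be 0 (perfect balance).
#'
#' @return A `circuit_params` list.
#' @examples
#' circuit_params(r_in = 100, tau_m = 10, bridge_error = 20)
#' @export
circuit_params <- function(r_e = 6, tau_e = 0.15, r_a = 35, r_in = 56,
                           tau_m = 9.8, e_rest = -76, v_bd = -330,
                           noise_rms = 0, bridge_error = 4) {
  stopifnot(r_e > 0, r_a > 0, r_in > 0, tau_e >= 0, tau_m > 0,
            noise_rms >= 0, bridge_error >= 0)
  if (tau_e > 0 && tau_e >= tau_m) {
    abort("electrode time constant `tau_e` must be smaller than `tau_m`")
  }
  if (v_bd >= -100) abort("breakdown voltage `v_bd` must be below -100 mV")
  structure(
    list(r_e = r_e, tau_e = tau_e, r_a = r_a, r_in = r_in, tau_m = tau_m,
         e_rest = e_rest, v_bd = v_bd, noise_rms = noise_rms,
         bridge_error = bridge_error),
    class = "circuit_params"
  )
}

#' Current-step stimulus protocol
#'
#' @param onset Step onset (s); must be positive so a pre-stimulus baseline
#'   exists.
#' @param duration Step duration (s). The passive fit needs at least 200 ms.
#' @param amplitude Step amplitude (nA); negative = hyperpolarizing.
#' @param tail Post-step recording tail (s).
#'
#' @return A `step_protocol` list.
#' @export
step_protocol <- function(onset = 0.1, duration = 0.5, amplitude = -0.1,
                          tail = 0.1) {
  stopifnot(onset > 0, duration > 0, tail >= 0)
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 tail = tail),
            class = "step_protocol")
}

#' Impedance-monitoring pulse train
#'
#' Defaults reproduce the monitoring stimulus used during the cortical
#' descent: 10 Hz, 50% duty-cycle pulses alternating between 0 and -1.11 nA.
#'
#' @param frequency Pulse rate (Hz).
#' @param duty On-fraction of each cycle.
#' @param amplitude On-phase current (nA, negative).
#' @param start,stop Active span of the train (s).
#'
#' @return A `pulse_train` list.
#' @export
pulse_train <- function(frequency = 10, duty = 0.5, amplitude = -1.11,
                        start = 0, stop = Inf) {
  stopifnot(frequency > 0, duty > 0, duty < 1, start >= 0, stop > start)
  structure(list(frequency = frequency, duty = duty, amplitude = amplitude,
                 start = start, stop = stop),
            class = "pulse_train")
}

#' Approach-and-access session scenario
#'
#' Describes one recording attempt: when the pipette touches the cell, when
#' pressure is released (seal growth starts), how fast the seal grows, how
#' access is finally obtained (`endpoint`), and optional reseal/suction
#' phases. Seal growth is an exponential approach toward `seal_ceiling`
#' (default 2 GOhm) with time constant `seal_tau`.
#'
#' @param endpoint One of `"TZ"` (zap only), `"TZS"` (zap, reseal, suction),
#'   `"TS"` (no zap, suction after slow sealing), `"FAIL"` (no access).
#' @param touch_time Time of membrane contact (s); `NA` for a FAIL scenario
#'   with no touch.
#' @param release_time Pressure-release time (s); seal growth starts here.
#' @param seal_tau Seal-growth time constant (s).
#' @param seal_ceiling Asymptotic seal resistance (MOhm).
#' @param touch_dr Resistance increase at touch (MOhm).
#' @param n_zaps 1 or 2 electroporation events (TZ/TZS only).
#' @param second_zap_offset For two-zap scenarios, how much less
#'   hyperpolarized the second zap is (mV, typically 100-150).
#' @param second_zap_delay Delay from first to second zap (s).
#' @param reseal_time For TZS, when the membrane starts resealing (s);
#'   default 3 s after the expected final zap.
#' @param suction_time For TZS/TS, time of the suction pulse that
#'   (re-)establishes access (s).
#' @param duration Total log duration (s).
#' @param artifact_frac Optional movement/cardiac artifact: sinusoidal
#'   fractional modulation of the electrode resistance (0.1 gives 20%
#'   peak-to-peak).
#' @param artifact_hz Artifact frequency (Hz).
#' @param pulse A [pulse_train()].
#'
#' @return A `session_scenario` list.
#' @export
session_scenario <- function(endpoint = c("TZ", "TZS", "TS", "FAIL"),
                             touch_time = 5, release_time = 6,
                             seal_tau = 16, seal_ceiling = 2000,
                             touch_dr = 0.5,
                             n_zaps = 1, second_zap_offset = 120,
                             second_zap_delay = 2,
                             reseal_time = NULL, suction_time = NULL,
                             duration = NULL,
                             artifact_frac = 0, artifact_hz = 1.5,
                             pulse = pulse_train()) {
  endpoint <- match.arg(endpoint)
  if (endpoint != "FAIL") {
    stopifnot(is.finite(touch_time), is.finite(release_time))
    if (touch_time >= release_time) {
      abort("`touch_time` must precede `release_time`")
    }
  }
  if (endpoint == "TS") n_zaps <- 0L
  if (endpoint %in% c("TZ", "TZS")) stopifnot(n_zaps %in% 1:2)
  # TZS reseal/suction defaults are derived from the (emergent) zap time
  # inside simulate_session() when left NULL here
  if (endpoint == "TS" && is.null(suction_time)) {
    suction_time <- release_time + 25
  }
  if (is.null(duration)) {
    duration <- max(release_time + 15,
                    (suction_time %||% -Inf) + 5,
                    if (endpoint == "FAIL") 20 else 0)
  }
  stopifnot(second_zap_offset >= 0, artifact_frac >= 0, seal_tau > 0,
            seal_ceiling > 0)
  structure(
    list(endpoint = endpoint, touch_time = touch_time,
         release_time = release_time, seal_tau = seal_tau,
         seal_ceiling = seal_ceiling, touch_dr = touch_dr,
         n_zaps = as.integer(n_zaps), second_zap_offset = second_zap_offset,
         second_zap_delay = second_zap_delay, reseal_time = reseal_time,
         suction_time = suction_time, duration = duration,
         artifact_frac = artifact_frac, artifact_hz = artifact_hz,
         pulse = pulse),
    class = "session_scenario"
  )
}

new_cc_trace <- function(time, voltage, current, sampling_rate, protocol,
                         meta = list()) {
  out <- tibble(time = time, voltage = voltage, current = current)
  structure(out,
            sampling_rate = sampling_rate, protocol = protocol, meta = meta,
            class = c("cc_trace", class(out)))
}

new_cc_session <- function(time, voltage, current, sampling_rate, pulse,
                           annotations, truth_events, params = NULL,
                           meta = list()) {
  out <- tibble(time = time, voltage = voltage, current = current)
  structure(out,
            sampling_rate = sampling_rate, pulse = pulse,
            annotations = annotations, truth_events = truth_events,
            params = params, meta = meta,
            class = c("cc_session", class(out)))
}

#' Trace and session attribute accessors
#'
#' @param x A `cc_trace` or `cc_session`.
#' @return `sampling_rate()` the sampling rate in Hz; `trace_protocol()` the
#'   attached [step_protocol()] or [pulse_train()]; `trace_meta()` the
#'   metadata list; `annotations()` the experimenter-annotation tibble;
#'   `truth_events()` the simulator ground-truth event tibble (or `NULL` for
#'   real data).
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname sampling_rate
#' @export
trace_protocol <- function(x) attr(x, "protocol") %||% attr(x, "pulse")

#' @rdname sampling_rate
#' @export
trace_meta <- function(x) attr(x, "meta") %||% list()

#' @rdname sampling_rate
#' @export
annotations <- function(x) attr(x, "annotations")

#' @rdname sampling_rate
#' @export
truth_events <- function(x) attr(x, "truth_events")

# unit-step charging factor: (x >= 0) * (1 - exp(-x / tau)), tau in the same
# units as x; tau = 0 gives a pure heaviside.
step_charge <- function(x, tau) {
  if (tau <= 0) return(as.numeric(x >= 0))
  ifelse(x >= 0, 1 - exp(-x / tau), 0)
}

#' Simulate a current-clamp step-response sweep
#'
#' Analytic solution of the series electrode + passive-membrane circuit for a
#' rectangular current step. After onset the noiseless voltage is
#' `e_rest + I * bridge_error * (1 - exp(-t/tau_e)) + I * r_in *
#' (1 - exp(-t/tau_m))`; the electrode component uses `bridge_error` because
#' that residual is what the analyst's recording shows after on-line bridge
#' balance. The command-current channel reproduces the stimulus exactly.
#'
#' Optionally a stereotyped spiking mechanism (leaky integrate-and-fire with
#' a fixed 2 ms waveform) is layered on depolarizing steps via `spike`; see
#' [spike_shape()].
#'
#' @param params A [circuit_params()].
#' @param protocol A [step_protocol()]; `duration` must be at least 200 ms so
#'   the steady-state window of the passive fit exists.
#' @param sampling_rate Samples per second (Hz); the sampling interval must
#'   not exceed `tau_e / 2` unless `tau_e = 0`.
#' @param seed Optional integer seed for the noise draw.
#' @param spike Optional [spike_shape()] enabling current-evoked spiking.
#'
#' @return A `cc_trace` tibble with columns `time` (s), `voltage` (mV),
#'   `current` (nA).
#' @examples
#' p <- circuit_params(r_in = 100, tau_m = 10, bridge_error = 20,
#'                     tau_e = 0.1, e_rest = -70)
#' tr <- simulate_step_response(p, step_protocol(amplitude = -0.1))
#' @export
simulate_step_response <- function(params, protocol,
                                   sampling_rate = 40000, seed = NULL,
                                   spike = NULL) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "step_protocol"))
  dt <- 1 / sampling_rate
  if (params$tau_e > 0 && dt > params$tau_e / 1000 / 2) {
    abort("sampling interval exceeds tau_e/2; raise `sampling_rate`")
  }
  if (protocol$duration < 0.2) {
    abort(paste("step `duration` must be at least 200 ms so the",
                "steady-state window is defined"))
  }
  total <- protocol$onset + protocol$duration + protocol$tail
  n <- floor(total / dt)
  time <- (seq_len(n) - 1) * dt
  i_amp <- protocol$amplitude
  on <- time >= protocol$onset & time < protocol$onset + protocol$duration
  current <- ifelse(on, i_amp, 0)

  rel_on <- time - protocol$onset
  rel_off <- time - (protocol$onset + protocol$duration)
  tau_e_s <- params$tau_e / 1000
  tau_m_s <- params$tau_m / 1000
  elec <- i_amp * params$bridge_error *
    (step_charge(rel_on, tau_e_s) - step_charge(rel_off, tau_e_s))
  memb <- i_amp * params$r_in *
    (step_charge(rel_on, tau_m_s) - step_charge(rel_off, tau_m_s))
  voltage <- params$e_rest + elec + memb

  if (!is.null(spike)) {
    voltage <- overlay_spikes(voltage, time, params, protocol, spike, dt)
  }
  if (params$noise_rms > 0) {
    noise_fun <- function() rnorm(n, 0, params$noise_rms)
    noise <- if (is.null(seed)) noise_fun() else
      withr::with_seed(seed, noise_fun())
    voltage <- voltage + noise
  }
  new_cc_trace(time, voltage, current, sampling_rate, protocol,
               meta = list(params = params,
                           filter_cutoff_hz = NA_real_))
}

#' Stereotyped action-potential parameters
#'
#' A fixed spike waveform for the integrate-and-fire overlay: linear rise at
#' `dvdt_max` from `threshold` to `peak`, then linear fall to `reset` within
#' `width_ms`.
#'
#' @param threshold Absolute firing threshold (mV).
#' @param peak Absolute spike peak (mV).
#' @param dvdt_max Maximum depolarization rate (mV/ms).
#' @param reset Post-spike reset potential (mV).
#' @param width_ms Total waveform width (ms).
#' @return A `spike_shape` list.
#' @export
spike_shape <- function(threshold = -50, peak = 11, dvdt_max = 230,
                        reset = -60, width_ms = 2) {
  stopifnot(peak > threshold, dvdt_max > 0, width_ms > 0, reset < threshold)
  structure(list(threshold = threshold, peak = peak, dvdt_max = dvdt_max,
                 reset = reset, width_ms = width_ms),
            class = "spike_shape")
}

# Replace the passive membrane trajectory with an integrate-and-fire one:
# whenever the (noiseless) membrane crosses `spike$threshold` during the
# step, a stereotyped waveform is pasted in and the membrane restarts its
# exponential approach to the step steady state from `spike$reset`.
overlay_spikes <- function(voltage, time, params, protocol, spike, dt) {
  on_start <- protocol$onset
  on_stop <- protocol$onset + protocol$duration
  tau_s <- params$tau_m / 1000
  v_target <- params$e_rest +
    protocol$amplitude * (params$r_in + params$bridge_error)
  if (v_target <= spike$threshold) return(voltage)

  dt_ms <- dt * 1000
  n_wave <- max(2L, round(spike$width_ms / dt_ms))
  rise <- (spike$peak - spike$threshold) / spike$dvdt_max # ms
  wave_t <- (seq_len(n_wave) - 1) * dt_ms
  wave <- ifelse(wave_t <= rise,
                 spike$threshold + spike$dvdt_max * wave_t,
                 spike$peak + (spike$reset - spike$peak) *
                   (wave_t - rise) / max(spike$width_ms - rise, dt_ms))
  wave <- pmin(wave, spike$peak)

  t0 <- on_start
  v0 <- params$e_rest
  out <- voltage
  repeat {
    # time (from t0) at which the exponential approach crosses threshold
    gap <- (v_target - v0)
    frac <- (spike$threshold - v0) / gap
    if (frac >= 1 || frac < 0) break
    t_cross <- t0 - tau_s * log(1 - frac)
    if (t_cross >= on_stop) break
    i0 <- which(time >= t_cross)[1]
    if (is.na(i0)) break
    idx <- i0:min(i0 + n_wave - 1L, length(out))
    out[idx] <- wave[seq_along(idx)]
    # resume passive charge from reset after the waveform
    t0 <- time[min(i0 + n_wave, length(out))]
    v0 <- spike$reset
    seg <- which(time >= t0 & time < on_stop)
    if (!length(seg)) break
    out[seg] <- v_target + (v0 - v_target) * exp(-(time[seg] - t0) / tau_s)
  }
  out
}

#' Apply the acquisition anti-alias filter
#'
#' Models the recording chain's low-pass stage as a 4th-order Bessel filter
#' (default cutoff 10 kHz) applied to the voltage channel. Kept as an
#' explicit step so unfiltered traces retain their closed-form shape.
#'
#' @param trace A `cc_trace`.
#' @param cutoff_hz Cutoff frequency (Hz).
#' @return The filtered trace; `trace_meta()$filter_cutoff_hz` records the
#'   cutoff.
#' @export
apply_acquisition_filter <- function(trace, cutoff_hz = 10000) {
  fs <- sampling_rate(trace)
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  # 4th-order Bessel analog prototype, poles normalized to -3 dB at
  # 1 rad/s (standard tabulated values), scaled to the cutoff and
  # discretized by the bilinear transform
  poles_norm <- c(complex(real = -0.657211, imaginary = 1.004050),
                  complex(real = -0.657211, imaginary = -1.004050),
                  complex(real = -0.904758, imaginary = 0.270919),
                  complex(real = -0.904758, imaginary = -0.270919))
  wc <- 2 * pi * cutoff_hz
  poles <- poles_norm * wc
  gain <- Re(prod(-poles))
  filt <- signal::bilinear(complex(0), poles, gain, T = 1 / fs)
  v <- as.numeric(signal::filter(filt, trace$voltage))
  meta <- trace_meta(trace)
  meta$filter_cutoff_hz <- cutoff_hz
  new_cc_trace(trace$time, v, trace$current, fs,
               attr(trace, "protocol"), meta)
}

#' Simulate a full approach-and-access session log
#'
#' Renders voltage and current channels of a recording attempt monitored
#' with the impedance pulse train. The instantaneous series resistance
#' follows the scenario phases: electrode alone in the bath, a small step at
#' touch, exponential seal growth after pressure release, electroporation
#' ("zap") the moment the on-pulse voltage reaches the breakdown voltage
#' `v_bd`, optional second zap / reseal / suction phases, and whole-cell
#' access (resistance `r_e + r_a`, DC level charging to `e_rest`). One
#' second after final access the pulse amplitude is stepped down to -0.1 nA,
#' as is done in practice; in TS scenarios the amplitude is decade-reduced
#' whenever on-pulse deflections would exceed 150 mV.
#'
#' Ground-truth events (touch, zap(s) with the true zap voltage, reseal,
#' suction break) are attached as `truth_events()`; experimenter annotations
#' (pressure release, suction, current changes) as `annotations()`.
#'
#' @param params A [circuit_params()].
#' @param scenario A [session_scenario()].
#' @param sampling_rate Log sampling rate (Hz). Session logs default to
#'   2 kHz; electrode charging faster than two samples is folded into an
#'   effective one-pole response.
#' @param seed Optional seed for the noise draw.
#'
#' @return A `cc_session` tibble (columns `time`, `voltage`, `current`).
#' @export
simulate_session <- function(params, scenario, sampling_rate = 2000,
                             seed = NULL) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(scenario, "session_scenario"))
  sc <- scenario
  p <- params
  pulse <- sc$pulse
  dt <- 1 / sampling_rate

  if (sc$endpoint %in% c("TZ", "TZS")) {
    r_needed <- abs(p$v_bd / pulse$amplitude)
    r_max <- p$r_e + sc$touch_dr + sc$seal_ceiling
    if (r_needed > r_max) {
      abort(sprintf(
        "breakdown voltage %.0f mV unreachable: needs %.0f MOhm but seal ceiling gives at most %.0f MOhm",
        p$v_bd, r_needed, r_max))
    }
    # predicted zap time from the seal-growth law, used to anchor default
    # reseal/suction times and the log duration
    seal_needed <- r_needed - p$r_e - sc$touch_dr
    t_zap_pred <- sc$release_time -
      sc$seal_tau * log(1 - seal_needed / sc$seal_ceiling)
    t_final_pred <- t_zap_pred + 0.15 +
      if (sc$n_zaps == 2L) sc$second_zap_delay else 0
    if (sc$endpoint == "TZS") {
      sc$reseal_time <- sc$reseal_time %||% (t_final_pred + 3)
      sc$suction_time <- sc$suction_time %||% (sc$reseal_time + 8)
      sc$duration <- max(sc$duration, sc$suction_time + 5)
    } else {
      sc$duration <- max(sc$duration, t_final_pred + 8)
    }
  }
  n <- floor(sc$duration / dt)
  time <- (seq_len(n) - 1) * dt

  tau_fast <- max(p$tau_e / 1000, 2 * dt)
  a_fast <- 1 - exp(-dt / tau_fast)
  a_slow <- 1 - exp(-dt / (p$tau_m / 1000))

  # pulse-train command current (before amplitude reductions)
  on <- time >= pulse$start & time < pulse$stop &
    (((time - pulse$start) * pulse$frequency) %% 1) < pulse$duty

  amp_level <- pulse$amplitude
  pending_amp <- NA_real_

  v_fast <- 0; v_slow <- 0; dc <- 0
  voltage <- numeric(n)
  current <- numeric(n)
  phase <- if (is.finite(sc$touch_time)) "bath" else "bath_nocontact"
  events <- list()
  ann <- list()
  zap1_v <- NA_real_; zap2_due <- Inf; r_mid <- NA_real_
  final_access_t <- NA_real_
  art <- sc$artifact_frac > 0

  add_event <- function(lst, t, kind, value) {
    lst[[length(lst) + 1]] <- list(time = t, kind = kind, value = value)
    lst
  }
  ann <- add_event(ann, sc$release_time, "pressure_release", NA_real_)
  if (!is.null(sc$suction_time)) {
    ann <- add_event(ann, sc$suction_time, "suction", NA_real_)
  }

  touched <- FALSE; released <- FALSE; reseal_done <- FALSE
  suction_t <- sc$suction_time %||% Inf
  reseal_t <- sc$reseal_time %||% Inf
  for (i in seq_len(n)) {
    t <- time[i]
    # amplitude changes take effect only in off phases
    if (!is.na(pending_amp) && !on[i]) {
      amp_level <- pending_amp
      pending_amp <- NA_real_
    }
    i_cmd <- if (on[i]) amp_level else 0

    if (!touched && is.finite(sc$touch_time) && t >= sc$touch_time &&
        sc$endpoint != "FAIL") {
      touched <- TRUE
      events <- add_event(events, t, "touch", sc$touch_dr)
    }
    if (!released && t >= sc$release_time && sc$endpoint != "FAIL") {
      released <- TRUE
    }

    fast_r <- p$r_e
    slow_r <- 0
    dc_target <- 0
    if (phase %in% c("bath", "bath_nocontact")) {
      if (touched) fast_r <- p$r_e + sc$touch_dr
      if (touched && released) phase <- "sealing"
    }
    if (phase == "sealing") {
      seal <- sc$seal_ceiling *
        (1 - exp(-(t - sc$release_time) / sc$seal_tau))
      fast_r <- p$r_e + sc$touch_dr + seal
      if (sc$endpoint == "TS") {
        # keep deflections under ~150 mV by decade current reduction
        while (abs(amp_level * fast_r) > 150 && abs(amp_level) > 0.002) {
          amp_level <- amp_level / 10
          ann <- add_event(ann, t, "current_change", amp_level)
        }
        if (t >= suction_t) {
          phase <- "wholecell"
          final_access_t <- t
          events <- add_event(events, t, "suction_break", NA_real_)
        }
      }
    } else if (phase == "partial") {
      fast_r <- r_mid
      dc_target <- p$e_rest / 2
      if (t >= zap2_due && on[i]) {
        # fire the second zap near the pulse plateau
        frac_on <- ((t - pulse$start) * pulse$frequency) %% 1 / pulse$duty
        if (frac_on > 0.5) {
          v_now <- dc + v_fast + v_slow
          events <- add_event(events, t, "zap", v_now)
          phase <- "wholecell"
          final_access_t <- t
        }
      }
    } else if (phase == "wholecell") {
      fast_r <- p$r_e + p$r_a
      slow_r <- p$r_in
      dc_target <- p$e_rest
      if (sc$endpoint == "TZS" && !reseal_done &&
          is.finite(final_access_t) && t >= reseal_t && t < suction_t) {
        phase <- "resealing"
        reseal_done <- TRUE
        events <- add_event(events, t, "reseal", NA_real_)
      }
    } else if (phase == "resealing") {
      # the membrane reforms a gigaseal; deflections are kept under
      # ~150 mV by decade current reductions, as during slow sealing
      res <- sc$seal_ceiling * (1 - exp(-(t - reseal_t) /
                                          (sc$seal_tau / 3)))
      fast_r <- p$r_e + p$r_a + res
      dc_target <- 0
      while (abs(amp_level * fast_r) > 150 && abs(amp_level) > 0.002) {
        amp_level <- amp_level / 10
        ann <- add_event(ann, t, "current_change", amp_level)
      }
      if (t >= suction_t) {
        phase <- "wholecell"
        events <- add_event(events, t, "suction_break", NA_real_)
        fast_r <- p$r_e + p$r_a
        slow_r <- p$r_in
        dc_target <- p$e_rest
      }
    }

    if (art) {
      fast_r <- fast_r * (1 + sc$artifact_frac *
                            sin(2 * pi * sc$artifact_hz * t))
    }

    v_fast <- v_fast + (i_cmd * fast_r - v_fast) * a_fast
    v_slow <- v_slow + (i_cmd * slow_r - v_slow) * a_slow
    dc <- dc + (dc_target - dc) * a_slow
    v <- dc + v_fast + v_slow

    # electroporation: the instant the on-pulse voltage reaches breakdown.
    # The crossing sample keeps the peak hyperpolarization (it is the
    # recorded V_zap); the resistance collapse takes effect from the next
    # sample.
    if (phase == "sealing" && sc$endpoint %in% c("TZ", "TZS") &&
        v <= p$v_bd) {
      events <- add_event(events, t, "zap", v)
      if (sc$n_zaps == 2L) {
        zap1_v <- v
        dc_mid <- p$e_rest / 2
        r_mid <- (zap1_v + sc$second_zap_offset - dc_mid) / pulse$amplitude
        r_mid <- max(r_mid, p$r_e + p$r_a + 5)
        zap2_due <- t + sc$second_zap_delay
        phase <- "partial"
        v_fast <- i_cmd * r_mid # instantaneous collapse of the patch
      } else {
        phase <- "wholecell"
        final_access_t <- t
        v_fast <- i_cmd * (p$r_e + p$r_a)
      }
    }
    # amplitude step-down one second after final whole-cell access
    if (phase == "wholecell" && is.finite(final_access_t) &&
        t >= final_access_t + 1 && abs(amp_level) > 0.15 &&
        is.na(pending_amp)) {
      pending_amp <- -0.1
      ann <- add_event(ann, t, "current_change", -0.1)
    }

    voltage[i] <- v
    current[i] <- i_cmd
  }

  if (p$noise_rms > 0) {
    noise_fun <- function() rnorm(n, 0, p$noise_rms)
    noise <- if (is.null(seed)) noise_fun() else
      withr::with_seed(seed, noise_fun())
    voltage <- voltage + noise
  }

  to_tbl <- function(lst) {
    if (!length(lst)) {
      return(tibble(time = numeric(), kind = character(),
                    value = numeric()))
    }
    tibble(time = vapply(lst, `[[`, numeric(1), "time"),
           kind = vapply(lst, `[[`, character(1), "kind"),
           value = vapply(lst, `[[`, numeric(1), "value")) |>
      dplyr::arrange(.data$time)
  }
  new_cc_session(time, voltage, current, sampling_rate, pulse,
                 annotations = to_tbl(ann), truth_events = to_tbl(events),
                 params = p,
                 meta = list(scenario = sc))
}

#' Simulate a cohort of recording sessions with ground truth
#'
#' Draws per-cell circuit parameters and an access endpoint from
#' configurable per-cell-type distributions, then (optionally) renders each
#' session log. Defaults reproduce the recorded-population summaries for
#' cortical neurons and glia: electrode resistance 6.0 +/- 0.73 /
#' 6.4 +/- 0.58 MOhm, input resistance 56 +/- 31 / 90 +/- 62 MOhm, membrane
#' time constant 9.8 +/- 5.2 / 1.5 (truncated below 5) ms, resting potential
#' -76 +/- 7.5 / -76 +/- 13 mV, access resistance 35 +/- 18 / 53 +/- 26
#' MOhm, zap voltage -330 +/- 53 / -350 +/- 64 mV, and endpoint mixes
#' 48/40/12% (neurons) and 61/24/15% (glia) for TZ/TZS/TS.
#'
#' @param n Number of cells.
#' @param cell_type `"neuron"`, `"glia"`, or a vector recycled to length
#'   `n`.
#' @param endpoint_mix Named numeric probabilities for TZ/TZS/TS, or `NULL`
#'   for the per-type defaults. A single endpoint name forces it.
#' @param overrides Named list overriding entries of the per-type
#'   distribution table (each entry `c(mean, sd)`, sd may be 0).
#' @param seed Integer seed (mandatory: cohorts are reproducible by
#'   construction).
#' @param render_logs If `FALSE`, only the ground-truth table is returned
#'   (cheap for large-n sampling checks).
#' @param sampling_rate Log sampling rate (Hz) when rendering.
#'
#' @return A list with `truth` (one row per cell: every sampled parameter,
#'   the endpoint and scenario times) and `sessions` (list of `cc_session`
#'   or `NULL`).
#' @export
simulate_cohort <- function(n, cell_type = "neuron", endpoint_mix = NULL,
                            overrides = list(), seed,
                            render_logs = TRUE, sampling_rate = 2000) {
  stopifnot(n >= 1, !missing(seed))
  types <- rep_len(cell_type, n)
  defaults <- list(
    neuron = list(r_e = c(6.0, 0.73), r_in = c(56, 31), tau_m = c(9.8, 5.2),
                  e_rest = c(-76, 7.5), r_a = c(35, 18), v_bd = c(-330, 53),
                  noise_rms = c(0, 0),
                  mix = c(TZ = 0.48, TZS = 0.40, TS = 0.12)),
    glia = list(r_e = c(6.4, 0.58), r_in = c(90, 62), tau_m = c(1.5, 1.2),
                e_rest = c(-76, 13), r_a = c(53, 26), v_bd = c(-350, 64),
                noise_rms = c(0, 0),
                mix = c(TZ = 0.61, TZS = 0.24, TS = 0.15))
  )
  for (nm in names(overrides)) {
    if (any(!is.finite(overrides[[nm]])) ||
        (length(overrides[[nm]]) > 1 && overrides[[nm]][2] < 0)) {
      abort(sprintf("override `%s` must be finite with non-negative sd", nm))
    }
  }

  rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    x <- rnorm(n, mean, sd)
    bad <- which(x < lower | x > upper)
    k <- 0
    while (length(bad) && k < 100) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- which(x < lower | x > upper)
      k <- k + 1
    }
    pmin(pmax(x, lower), upper)
  }

  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      ty <- types[i]
      d <- defaults[[ty]]
      for (nm in names(overrides)) {
        if (nm %in% names(d)) d[[nm]] <- overrides[[nm]]
      }
      mix <- endpoint_mix %||% d$mix
      if (is.character(mix)) {
        ep <- mix
      } else {
        ep <- sample(names(mix), 1, prob = mix)
      }
      lims <- list(r_e = c(3, 12), r_in = c(5, 400), e_rest = c(-110, -50),
                   r_a = c(8, 120), v_bd = c(-550, -160),
                   tau_m = if (ty == "glia") c(0.3, 4.9) else c(3, 40))
      draw <- function(nm) {
        rtrunc(1, d[[nm]][1], d[[nm]][2], lims[[nm]][1], lims[[nm]][2])
      }
      r_e <- draw("r_e")
      # For zap endpoints the drawn triple must live in the regime where
      # electroporation is observable: the whole-cell resistance reached
      # after the zap must sit well below the seal resistance at breakdown
      # (here at most ~70% of it), otherwise no abrupt drop exists.
      amp <- abs(pulse_train()$amplitude)
      repeat {
        r_in <- draw("r_in"); r_a <- draw("r_a"); v_bd <- draw("v_bd")
        if (ep == "TS" ||
            abs(v_bd) >= 1.4 * amp * (r_e + r_a + r_in)) break
      }
      tibble(
        cell_id = sprintf("%s_%03d", ty, i), cell_type = ty, endpoint = ep,
        r_e = r_e, r_in = r_in, tau_m = draw("tau_m"),
        e_rest = draw("e_rest"), r_a = r_a, v_bd = v_bd,
        noise_rms = max(d$noise_rms[1], 0),
        # TS attempts are the slow sealers (zap abandoned), so their seal
        # grows several-fold slower
        seal_tau = exp(rnorm(1, log(16), 0.45)) *
          (if (ep == "TS") 5 else 1),
        touch_time = stats::runif(1, 3, 8),
        release_delay = stats::runif(1, 0.5, 1.5)
      )
    }) |> dplyr::bind_rows()

    sessions <- if (render_logs) {
      purrr::pmap(rows, function(cell_id, cell_type, endpoint, r_e, r_in,
                                 tau_m, e_rest, r_a, v_bd, noise_rms,
                                 seal_tau, touch_time, release_delay) {
        cp <- circuit_params(r_e = r_e, r_in = r_in, tau_m = tau_m,
                             e_rest = e_rest, r_a = r_a, v_bd = v_bd,
                             noise_rms = noise_rms)
        sc <- session_scenario(endpoint = endpoint, touch_time = touch_time,
                               release_time = touch_time + release_delay,
                               seal_tau = seal_tau)
        simulate_session(cp, sc, sampling_rate = sampling_rate)
      })
    } else NULL
  })
  list(truth = rows, sessions = sessions)
}
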