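# Shared fixtures: quick parameter sets and hand-built traces.

quick_params <- function(...) {
  args <- utils::modifyList(
    list(r_in = 100, tau_m = 10, tau_e = 0.1, bridge_error = 20,
         e_rest = -70, noise_rms = 0),
    list(...))
  do.call(circuit_params, args)
}

quick_step <- function(...) {
  args <- utils::modifyList(list(onset = 0.1, amplitude = -0.1), list(...))
  do.call(step_protocol, args)
}

# build a cc_trace directly from a voltage vector (40 kHz unless stated)
make_trace <- function(voltage, protocol = quick_step(), fs = 40000,
                       current = NULL) {
  n <- length(voltage)
  time <- (seq_len(n) - 1) / fs
  if (is.null(current)) {
    on <- time >= protocol$onset &
      time < protocol$onset + protocol$duration
    current <- ifelse(on, protocol$amplitude, 0)
  }
  touchzap:::new_cc_trace(time, voltage, current, fs, protocol)
}

# independent nonlinear two-exponential least-squares oracle
two_exp_oracle <- function(tr, proto = attr(tr, "protocol")) {
  on <- tr$time >= proto$onset & tr$time < proto$onset + proto$duration
  tt <- tr$time[on] - proto$onset
  vv <- tr$voltage[on]
  a0 <- min(vv) - vv[1]
  fit <- minpack.lm::nlsLM(
    vv ~ e + a1 * (1 - exp(-tt / t1)) + a2 * (1 - exp(-tt / t2)),
    start = list(e = vv[1], a1 = a0 * 0.2, a2 = a0 * 0.8,
                 t1 = 1.5e-4, t2 = 5e-3),
    lower = c(-120, -60, -60, 1e-5, 3.5e-4),
    upper = c(0, 60, 60, 4e-4, 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 400))
  co <- coef(fit)
  list(tau_m = co[["t2"]] * 1000,
       r_in = abs(co[["a2"]] / proto$amplitude),
       r_a = abs(co[["a1"]] / proto$amplitude))
}

# a stereotyped spike waveform built on the sample grid: linear rise at a
# known max slope to a known peak, linear fall, with a slow approach ramp
# so the detector's threshold crossing is not the fastest segment
spike_fixture <- function(fs = 40000, v_rest = -76, peak = 11,
                          dvdt_max = 230, onset = 0.05, duration = 0.25) {
  dt_ms <- 1000 / fs
  n <- round((onset + duration + 0.05) * fs)
  time <- (seq_len(n) - 1) / fs
  v <- rep(v_rest, n)
  step_idx <- which(time >= onset & time < onset + duration)
  # approach ramp at 100 mV/ms from rest to -50 starting 2 ms into the step
  t_ramp <- onset + 0.002
  i <- which(time >= t_ramp)[1]
  vcur <- v_rest
  while (vcur < -50 - 1e-9) {
    vcur <- min(vcur + 100 * dt_ms, -50)
    v[i] <- vcur
    i <- i + 1
  }
  # spike: rise at exactly dvdt_max per ms, clamped at the peak
  k <- 0
  repeat {
    vv <- min(-50 + dvdt_max * k * dt_ms, peak)
    v[i] <- vv
    i <- i + 1
    k <- k + 1
    if (vv >= peak) break
  }
  # fall to -60 over 1.5 ms, then back to rest
  fall <- seq(peak, -60, length.out = round(1.5 / dt_ms))
  v[i:(i + length(fall) - 1)] <- fall
  v[(i + length(fall)):n] <- v_rest
  proto <- step_protocol(onset = onset, duration = duration,
                         amplitude = 0.25, tail = 0.05)
  make_trace(v, proto, fs)
}
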