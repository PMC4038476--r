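test_that("per-pulse resistance recovers the bath electrode resistance", {
  p <- circuit_params(r_e = 6, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "FAIL",
                                              touch_time = NA,
                                              release_time = 6))
  series <- pulse_resistance_series(log)
  # -1.11 nA across 6 MOhm: -6.66 mV deflections
  expect_equal(mean(series$r_total), 6, tolerance = 1e-2)
  expect_equal(mean(series$r_total * series$amplitude), -6.66,
               tolerance = 0.02)
})

test_that("whole-cell resistance approaches the series sum of the circuit", {
  p <- circuit_params(r_e = 6, r_a = 35, r_in = 56, tau_m = 9.8,
                      v_bd = -333, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "TZ"))
  series <- pulse_resistance_series(log)
  zap_t <- truth_events(log)$time[truth_events(log)$kind == "zap"]
  post <- series[series$time > zap_t + 2, ]
  # tau_m truncates the plateau slightly: documented tolerance
  expect_equal(median(post$r_total), 6 + 35 + 56, tolerance = 0.05)
})

test_that("zero-length and pulse-free logs give empty series", {
  p <- circuit_params(noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "FAIL",
                                              touch_time = NA,
                                              release_time = 6))
  empty <- log[0, ]
  attributes(empty) <- attributes(log)[c("class", "names")]
  attr(empty, "pulse") <- attr(log, "pulse")
  attr(empty, "sampling_rate") <- sampling_rate(log)
  expect_equal(nrow(pulse_resistance_series(empty)), 0)

  bad <- log
  attr(bad, "pulse") <- NULL
  expect_error(pulse_resistance_series(bad), "pulse")
  attr(bad, "pulse") <- pulse_train(amplitude = -1)
  attr(bad, "pulse")$amplitude <- 0
  expect_error(pulse_resistance_series(bad), "zero")
})

test_that("touch detection lands within a pulse of the injected contact", {
  p <- circuit_params(r_e = 6, v_bd = -333, noise_rms = 0)
  sc <- session_scenario(endpoint = "TZ", touch_time = 5,
                         release_time = 6, touch_dr = 0.5)
  log <- simulate_session(p, sc)
  series <- pulse_resistance_series(log)
  touch <- detect_touch(series)
  expect_equal(nrow(touch), 1)
  expect_lt(abs(touch$time - 5), 0.15)
  expect_equal(touch$value, 0.5, tolerance = 0.2)

  # flat series: nothing to find
  flat <- tibble::tibble(time = seq(0, 20, by = 0.1),
                         r_total = 6, amplitude = -1.11, v_min = -6.7)
  expect_equal(nrow(detect_touch(flat)), 0)
})

test_that("20% resistance fluctuations abort the attempt as unstable", {
  p <- circuit_params(r_e = 6, noise_rms = 0)
  sc <- session_scenario(endpoint = "FAIL", touch_time = NA,
                         release_time = 6, artifact_frac = 0.1,
                         artifact_hz = 1.5)
  log <- simulate_session(p, sc)
  series <- pulse_resistance_series(log)
  touch <- detect_touch(series)
  expect_equal(nrow(touch), 0)
  expect_identical(attr(touch, "qc"), "unstable")
})

test_that("zap detection matches simulator ground truth", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "TZ"))
  zaps <- detect_zaps(log)
  truth <- truth_events(log)
  expect_equal(nrow(zaps), 1)
  expect_lt(abs(zaps$value - truth$value[truth$kind == "zap"]), 2)

  # whole-cell-only style log (no zap): nothing detected
  flat <- simulate_session(p, session_scenario(endpoint = "FAIL",
                                               touch_time = NA,
                                               release_time = 6))
  expect_equal(nrow(detect_zaps(flat)), 0)
})

test_that("two-zap sessions yield two events 100-150 mV apart", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "TZ", n_zaps = 2,
                                              second_zap_offset = 120))
  zaps <- detect_zaps(log)
  expect_equal(nrow(zaps), 2)
  dv <- zaps$value[2] - zaps$value[1]
  expect_gte(dv, 100)
  expect_lte(dv, 150)
  truth <- truth_events(log)
  expect_equal(zaps$value,
               truth$value[truth$kind == "zap"], tolerance = 0.02)
})

test_that("zap delay subtracts the pressure-release annotation", {
  ev <- tibble::tibble(time = 12.6, kind = "zap", value = -333)
  ann <- tibble::tibble(time = 10, kind = "pressure_release",
                        value = NA_real_)
  expect_equal(measure_zap_timing(ev, ann), 2.6)
  expect_error(measure_zap_timing(ev, ann[0, ]), "pressure_release")
  early <- tibble::tibble(time = 9, kind = "zap", value = -333)
  expect_error(measure_zap_timing(early, ann), "ordering")
  none <- ev[0, ]
  expect_true(is.na(measure_zap_timing(none, ann)))
})

test_that("endpoint rules map event sequences to TZ/TZS/TS/FAIL", {
  mk <- function(kinds, times = seq_along(kinds)) {
    tibble::tibble(time = times, kind = kinds,
                   value = ifelse(kinds == "zap", -300, NA_real_))
  }
  expect_equal(classify_endpoint(mk(c("touch", "zap")))$endpoint, "TZ")
  expect_equal(
    classify_endpoint(mk(c("touch", "zap", "reseal",
                           "suction_break")))$endpoint, "TZS")
  expect_equal(classify_endpoint(mk(c("touch", "suction_break")))$endpoint,
               "TS")
  bad <- classify_endpoint(mk(c("suction_break", "touch")))
  expect_equal(bad$endpoint, "FAIL")
  expect_match(bad$reason, "suction precedes touch")
  expect_equal(classify_endpoint(mk(character(0)))$endpoint, "FAIL")
  # zap after reseal without suction is not a clean sequence
  odd <- classify_endpoint(mk(c("touch", "zap", "reseal")))
  expect_equal(odd$endpoint, "FAIL")
})

test_that("the full chain reproduces each scenario's endpoint", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  for (ep in c("TZ", "TZS", "TS")) {
    log <- simulate_session(p, session_scenario(endpoint = ep))
    call <- classify_endpoint(detect_events(log), annotations(log))
    expect_equal(call$endpoint, ep)
    if (ep != "TS") {
      expect_gte(call$n_zaps, 1)
      expect_lt(abs(call$v_zap - (-333)), 3)
      expect_gt(call$t_zap, 0)
    } else {
      expect_equal(call$n_zaps, 0)
      expect_true(is.na(call$t_zap))
    }
  }
})

test_that("endpoint calls survive moderate noise", {
  # per-pulse resistance noise scales as 1/sqrt(samples per plateau), so
  # noisy sessions are rendered near the acquisition rate regime
  p <- circuit_params(v_bd = -333, noise_rms = 1)
  for (ep in c("TZ", "TZS", "TS")) {
    log <- simulate_session(p, session_scenario(endpoint = ep),
                            sampling_rate = 8000, seed = 3)
    call <- classify_endpoint(detect_events(log), annotations(log))
    expect_equal(call$endpoint, ep)
  }
})

test_that("resistance series and session plots build", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "TZ"))
  expect_s3_class(plot_resistance(pulse_resistance_series(log),
                                  truth_events(log)), "ggplot")
  expect_s3_class(autoplot(log), "ggplot")
})
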