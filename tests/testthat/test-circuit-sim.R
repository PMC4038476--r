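test_that("step-response steady state follows Ohm's law", {
  p <- circuit_params(r_in = 100, tau_m = 10, tau_e = 0, bridge_error = 0,
                      e_rest = -70, noise_rms = 0)
  tr <- simulate_step_response(p, quick_step())
  expect_equal(estimate_v_ss(tr), -80, tolerance = 1e-3)

  # zero input stays flat at rest
  tr0 <- simulate_step_response(p, step_protocol(amplitude = 0))
  expect_true(all(tr0$voltage == -70))
  expect_true(all(tr0$current == 0))
})

test_that("two-exponential closed form matches an independent ODE solution", {
  p <- quick_params()
  proto <- quick_step()
  tr <- simulate_step_response(p, proto)
  # closed form at onset + 0.5 ms
  v_expect <- -70 - 0.1 * 20 * (1 - exp(-5)) - 0.1 * 100 * (1 - exp(-0.05))
  i <- which.min(abs(tr$time - (proto$onset + 5e-4)))
  expect_equal(tr$voltage[i], v_expect, tolerance = 1e-9)
  expect_equal(v_expect, -72.4742, tolerance = 1e-4)

  # independent route: integrate the circuit ODE with deSolve
  rhs <- function(t, y, parms) {
    i_cmd <- if (t >= proto$onset &&
                 t < proto$onset + proto$duration) proto$amplitude else 0
    list(c((i_cmd * p$bridge_error - y[1]) / (p$tau_e / 1000),
           (i_cmd * p$r_in - y[2]) / (p$tau_m / 1000)))
  }
  probe <- proto$onset + c(5e-4, 2e-3, 0.01, 0.05)
  sol <- deSolve::lsoda(c(0, 0), times = c(0, probe), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  v_ode <- p$e_rest + sol[-1, 2] + sol[-1, 3]
  v_sim <- sapply(probe, function(tt)
    tr$voltage[which.min(abs(tr$time - tt))])
  expect_equal(unname(v_sim), unname(v_ode), tolerance = 1e-6)
})

test_that("step simulation validates sampling and duration", {
  p <- quick_params(tau_e = 0.1)
  expect_error(simulate_step_response(p, quick_step(), sampling_rate = 1000),
               "tau_e")
  expect_error(simulate_step_response(p, step_protocol(duration = 0.1)),
               "200 ms")
  expect_error(circuit_params(v_bd = -50), "-100")
  expect_error(circuit_params(tau_e = 12, tau_m = 10), "tau_m")
})

test_that("trace content is independent of sampling rate on a common grid", {
  p <- quick_params()
  tr40 <- simulate_step_response(p, quick_step(), sampling_rate = 40000)
  tr80 <- simulate_step_response(p, quick_step(), sampling_rate = 80000)
  expect_equal(tr80$voltage[seq(1, 2 * nrow(tr40), by = 2)], tr40$voltage,
               tolerance = 1e-12)
})

test_that("noise draws are reproducible under a fixed seed", {
  p <- quick_params(noise_rms = 1)
  a <- simulate_step_response(p, quick_step(), seed = 5)
  b <- simulate_step_response(p, quick_step(), seed = 5)
  expect_identical(a$voltage, b$voltage)
  c <- simulate_step_response(p, quick_step(), seed = 6)
  expect_false(identical(a$voltage, c$voltage))
})

test_that("whole-cell steady-state invariant holds with noise", {
  p <- quick_params(noise_rms = 0.5)
  tr <- simulate_step_response(p, quick_step(), seed = 1)
  v_ss <- estimate_v_ss(tr)
  n_win <- sum(tr$time >= 0.2 & tr$time < 0.3)
  expect_lt(abs(abs(v_ss - p$e_rest) - 0.1 * (20 + 100)),
            10 * 0.5 / sqrt(n_win) + 0.01)
})

test_that("session zap fires when the seal crosses breakdown", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  sc <- session_scenario(endpoint = "TZ")
  log <- simulate_session(p, sc)
  ev <- truth_events(log)
  zap <- ev[ev$kind == "zap", ]
  expect_equal(nrow(zap), 1)
  # -333 / -1.11 = 300 MOhm: resistance at the zap equals V_zap / amplitude
  r_at_zap <- zap$value / -1.11
  expect_gte(r_at_zap, 300)
  seal <- sc$seal_ceiling * (1 - exp(-(zap$time - sc$release_time) /
                                       sc$seal_tau))
  # within one sample of the crossing
  dr_per_sample <- sc$seal_ceiling / sc$seal_tau / sampling_rate(log) * 5
  expect_equal(r_at_zap, p$r_e + sc$touch_dr + seal,
               tolerance = max(dr_per_sample, 0.05))
})

test_that("FAIL scenario with no touch keeps resistance at R_e", {
  p <- circuit_params(r_e = 6, noise_rms = 0)
  sc <- session_scenario(endpoint = "FAIL", touch_time = NA,
                         release_time = 6)
  log <- simulate_session(p, sc)
  series <- pulse_resistance_series(log)
  expect_gt(nrow(series), 100)
  expect_equal(mean(series$r_total), 6, tolerance = 0.01)
  expect_lt(max(abs(series$r_total - 6)), 0.1)
})

test_that("TZS ground truth follows the touch-zap-reseal-suction order", {
  p <- circuit_params(v_bd = -333, noise_rms = 0)
  log <- simulate_session(p, session_scenario(endpoint = "TZS"))
  ev <- truth_events(log)
  expect_identical(ev$kind, c("touch", "zap", "reseal", "suction_break"))
  expect_true(!is.unsorted(ev$time))
})

test_that("unreachable breakdown voltage raises a named error", {
  p <- circuit_params(v_bd = -520, noise_rms = 0)
  sc <- session_scenario(endpoint = "TZ", seal_ceiling = 300)
  expect_error(simulate_session(p, sc), "unreachable")
})

test_that("cohorts are reproducible and honor the endpoint mix", {
  a <- simulate_cohort(10, endpoint_mix = "TZ", seed = 9,
                       render_logs = FALSE)
  b <- simulate_cohort(10, endpoint_mix = "TZ", seed = 9,
                       render_logs = FALSE)
  expect_identical(a$truth, b$truth)

  big <- simulate_cohort(1000, cell_type = "neuron", seed = 21,
                         render_logs = FALSE)
  mix <- table(big$truth$endpoint) / 1000
  for (ep in c(TZ = 0.48, TZS = 0.40, TS = 0.12) |> names()) {
    p0 <- c(TZ = 0.48, TZS = 0.40, TS = 0.12)[[ep]]
    expect_lt(abs(mix[[ep]] - p0), 3 * sqrt(p0 * (1 - p0) / 1000))
  }
})

test_that("rendered cohort sessions are deterministic given the seed", {
  a <- simulate_cohort(2, endpoint_mix = "TZ", seed = 4)
  b <- simulate_cohort(2, endpoint_mix = "TZ", seed = 4)
  expect_identical(a$sessions[[1]]$voltage, b$sessions[[1]]$voltage)
  expect_identical(truth_events(a$sessions[[2]]),
                   truth_events(b$sessions[[2]]))
})

test_that("glia draws respect the classifier's time-constant criterion", {
  coh <- simulate_cohort(200, cell_type = "glia", seed = 13,
                         render_logs = FALSE)
  expect_true(all(coh$truth$tau_m < 5))
  expect_true(all(coh$truth$tau_m > 0))
})

test_that("invalid cohort overrides are rejected", {
  expect_error(simulate_cohort(5, overrides = list(r_in = c(56, -3)),
                               seed = 1, render_logs = FALSE),
               "non-negative sd")
})

test_that("acquisition filter preserves DC and records its cutoff", {
  p <- quick_params()
  tr <- simulate_step_response(p, quick_step())
  f <- apply_acquisition_filter(tr, 10000)
  expect_equal(trace_meta(f)$filter_cutoff_hz, 10000)
  # steady levels are unchanged by a unity-DC-gain low-pass
  expect_equal(estimate_v_ss(f), estimate_v_ss(tr), tolerance = 1e-3)
})
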