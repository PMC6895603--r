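# In-silico protocols: pacing, rate dependence, voltage clamp, block
# calibration.

test_that("steady-state pacing is idempotent under restart", {
  p <- cm_parameters("control")
  a <- pace_to_steady_state(p, pacing_protocol())
  b <- pace_to_steady_state(p, pacing_protocol(beats = 10, tol = 1),
                            init = a$state)
  expect_lt(abs(b$features$ap$APD90_ms / a$features$ap$APD90_ms - 1),
            0.005)
})

test_that("extending the equilibration changes APD90 by < 1%", {
  p <- cm_parameters("control")
  short <- pace_to_steady_state(p, pacing_protocol(beats = 50, tol = 1e-3))
  long <- suppressWarnings(
    pace_to_steady_state(p, pacing_protocol(beats = 100, tol = 1e-9)))
  expect_lt(abs(long$features$ap$APD90_ms /
                  short$features$ap$APD90_ms - 1), 0.01)
})

test_that("the convergence report carries the required diagnostics", {
  p <- cm_parameters("control")
  a <- pace_to_steady_state(p, pacing_protocol())
  expect_true(a$convergence$converged)
  expect_lt(a$convergence$apd90_rel_change, 0.001)
  expect_lt(a$convergence$dia_cai_rel_change, 0.001)
  expect_true(a$convergence$trigger %in% c("tolerance", "beat_cap"))
  # provenance present
  expect_true(is.numeric(a$provenance$params_hash))
  expect_identical(a$provenance$solver$method, "lsoda")
})

test_that("control APD90 decreases monotonically from 1 to 3 Hz", {
  rd <- rate_dependence(cm_parameters("control"), c(1, 2, 3))
  expect_false(any(rd$flagged))
  expect_true(all(diff(rd$APD90_ms) < 0))
  # diastolic interval positive at every frequency (capture check)
  expect_true(all(rd$APD90_ms < 1000 / rd$frequency_hz))
})

test_that("the 1.5x g_CaL preset has longer APD90 at 1, 2 and 3 Hz", {
  rd <- rate_dependence(cm_parameters("control"), c(1, 2, 3))
  rdh <- rate_dependence(cm_parameters("hcm_1p5x_ical"), c(1, 2, 3))
  expect_true(all(rdh$APD90_ms > rd$APD90_ms))
})

test_that("a single-frequency table equals pace_to_steady_state", {
  p <- cm_parameters("control")
  rd <- rate_dependence(p, 1)
  ps <- pace_to_steady_state(p, pacing_protocol())
  expect_equal(rd$APD90_ms, ps$features$ap$APD90_ms, tolerance = 1e-6)
})

test_that("voltage-clamp I_CaL amplitude is linear in g_CaL within 5%", {
  p <- cm_parameters("control")
  amps <- vapply(c(0.5, 1, 1.5), function(f)
    voltage_clamp_ical(scale_conductance(p, "ICaL", f))$amplitude_pA_per_pF,
    numeric(1))
  expect_lt(abs(amps[1] / amps[2] - 0.5), 0.05 * 0.5)
  expect_lt(abs(amps[3] / amps[2] - 1.5), 0.05 * 1.5)
})

test_that("zero L-type conductance gives zero clamp amplitude", {
  p0 <- scale_conductance(cm_parameters("control"), "ICaL", 1e-12)
  expect_lt(voltage_clamp_ical(p0)$amplitude_pA_per_pF, 1e-9)
})

test_that("nifedipine subtraction equals the direct I_CaL amplitude", {
  p <- cm_parameters("control")
  direct <- voltage_clamp_ical(p)
  sub <- voltage_clamp_ical(p, nifedipine_subtraction = TRUE)
  expect_lt(abs(sub$amplitude_pA_per_pF / direct$amplitude_pA_per_pF
                - 1), 0.02)
})

test_that("block calibration: zero target gives zero block", {
  blk <- calibrate_block(cm_parameters("control"), "force_amplitude", 0)
  expect_equal(blk$fraction, 0)
})

test_that("block calibration hits its target and is monotone", {
  p <- cm_parameters("control")
  proto <- pacing_protocol()
  b1 <- calibrate_block(p, "force_amplitude", -0.06, proto)
  b2 <- calibrate_block(p, "force_amplitude", -0.11, proto)
  expect_gt(b2$fraction, b1$fraction)      # larger effect, larger block
  expect_gt(b1$fraction, 0)
  expect_lt(b2$fraction, 1)
  expect_lt(abs(attr(b2, "achieved") + 0.11), 0.005)
})

test_that("unreachable calibration targets fail loudly", {
  expect_error(
    calibrate_block(cm_parameters("control"), "force_amplitude", -0.999,
                    pacing_protocol()),
    "unreachable")
})
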