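# Generator contracts: determinism, exact noiseless round trips, and
# recovery of programmed group contrasts through the metrics pipeline.

test_that("force-trace generator round-trips exactly at zero noise", {
  g <- gen_force_trace(force_config(noise_sd = 0, dt_ms = 0.5))
  f <- contraction_features(g$trace)
  expect_equal(f$amplitude_mN, g$truth$amplitude_mN, tolerance = 1e-3)
  expect_equal(f$T1_80_ms, g$truth$T1_80_ms, tolerance = 0.5)
  expect_equal(f$T2_80_ms, g$truth$T2_80_ms, tolerance = 0.5)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_force_trace(force_config(noise_sd = 0.01, seed = 7))
  b <- gen_force_trace(force_config(noise_sd = 0.01, seed = 7))
  c <- gen_force_trace(force_config(noise_sd = 0.01, seed = 8))
  expect_identical(a$trace$value, b$trace$value)
  expect_false(identical(a$trace$value, c$trace$value))

  i1 <- gen_sarcomere_image(image_config(jitter_sd_um = 0.2, seed = 3))
  i2 <- gen_sarcomere_image(image_config(jitter_sd_um = 0.2, seed = 3))
  expect_identical(i1$image$intensity, i2$image$intensity)

  q1 <- gen_qt_rr(qtrr_config(seed = 5))
  q2 <- gen_qt_rr(qtrr_config(seed = 5))
  expect_identical(q1, q2)
})

test_that("overlapping pulses are refused", {
  expect_error(gen_force_trace(force_config(t1_ms = 400, t2_ms = 900,
                                            pacing_hz = 1)),
               "overlap")
})

test_that("programmed HCM-vs-control force contrast is recovered", {
  # +58% amplitude and +54% relaxation time between groups
  ctl <- gen_force_trace(force_config(noise_sd = 0.002, seed = 1))
  hcm <- gen_force_trace(force_config(amplitude_mN = 0.15 * 1.58,
                                      t2_ms = 200 * 1.54,
                                      noise_sd = 0.002, seed = 2))
  fc <- contraction_features(ctl$trace)
  fh <- contraction_features(hcm$trace)
  expect_lt(abs(fh$amplitude_mN / fc$amplitude_mN - 1.58), 0.03 * 1.58)
  expect_lt(abs(fh$T2_80_ms / fc$T2_80_ms - 1.54), 0.03 * 1.54)
})

test_that("T2 is recovered within 5 ms at SNR 20", {
  g <- gen_force_trace(force_config(t2_ms = 250,
                                    noise_sd = 0.15 / 20, seed = 42))
  f <- contraction_features(g$trace)
  expect_lt(abs(f$T2_80_ms - 250), 5)
})

test_that("AP generator round-trips APDs exactly at zero noise", {
  g <- gen_ap_trace(ap_config(noise_sd = 0))
  f <- ap_features(g$trace)
  expect_equal(f$APD50_ms, 154.9, tolerance = 0.5)
  expect_equal(f$APD90_ms, 242.2, tolerance = 0.5)
  expect_equal(f$TOP_mV, -76.1, tolerance = 0.1)
  expect_equal(f$APA_mV, 100.9, tolerance = 0.2)
})

test_that("programmed APD90 group ratio is recovered within 2%", {
  a <- gen_ap_trace(ap_config(noise_sd = 0))
  b <- gen_ap_trace(ap_config(apd50_ms = 298.9, apd90_ms = 364,
                              noise_sd = 0))
  fa <- ap_features(a$trace)
  fb <- ap_features(b$trace)
  ratio <- fb$APD90_ms / fa$APD90_ms
  expect_lt(abs(ratio - 364 / 242.2), 0.02 * ratio)
})

test_that("TOP is recovered within 2 mV at 2 mV noise", {
  g <- gen_ap_trace(ap_config(noise_sd = 2, n_beats = 5, seed = 9))
  f <- ap_features(g$trace)
  expect_lt(abs(f$TOP_mV - (-76.1)), 2)
})

test_that("force-pCa generator round-trips through hill_fit", {
  g <- gen_force_pca(pca_config(noise_sd = 0))
  fit <- hill_fit(g$data)
  expect_equal(unname(coef(fit)),
               c(g$truth$Fmax, g$truth$pCa50, g$truth$nH),
               tolerance = 1e-6)
  # seeded reproducibility
  a <- gen_force_pca(pca_config(noise_sd = 0.02, seed = 4))
  b <- gen_force_pca(pca_config(noise_sd = 0.02, seed = 4))
  expect_identical(a$data$force_mN, b$data$force_mN)
})

test_that("QT/RR table round-trips through qtc and RR = 1 is identity", {
  g <- gen_qt_rr(qtrr_config(n = 30, seed = 2))
  expect_equal(qtc(g$QT_ms, g$RR_s, "bazett"), g$QTcB_ms,
               tolerance = 1e-12)
  expect_equal(qtc(g$QT_ms, g$RR_s, "fridericia"), g$QTcF_ms,
               tolerance = 1e-12)
  g$RR_s <- rep(1, nrow(g))
  expect_equal(qtc(g$QT_ms, g$RR_s, "bazett"), g$QT_ms)
})
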