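# Feature extraction from voltage and force traces.

test_that("analytic triangle AP yields closed-form features", {
  # instant rise -80 -> +20 mV, linear fall back over 300 ms
  tt <- seq(0, 400, by = 0.1)
  v <- ifelse(tt < 10, -80,
              ifelse(tt <= 310, 20 - (tt - 10) / 300 * 100, -80))
  f <- ap_features(as_trace(tt, v))
  expect_equal(f$APA_mV, 100, tolerance = 1e-3)
  expect_equal(f$TOP_mV, -80, tolerance = 1e-6)
  # APA 100: 50% repol at -30 mV -> 150 ms after rise; 90% at -70 -> 270
  expect_equal(f$APD50_ms, 150, tolerance = 0.2)
  expect_equal(f$APD90_ms, 270, tolerance = 0.2)
  expect_false(f$censored)
})

test_that("logistic upstroke Vmax matches the analytic maximum slope", {
  # V(t) = -80 + 120 / (1 + exp(-(t - 30) / 2)): max dV/dt = 120/(4*2)
  tt <- seq(0, 400, by = 0.05)
  v <- -80 + 120 / (1 + exp(-(tt - 30) / 2)) -
    ifelse(tt > 50, (tt - 50) * 0.4, 0)
  f <- ap_features(as_trace(tt, v))
  expect_equal(f$Vmax_V_per_s, 120 / 8, tolerance = 0.01)
})

test_that("repolarization censoring is flagged", {
  tt <- seq(0, 100, by = 0.1)
  v <- ifelse(tt < 10, -80, 20)  # never repolarizes
  f <- ap_features(as_trace(tt, v))
  expect_true(f$censored)
  expect_true(is.na(f$APD90_ms))
})

test_that("no-AP input raises an error", {
  tt <- seq(0, 100, by = 0.1)
  expect_error(ap_features(as_trace(tt, rep(-80, length(tt)))),
               "no action potential")
})

test_that("symmetric triangular force pulse gives closed-form features", {
  tt <- seq(0, 500, by = 0.5)
  v <- pmax(0, 1 - abs(tt - 150) / 100)  # rise 100 ms, fall 100 ms, 1 mN
  f <- contraction_features(as_trace(tt, v, "force", "mN"))
  expect_equal(f$amplitude_mN, 1, tolerance = 0.02)
  expect_equal(f$T1_80_ms, 80, tolerance = 1)
  expect_equal(f$T2_80_ms, 80, tolerance = 1)
})

test_that("bi-exponential pulse matches a dense brute-force oracle", {
  shape <- function(t) {
    x <- pmax(t - 50, 0)
    (exp(-x / 120) - exp(-x / 30)) * (t > 50)
  }
  tt <- seq(0, 900, by = 0.5)
  v <- shape(tt)
  f <- contraction_features(as_trace(tt, v, "force", "mN"))

  # brute-force oracle on a 100x denser grid: direct threshold scan
  td <- seq(0, 900, by = 0.005)
  vd <- shape(td)
  pk <- which.max(vd)
  amp <- vd[pk] - quantile(vd, 0.10)
  lvl <- quantile(vd, 0.10) + 0.2 * amp
  up <- max(td[which(td < td[pk] & vd < lvl)])
  dn <- min(td[which(td > td[pk] & vd < lvl)])
  expect_equal(f$T1_80_ms, td[pk] - up, tolerance = 0.5)
  expect_equal(f$T2_80_ms, dn - td[pk], tolerance = 0.5)
})

test_that("force features are scale-equivariant and shift-invariant", {
  g <- gen_force_trace(force_config(noise_sd = 0, duration_s = 4))
  tr <- g$trace
  f0 <- contraction_features(tr)
  f3 <- contraction_features(as_trace(tr$time_ms, 3 * tr$value,
                                      "force", "mN"))
  expect_equal(f3$amplitude_mN, 3 * f0$amplitude_mN, tolerance = 1e-6)
  expect_equal(f3$T1_80_ms, f0$T1_80_ms, tolerance = 1e-6)
  expect_equal(f3$T2_80_ms, f0$T2_80_ms, tolerance = 1e-6)
  fs <- contraction_features(as_trace(tr$time_ms + 500, tr$value,
                                      "force", "mN"))
  expect_equal(fs$peak_time_ms, f0$peak_time_ms + 500, tolerance = 1e-6)
  expect_equal(fs$T2_80_ms, f0$T2_80_ms, tolerance = 1e-6)
})

test_that("features are stable under 10 kHz -> 2 kHz decimation", {
  g <- gen_force_trace(force_config(noise_sd = 0, dt_ms = 0.1,
                                    duration_s = 4))
  tr <- g$trace
  f10 <- contraction_features(tr)
  keep <- seq(1, nrow(tr), by = 5)
  f2 <- contraction_features(as_trace(tr$time_ms[keep],
                                      tr$value[keep], "force", "mN"))
  expect_equal(f2$T1_80_ms, f10$T1_80_ms, tolerance = 1)
  expect_equal(f2$T2_80_ms, f10$T2_80_ms, tolerance = 1)
})

test_that("percent change is exact and antisymmetric as algebra demands", {
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(2, 1.42), -29)
  # a -20% change reversed is +25%
  expect_equal(percent_change(0.8, 1), 25)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("QTc corrections follow the stated formulas", {
  expect_equal(qtc(400, 1, "bazett"), 400)
  expect_equal(qtc(400, 1, "fridericia"), 400)
  expect_equal(qtc(400, 0.64, "bazett"), 500)
  # independent element-wise evaluation oracle
  set.seed(42)
  qt <- runif(50, 300, 500)
  rr <- runif(50, 0.5, 1.5)
  expect_equal(qtc(qt, rr, "bazett"), qt * rr^(-0.5),
               tolerance = 1e-12)
  expect_equal(qtc(qt, rr, "fridericia"), qt * exp(-log(rr) / 3),
               tolerance = 1e-12)
  expect_error(qtc(-1, 1), "positive")
})

test_that("MAP-shaped traces are processed unchanged (MAPD90)", {
  # MAP morphology: slower upstroke, rounded dome
  tt <- seq(0, 600, by = 0.5)
  v <- -20 + 35 / (1 + exp(-(tt - 30) / 4)) /
    (1 + exp((tt - 280) / 30))
  f <- ap_features(as_trace(tt, v))
  expect_gt(f$APD90_ms, 200)
  expect_false(f$censored)
})
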