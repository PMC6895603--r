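# Electromechanical cell model: rate equations, conservation, parameter
# perturbation and block plumbing.

test_that("R and compiled derivatives agree at perturbed states", {
  p <- cm_parameters("control")
  base <- unclass(cm_initial_state("control", paced = TRUE))
  set.seed(1)
  for (i in 1:5) {
    st <- base
    st["V"] <- runif(1, -85, 30)
    gates <- c("m", "h", "j", "d", "f", "fca", "xr", "xs", "y", "g",
               "rto", "sto", "TRPN", "XB")
    st[gates] <- pmin(pmax(base[gates] * runif(length(gates), 0.5, 1.5),
                           0), 1)
    st["Cai"] <- base[["Cai"]] * runif(1, 0.5, 20)
    st["CaSR"] <- base[["CaSR"]] * runif(1, 0.5, 1.5)
    dR <- cm_derivatives(st, p)
    mat <- ehtkit:::.cm_run(st, p, times = c(0, 1e-6), stim_on = FALSE)
    # compiled side checked through one tiny lsoda step: the state after
    # dt=1e-6 ms must match the R-side forward-Euler prediction closely
    dC <- (mat[2, ehtkit:::.cm_state_names] - st) / 1e-6
    big <- abs(dR) > 1e-6
    expect_lt(max(abs(dC[big] - dR[big]) / abs(dR[big])), 1e-3)
  }
})

test_that("component currents sum to the total ionic current", {
  p <- cm_parameters("control")
  for (paced in c(TRUE, FALSE)) {
    st <- unclass(cm_initial_state("control", paced = paced))
    cur <- cm_currents(st, p)
    comp <- sum(cur[c("I_Na", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_f",
                      "I_to", "I_NaCa", "I_NaK", "I_bNa", "I_bCa",
                      "I_pCa")])
    expect_lt(abs(comp - cur[["I_ion"]]) / max(abs(cur[["I_ion"]]),
                                               1e-12), 1e-9)
  }
})

test_that("the resting state is a near-fixed point and drifts < 0.5 mV/10 s", {
  p <- cm_parameters("control")
  rest <- unclass(cm_initial_state("control"))
  d <- cm_derivatives(rest, p)
  # voltage and gating derivatives vanish at rest (slow ion pools are
  # held by their own balance and move on much longer timescales)
  expect_lt(abs(d[["V"]]), 1e-3)
  gates <- c("m", "h", "j", "d", "f", "xr", "xs", "y", "rto", "sto")
  expect_lt(max(abs(d[gates])), 1e-4)
  m <- ehtkit:::.cm_run(rest, p, c(0, 10000), stim_on = FALSE)
  expect_lt(abs(m[2, "V"] - m[1, "V"]), 0.5)
})

test_that("gating variables set to their V-dependent steady state are stationary", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control"))
  V <- st[["V"]]
  st["m"] <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  st["xr"] <- 1 / (1 + exp((-26 - V) / 7))
  st["rto"] <- 1 / (1 + exp((20 - V) / 6))
  d <- cm_derivatives(st, p)
  expect_lt(abs(d[["m"]]), 1e-10)
  expect_lt(abs(d[["xr"]]), 1e-10)
  expect_lt(abs(d[["rto"]]), 1e-10)
})

test_that("finite-difference Jacobian matches brute-force directional differences", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control", paced = TRUE))
  # pull bounded states slightly into the interior so that symmetric
  # perturbations stay admissible
  gates <- c("m", "h", "j", "d", "f", "fca", "xr", "xs", "y", "g",
             "TRPN", "XB", "rto", "sto")
  st[gates] <- pmin(pmax(st[gates], 1e-3), 1 - 1e-3)
  nS <- length(st)
  eps <- pmin(1e-5 * pmax(abs(st), 1e-3), 2e-4)
  # column-by-column finite-difference Jacobian
  J <- matrix(0, nS, nS)
  for (i in seq_len(nS)) {
    sp <- st; sp[i] <- sp[i] + eps[i]
    sm <- st; sm[i] <- sm[i] - eps[i]
    J[, i] <- (cm_derivatives(sp, p) - cm_derivatives(sm, p)) /
      (2 * eps[i])
  }
  # independent brute-force oracle: directional central differences
  set.seed(7)
  for (k in 1:3) {
    dir <- rnorm(nS)
    hvec <- dir * eps               # component-scaled direction
    fp <- cm_derivatives(st + hvec, p)
    fm <- cm_derivatives(st - hvec, p)
    fdir <- (fp - fm) / 2
    jdir <- as.numeric(J %*% hvec)
    big <- abs(jdir) > 1e-3 * max(abs(jdir))
    expect_lt(max(abs(fdir[big] - jdir[big]) / abs(jdir[big])), 1e-4)
  }
})

test_that("invalid states are rejected with the offending field named", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control"))
  st[["Cai"]] <- NaN
  expect_error(cm_derivatives(st, p), "Cai")
  st <- unclass(cm_initial_state("control"))
  st[["m"]] <- 1.5
  expect_error(cm_derivatives(st, p), "m")
})

test_that("scale_conductance touches exactly one field", {
  p <- cm_parameters("control")
  p2 <- scale_conductance(p, "ICaL", 1.5)
  expect_equal(p2[["g_CaL"]], 1.5 * p[["g_CaL"]])
  other <- setdiff(names(unclass(p)), "g_CaL")
  expect_identical(as.numeric(unclass(p2)[other]),
                   as.numeric(unclass(p)[other]))
  expect_error(scale_conductance(p, "nonsense", 2), "unknown")
  expect_error(scale_conductance(p, "ICaL", -1), "positive")
  # the hcm preset is exactly the control with a 1.5-fold L-type term
  expect_equal(as.numeric(unclass(cm_parameters("hcm_1p5x_ical"))),
               as.numeric(unclass(scale_conductance(p, "ICaL", 1.5))))
})

test_that("fractional block scales the conductance by (1 - b)", {
  p <- cm_parameters("control")
  pb0 <- apply_block(p, block_spec("ICaL", 0))
  expect_equal(as.numeric(unclass(pb0)), as.numeric(unclass(p)))
  pb <- apply_block(p, block_spec("ICaL", fraction = 1))
  expect_equal(pb[["g_CaL"]], 0)
  # concentration mode follows the Hill relation
  b <- block_spec("ICaL", conc = 3, ic50 = 3, hill = 1)
  expect_equal(b$fraction, 0.5)
  expect_error(block_spec("ICaL", fraction = 1.2), "\\[0, 1\\]")
  expect_error(block_spec("ICaL", conc = 3, ic50 = -1), "ic50")
})

test_that("active force is zero without attached cross-bridges and bounded", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control"))
  st[["XB"]] <- 0
  expect_equal(active_force(st, p), 0)
  st[["XB"]] <- 1
  expect_equal(active_force(st, p), p[["F_max"]])
  expect_equal(active_force(st, p, as_mN = TRUE),
               p[["F_max"]] * p[["cross_section"]])
})

test_that("clamped saturating Ca2+ drives force to a bounded plateau", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control"))
  st[["Cai"]] <- 0.01  # saturating
  m <- ehtkit:::.cm_run(st, p, seq(0, 2000, by = 10), stim_on = FALSE,
                        clamp = TRUE, buffer_ca = TRUE)
  fr <- m[, "F_stress"]
  late <- m[, "time"] >= 100
  expect_true(all(diff(fr[late]) > -1e-6))    # monotone approach
  expect_lt(max(fr), p[["F_max"]])            # bounded
  expect_gt(fr[length(fr)], 0.9 * fr[length(fr) - 20])  # plateaued
})

test_that("force peaks after the AP upstroke within the beat", {
  paced <- pace_to_steady_state(cm_parameters("control"),
                                pacing_protocol())
  tr <- paced$trace
  t_vpeak <- tr$time_ms[which.max(tr$V_mV)]
  t_fpeak <- tr$time_ms[which.max(tr$F_mN)]
  expect_gt(t_fpeak, t_vpeak)   # mechanical delay > 0
})

test_that("gating variables stay within [0,1] over a paced protocol", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control", paced = TRUE))
  res <- ehtkit:::.cm_beat(st, p, 1000, dt_out = 0.5)
  gates <- c("m", "h", "j", "d", "f", "fca", "xr", "xs", "y", "g",
             "rto", "sto")
  gm <- res$mat[, gates]
  expect_gte(min(gm), -1e-6)
  expect_lte(max(gm), 1 + 1e-6)
})

test_that("simulation output is bit-identical across repeated runs", {
  p <- cm_parameters("control")
  st <- unclass(cm_initial_state("control", paced = TRUE))
  a <- ehtkit:::.cm_beat(st, p, 1000, dt_out = 0.5)
  b <- ehtkit:::.cm_beat(st, p, 1000, dt_out = 0.5)
  expect_identical(a$mat, b$mat)
})

test_that("parameter validation rejects physical impossibilities", {
  expect_error(cm_parameters("control", g_CaL = -1), "negative")
  expect_error(cm_parameters("control", Ca_o = 0), "> 0")
  expect_error(cm_parameters("control", bogus = 1), "unknown")
})

test_that("parameter sets and states survive a JSON round trip", {
  p <- cm_parameters("hcm_1p5x_ical")
  f <- tempfile(fileext = ".json")
  write_cm_json(p, f)
  p2 <- read_cm_json(f)
  expect_equal(unclass(p2), unclass(p))
  st <- cm_initial_state("control", paced = TRUE)
  f2 <- tempfile(fileext = ".json")
  write_cm_json(st, f2)
  expect_equal(unclass(read_cm_json(f2)), unclass(st))
})
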