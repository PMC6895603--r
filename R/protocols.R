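# In-silico experimental protocols: steady-state pacing, rate dependence,
# voltage-clamp I_CaL extraction, and fractional-block calibration.
# Integration uses the compiled model right-hand side (src/cmmodel.c)
# through deSolve's lsoda with the stiff-integration contract
# rtol 1e-6, atol 1e-8, max step 1 ms while the stimulus is active.

.cm_rtol <- 1e-6
.cm_atol <- 1e-8

# Low-level segment integration with the compiled RHS.
.cm_run <- function(state, params, times, stim_on = FALSE,
                    clamp = FALSE, buffer_ca = FALSE, hmax = NULL) {
  p <- unclass(params)
  p[["stim_on"]] <- as.numeric(stim_on)
  p[["clamp_mode"]] <- as.numeric(clamp)
  p[["buffer_ca"]] <- as.numeric(buffer_ca)
  if (is.null(hmax)) hmax <- if (stim_on) 1 else 0
  out <- deSolve::lsoda(
    y = unname(state[.cm_state_names]), times = times, func = "cm_derivs",
    parms = unname(p), dllname = "ehtkit", initfunc = "cm_initmod",
    nout = 17, outnames = .cm_current_names,
    rtol = .cm_rtol, atol = .cm_atol, hmax = hmax, maxsteps = 50000)
  colnames(out) <- c("time", .cm_state_names, .cm_current_names)
  out
}

# One paced beat: stimulus segment then diastolic segment.
# Returns the sampled matrix and the end state.
.cm_beat <- function(state, params, period_ms, dt_out) {
  sd <- params[["stim_dur"]]
  dt <- min(dt_out, 0.5)          # upstroke resolution cap
  n1 <- max(2L, ceiling(sd / dt) + 1L)
  t1 <- seq(0, sd, length.out = n1)
  seg1 <- .cm_run(state, params, t1, stim_on = TRUE)
  s1 <- seg1[nrow(seg1), .cm_state_names]
  dt1 <- sd / (n1 - 1)
  n2 <- max(2L, round((period_ms - sd) / dt1) + 1L)
  t2 <- seq(sd, period_ms, length.out = n2)
  seg2 <- .cm_run(s1, params, t2, stim_on = FALSE)
  mat <- rbind(seg1[-nrow(seg1), , drop = FALSE], seg2)
  list(mat = mat, state = seg2[nrow(seg2), .cm_state_names])
}

#' Pacing protocol specification
#'
#' @param hz pacing frequency (Hz).
#' @param beats maximum number of beats (the equilibration cap).
#' @param record number of final beats to record at fine resolution.
#' @param tol steady-state tolerance: maximum relative change of APD90
#'   and diastolic Ca2+ over the last 10 beats.
#' @param dt_ms output sampling interval for recorded beats (ms).
#' @return Object of class \code{pacing_protocol}.
#' @export
pacing_protocol <- function(hz = 1, beats = 300, record = 1,
                            tol = 0.001, dt_ms = 0.1) {
  stopifnot(hz > 0, beats >= 1, record >= 1, tol > 0, dt_ms > 0)
  structure(list(hz = hz, beats = as.integer(beats),
                 record = as.integer(record), tol = tol, dt_ms = dt_ms),
            class = "pacing_protocol")
}

#' Pace the cell model to steady state
#'
#' Paces the model at a fixed frequency until the steady-state criterion
#' is met (maximum relative change of APD90 and diastolic Ca2+ below
#' \code{tol} over the last 10 beats) or the beat cap is reached,
#' mirroring the equilibration practice of EHT action-potential
#' recordings. The final beat(s) are returned sampled at
#' \code{protocol$dt_ms} (default 0.1 ms).
#'
#' @param params a \code{\link{cm_parameters}} object.
#' @param protocol a \code{\link{pacing_protocol}}.
#' @param init optional initial state; defaults to the preset's stored
#'   1-Hz paced diastolic state when available, else the resting state.
#' @return Object of class \code{cm_paced}: list with \code{trace} (data
#'   frame: \code{time_ms}, \code{V_mV}, \code{F_mN}, \code{F_stress},
#'   \code{Cai_mM}, \code{ICaL_pA_per_pF}), \code{state} (end-diastolic
#'   state), \code{convergence} report, \code{features} (AP and
#'   contraction features of the final beat), \code{protocol}, and
#'   provenance (parameter hash, solver settings).
#' @export
pace_to_steady_state <- function(params, protocol = pacing_protocol(),
                                 init = NULL) {
  stopifnot(inherits(params, "cm_parameters"),
            inherits(protocol, "pacing_protocol"))
  if (is.null(init)) {
    preset <- attr(params, "preset")
    init <- if (!is.null(preset)) cm_initial_state(preset, paced = TRUE)
            else cm_initial_state("control", paced = TRUE)
  }
  state <- validate_cm_state(unclass(init))
  period <- 1000 / protocol$hz

  apd_hist <- rep(NA_real_, protocol$beats)
  cai_hist <- rep(NA_real_, protocol$beats)
  converged <- FALSE
  beats_run <- 0L
  for (b in seq_len(protocol$beats)) {
    res <- .cm_beat(state, params, period, dt_out = 1)
    state <- res$state
    beats_run <- b
    ap <- tryCatch(
      ap_features(as_trace(res$mat[, "time"], res$mat[, "V"])),
      error = function(e) NULL)
    apd_hist[b] <- if (is.null(ap) || ap$censored) NA_real_ else ap$APD90_ms
    cai_hist[b] <- state[["Cai"]]
    if (b >= 10) {
      w <- (b - 9):b
      da <- diff(range(apd_hist[w])) / mean(apd_hist[w])
      dc <- diff(range(cai_hist[w])) / mean(cai_hist[w])
      if (is.finite(da) && is.finite(dc) &&
          max(da, dc) < protocol$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("pacing did not meet the steady-state criterion within ",
            protocol$beats, " beats; returning final beats", call. = FALSE)

  # record the final beat(s) at fine resolution
  mats <- vector("list", protocol$record)
  for (r in seq_len(protocol$record)) {
    res <- .cm_beat(state, params, period, dt_out = protocol$dt_ms)
    state <- res$state
    m <- res$mat
    m[, "time"] <- m[, "time"] + (r - 1) * period
    mats[[r]] <- m
  }
  mat <- do.call(rbind, mats)
  cs <- params[["cross_section"]]
  trace <- data.frame(time_ms = mat[, "time"], V_mV = mat[, "V"],
                      F_mN = mat[, "F_stress"] * cs,
                      F_stress = mat[, "F_stress"],
                      Cai_mM = mat[, "Cai"],
                      ICaL_pA_per_pF = mat[, "I_CaL"])

  w <- max(1, beats_run - 9):beats_run
  apd_w <- apd_hist[w][is.finite(apd_hist[w])]
  conv <- list(
    converged = converged, beats_run = beats_run,
    trigger = if (converged) "tolerance" else "beat_cap",
    apd90_rel_change = if (length(apd_w) >= 2)
      diff(range(apd_w)) / mean(apd_w) else NA_real_,
    dia_cai_rel_change = diff(range(cai_hist[w])) / mean(cai_hist[w]))

  last <- mat[, "time"] >= (protocol$record - 1) * period
  vtr <- as_trace(mat[last, "time"], mat[last, "V"], "ap", "mV")
  ftr <- as_trace(trace$time_ms, trace$F_mN, "force", "mN")
  feats <- list(
    ap = tryCatch(ap_features(vtr, stim_time = vtr$time_ms[1]),
                  error = function(e) NULL),
    contraction = tryCatch(contraction_features(ftr),
                           error = function(e) NULL))

  structure(list(trace = trace, state = structure(state,
                                                  class = "cm_state"),
                 convergence = conv, features = feats,
                 protocol = protocol,
                 provenance = list(
                   params_hash = .params_hash(params),
                   solver = list(method = "lsoda", rtol = .cm_rtol,
                                 atol = .cm_atol, hmax_stim_ms = 1))),
            class = "cm_paced")
}

.params_hash <- function(params) {
  v <- unclass(params)
  sum(abs(v) * seq_along(v)) + sum(v^2)  # cheap deterministic fingerprint
}

#' @export
print.cm_paced <- function(x, ...) {
  cat("<cm_paced>", x$protocol$hz, "Hz,", x$convergence$beats_run,
      "beats,",
      if (x$convergence$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$features$ap)) {
    a <- x$features$ap
    cat(sprintf("  AP: TOP %.1f mV, APA %.1f mV, APD50 %.1f ms, APD90 %.1f ms\n",
                a$TOP_mV, a$APA_mV, a$APD50_ms, a$APD90_ms))
  }
  if (!is.null(x$features$contraction)) {
    f <- x$features$contraction
    cat(sprintf("  Force: amplitude %.4g mN, T1_80 %.0f ms, T2_80 %.0f ms\n",
                f$amplitude_mN, f$T1_80_ms, f$T2_80_ms))
  }
  invisible(x)
}

#' @export
plot.cm_paced <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$time_ms, x$trace$V_mV, type = "l",
                 xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::plot(x$trace$time_ms, x$trace$F_mN, type = "l",
                 xlab = "time (ms)", ylab = "force (mN)", ...)
  invisible(x)
}

#' APD and force rate dependence
#'
#' Runs \code{\link{pace_to_steady_state}} at each frequency and
#' tabulates APD90, APD50 and contraction features, the in-silico
#' analogue of cycle-length dependence measurements. Rows where 2:1
#' capture failure is detected (a beat without an AP) are flagged.
#'
#' @param params a \code{\link{cm_parameters}} object.
#' @param frequencies_hz frequencies in (0.2, 4] Hz.
#' @param protocol template \code{\link{pacing_protocol}} (its \code{hz}
#'   is replaced per row).
#' @return Data frame with one row per frequency: \code{frequency_hz},
#'   \code{APD90_ms}, \code{APD50_ms}, \code{force_amplitude_mN},
#'   \code{T2_80_ms}, \code{flagged}.
#' @export
rate_dependence <- function(params, frequencies_hz,
                            protocol = pacing_protocol()) {
  stopifnot(all(frequencies_hz > 0.2), all(frequencies_hz <= 4))
  env <- environment()
  init <- NULL
  rows <- lapply(frequencies_hz, function(hz) {
    pr <- protocol
    pr$hz <- hz
    paced <- suppressWarnings(
      pace_to_steady_state(params, pr, init = env$init))
    env$init <- paced$state
    ap <- paced$features$ap
    ct <- paced$features$contraction
    flagged <- is.null(ap) || isTRUE(ap$censored) ||
      (!is.null(ap) && ap$APD90_ms >= 1000 / hz)
    data.frame(frequency_hz = hz,
               APD90_ms = if (is.null(ap)) NA_real_ else ap$APD90_ms,
               APD50_ms = if (is.null(ap)) NA_real_ else ap$APD50_ms,
               force_amplitude_mN =
                 if (is.null(ct)) NA_real_ else ct$amplitude_mN,
               T2_80_ms = if (is.null(ct)) NA_real_ else ct$T2_80_ms,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Voltage-clamp protocol specification
#'
#' @param holding_mV holding potential (mV).
#' @param test_mV test potential (mV).
#' @param duration_ms depolarizing-step duration (ms).
#' @param hz inter-pulse frequency (Hz).
#' @param buffer_ca emulate pipette Ca2+ buffering (EGTA): intracellular
#'   Ca2+ is frozen at its holding value during the protocol.
#' @return Object of class \code{clamp_protocol}.
#' @export
clamp_protocol <- function(holding_mV = -80, test_mV = 10,
                           duration_ms = 300, hz = 0.5,
                           buffer_ca = TRUE) {
  stopifnot(duration_ms > 0, hz > 0)
  structure(list(holding_mV = holding_mV, test_mV = test_mV,
                 duration_ms = duration_ms, hz = hz,
                 buffer_ca = buffer_ca),
            class = "clamp_protocol")
}

#' Voltage-clamp measurement of I_CaL
#'
#' Emulates the whole-cell L-type Ca2+ current measurement: the membrane
#' is held at the holding potential until gating equilibrates, stepped to
#' the test potential, and the current amplitude is computed as the
#' difference between peak inward current and the current at the end of
#' the depolarizing step. The nifedipine-sensitive current is emulated as
#' the trace difference between the unblocked run and a run with the
#' L-type component fully blocked.
#'
#' @param params a \code{\link{cm_parameters}} object.
#' @param protocol a \code{\link{clamp_protocol}}.
#' @param nifedipine_subtraction logical; compute the amplitude on the
#'   full-block-subtracted current instead of the direct I_CaL.
#' @return Object of class \code{cm_clamp}: list with \code{trace}
#'   (time_ms, ICaL_pA_per_pF), \code{amplitude_pA_per_pF} (positive
#'   magnitude of peak-minus-late current), \code{peak_pA_per_pF},
#'   \code{late_pA_per_pF}, \code{protocol}.
#' @export
voltage_clamp_ical <- function(params, protocol = clamp_protocol(),
                               nifedipine_subtraction = FALSE) {
  stopifnot(inherits(params, "cm_parameters"),
            inherits(protocol, "clamp_protocol"))
  run_one <- function(pp) {
    st <- unclass(cm_initial_state("control", paced = FALSE))
    st[["V"]] <- protocol$holding_mV
    # equilibrate gating at holding potential (clamped, 5 s)
    eq <- .cm_run(st, pp, times = c(0, 5000), stim_on = FALSE,
                  clamp = TRUE, buffer_ca = protocol$buffer_ca)
    s0 <- eq[nrow(eq), .cm_state_names]
    s0[["V"]] <- protocol$test_mV
    tt <- seq(0, protocol$duration_ms, by = 0.1)
    step <- .cm_run(s0, pp, times = tt, stim_on = FALSE, clamp = TRUE,
                    buffer_ca = protocol$buffer_ca)
    step
  }
  step <- run_one(params)
  ical <- step[, "I_CaL"]
  if (nifedipine_subtraction) {
    blocked <- apply_block(params, block_spec("ICaL", fraction = 1))
    step_b <- run_one(blocked)
    ical <- ical - step_b[, "I_CaL"]
  }
  peak <- min(ical)            # peak inward (most negative)
  late <- ical[length(ical)]   # current at end of the step
  amplitude <- late - peak     # positive magnitude
  structure(list(
    trace = data.frame(time_ms = step[, "time"], ICaL_pA_per_pF = ical),
    amplitude_pA_per_pF = amplitude, peak_pA_per_pF = peak,
    late_pA_per_pF = late, protocol = protocol,
    nifedipine_subtraction = nifedipine_subtraction),
    class = "cm_clamp")
}

#' @export
print.cm_clamp <- function(x, ...) {
  cat("<cm_clamp>", x$protocol$holding_mV, "->", x$protocol$test_mV,
      "mV:", sprintf("I_CaL amplitude %.3f pA/pF\n",
                     x$amplitude_pA_per_pF))
  invisible(x)
}

#' Calibrate a fractional block against an observable
#'
#' Finds, by deterministic bisection, the fractional block of a component
#' (default the L-type Ca2+ channel) that changes a steady-state
#' observable of the reference model by a given relative amount. This
#' anchors the in-silico diltiazem emulation: the fraction is calibrated
#' on the control model's force response (e.g. -11 percent), and the same
#' fraction is then applied unchanged to other presets, making their
#' responses emergent predictions.
#'
#' @param params_reference reference \code{\link{cm_parameters}}.
#' @param observable one of \code{"force_amplitude"}, \code{"APD90"},
#'   \code{"APD50"}.
#' @param target_relative_change target signed relative change (e.g.
#'   \code{-0.11} for an 11 percent reduction); must be negative.
#' @param protocol a \code{\link{pacing_protocol}}.
#' @param component blocked component (default \code{"ICaL"}).
#' @param tol_abs absolute tolerance on the achieved relative change.
#' @return A \code{\link{block_spec}} with the calibrated fraction;
#'   attributes carry the achieved change and the baseline value.
#' @export
calibrate_block <- function(params_reference,
                            observable = c("force_amplitude", "APD90",
                                           "APD50"),
                            target_relative_change,
                            protocol = pacing_protocol(),
                            component = "ICaL", tol_abs = 0.005) {
  observable <- match.arg(observable)
  stopifnot(inherits(params_reference, "cm_parameters"))
  if (!is.numeric(target_relative_change) ||
      length(target_relative_change) != 1L ||
      target_relative_change > 0)
    stop("target_relative_change must be <= 0", call. = FALSE)

  read_obs <- function(paced) {
    val <- switch(observable,
           force_amplitude = paced$features$contraction$amplitude_mN,
           APD90 = paced$features$ap$APD90_ms,
           APD50 = paced$features$ap$APD50_ms)
    # a fully suppressed observable (no detectable peak/AP) reads as 0
    if (is.null(val) || !is.finite(val)) 0 else val
  }
  base <- pace_to_steady_state(params_reference, protocol)
  base_val <- read_obs(base)
  if (is.null(base_val) || !is.finite(base_val) || base_val == 0)
    stop("baseline observable could not be measured", call. = FALSE)

  if (target_relative_change == 0)
    return(structure(block_spec(component, fraction = 0),
                     achieved = 0, baseline = base_val))

  eval_b <- function(b) {
    pb <- apply_block(params_reference, block_spec(component, fraction = b))
    paced <- pace_to_steady_state(pb, protocol, init = base$state)
    val <- read_obs(paced)
    (val - base_val) / base_val
  }

  lo <- 0; hi <- 1
  f_hi <- eval_b(hi)
  if (f_hi > target_relative_change)
    stop("target change unreachable even at full block (achieves ",
         sprintf("%.1f%%", 100 * f_hi), ")", call. = FALSE)
  f_lo <- 0
  b <- NA_real_; achieved <- NA_real_
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    f_mid <- eval_b(mid)
    if (abs(f_mid - target_relative_change) < tol_abs) {
      b <- mid; achieved <- f_mid
      break
    }
    if (f_mid > target_relative_change) { lo <- mid; f_lo <- f_mid }
    else { hi <- mid; f_hi <- f_mid }
    if (hi - lo < 1e-5) { b <- mid; achieved <- f_mid; break }
  }
  if (is.na(b)) { b <- (lo + hi) / 2; achieved <- eval_b(b) }
  structure(block_spec(component, fraction = b),
            achieved = achieved, baseline = base_val)
}
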