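# R-language mirror of the compiled cell-model right-hand side
# (src/cmmodel.c). Both implementations encode the same equations; the
# test suite asserts their agreement at randomly sampled states, and all
# reported currents come from this single R routine.

.cm_state_names <- c("V", "m", "h", "j", "d", "f", "fca", "xr", "xs",
                     "y", "g", "Nai", "Ki", "Cai", "CaSR", "TRPN", "XB",
                     "rto", "sto")

.cm_current_names <- c("I_Na", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_f",
                       "I_to", "I_NaCa", "I_NaK", "I_bNa", "I_bCa",
                       "I_pCa", "I_stim", "I_ion", "F_stress", "J_rel",
                       "J_up")

# fixed constants shared with the C implementation
.cm_const <- list(
  Frd = 96.4867, Rgas = 8.3143,
  Buf_c = 0.15, K_bufc = 0.001, Buf_sr = 10, K_bufsr = 0.3,
  gama = 0.35, Km_Nai = 87.5, Km_Ca = 1.38, k_sat = 0.1, alpha_ncx = 2.5,
  Km_K = 1, Km_Na = 20, K_pCa = 5e-4,
  F_conv = 96485.34
)

#' Default initial state of the cell model
#'
#' Returns a quiescent state vector near the model's resting equilibrium
#' for the given preset. Presets ship with stored states obtained by long
#' unpaced relaxation (resting) or by pacing to steady state at 1 Hz
#' (paced; used to warm-start pacing protocols).
#'
#' @param preset \code{"control"} or \code{"hcm_1p5x_ical"}.
#' @param paced logical; return the 1-Hz steady-state diastolic state
#'   instead of the resting state.
#' @return Named numeric state vector (class \code{cm_state}).
#' @export
cm_initial_state <- function(preset = c("control", "hcm_1p5x_ical"),
                             paced = FALSE) {
  preset <- match.arg(preset)
  states <- .cm_preset_states()
  key <- paste0(preset, if (paced) "_paced" else "_rest")
  st <- states[[key]]
  structure(st, class = "cm_state")
}

validate_cm_state <- function(state) {
  if (length(state) != length(.cm_state_names))
    stop("state must have ", length(.cm_state_names), " fields",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- .cm_state_names
  bad <- names(state)[!is.finite(state)]
  if (length(bad))
    stop("non-finite state component: ", paste(bad, collapse = ", "),
         call. = FALSE)
  gates <- c("m", "h", "j", "d", "f", "fca", "xr", "xs", "y", "g",
             "TRPN", "XB", "rto", "sto")
  tol <- 1e-6
  out_of_range <- gates[state[gates] < -tol | state[gates] > 1 + tol]
  if (length(out_of_range))
    stop("gating/state fraction outside [0,1]: ",
         paste(out_of_range, collapse = ", "), call. = FALSE)
  conc <- c("Nai", "Ki", "Cai", "CaSR")
  bad <- conc[state[conc] <= 0]
  if (length(bad))
    stop("nonpositive concentration: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(state)
}

# Full rate computation: derivatives plus per-component currents.
.cm_rates <- function(state, params, stim_active = FALSE) {
  k <- .cm_const
  s <- as.list(state)
  p <- as.list(unclass(params))

  RTF <- k$Rgas * p$temp / k$Frd
  E_Na <- RTF * log(p$Na_o / s$Nai)
  E_K  <- RTF * log(p$K_o / s$Ki)
  E_Ks <- RTF * log((p$K_o + 0.03 * p$Na_o) / (s$Ki + 0.03 * s$Nai))
  E_Ca <- 0.5 * RTF * log(p$Ca_o / s$Cai)
  V <- s$V

  I_Na <- p$g_Na * s$m^3 * s$h * s$j * (V - E_Na)
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V < -40) {
    a_h <- 0.057 * exp(-(V + 80) / 6.8)
    b_h <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    a_j <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    b_j <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    a_h <- 0
    b_h <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    a_j <- 0
    b_j <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  tau_h <- 1 / (a_h + b_h)
  tau_j <- 1 / (a_j + b_j)

  vfrt2 <- 2 * V / RTF
  ghk <- if (abs(vfrt2) < 1e-6)
    2 * k$Frd * (s$Cai - 0.341 * p$Ca_o)
  else
    2 * k$Frd * vfrt2 * (s$Cai * exp(vfrt2) - 0.341 * p$Ca_o) /
      (exp(vfrt2) - 1)
  I_CaL <- p$g_CaL * s$d * s$f * s$fca * ghk
  d_inf <- 1 / (1 + exp((-5 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 0.08 + 0.92 / (1 + exp((V + 20) / 7))
  tau_f <- 40 + 500 / (1 + exp(-(V + 15) / 8))
  fca_inf <- 0.92 + 0.08 / (1 + (s$Cai / 0.0015)^2)
  tau_fca <- 15

  xr_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr <- (100 / (1 + exp((-45 - V) / 10))) *
    (6 / (1 + exp((V + 30) / 11.5)))
  r_inf <- 1 / (1 + exp((V - 10) / 34)) / (1 + exp(-(V + 58) / 5))
  I_Kr <- p$g_Kr * sqrt(p$K_o / 5.4) * s$xr * r_inf * (V - E_K)

  xs_inf <- 1 / (1 + exp((-35 - V) / 6))
  tau_xs <- (400 / sqrt(1 + exp((-10 - V) / 6))) *
    (1 / (1 + exp((V - 60) / 20)))
  I_Ks <- p$g_Ks * s$xs^2 * (V - E_Ks)

  rto_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_rto <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  sto_inf <- 1 / (1 + exp((V + 20) / 5))
  tau_sto <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  I_to <- p$g_to * s$rto * s$sto * (V - E_K)

  a_k1 <- 0.1 / (1 + exp(0.06 * (V - E_K - 200)))
  b_k1 <- (3 * exp(2e-4 * (V - E_K + 100)) + exp(0.1 * (V - E_K - 10))) /
    (1 + exp(-0.5 * (V - E_K)))
  I_K1 <- p$g_K1 * sqrt(p$K_o / 5.4) * (a_k1 / (a_k1 + b_k1)) * (V - E_K)

  I_f <- p$g_f * s$y * (V - p$E_f)
  y_inf <- 1 / (1 + exp((V + 80.6) / 6.8))
  tau_y <- 1000

  vfrt <- V / RTF
  I_NaCa <- p$k_NaCa *
    (exp(k$gama * vfrt) * s$Nai^3 * p$Ca_o -
     exp((k$gama - 1) * vfrt) * p$Na_o^3 * s$Cai * k$alpha_ncx) /
    ((k$Km_Nai^3 + p$Na_o^3) * (k$Km_Ca + p$Ca_o) *
     (1 + k$k_sat * exp((k$gama - 1) * vfrt)))

  I_NaK <- p$P_NaK * p$K_o * s$Nai^3 /
    ((p$K_o + k$Km_K) * (s$Nai^3 + k$Km_Na^3) *
     (1 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt)))

  I_bNa <- p$g_bNa * (V - E_Na)
  I_bCa <- p$g_bCa * (V - E_Ca)
  I_pCa <- p$g_pCa * s$Cai / (s$Cai + k$K_pCa)

  I_ion <- I_Na + I_CaL + I_Kr + I_Ks + I_K1 + I_f + I_to + I_NaCa +
    I_NaK + I_bNa + I_bCa + I_pCa
  I_stim <- if (isTRUE(stim_active)) -p$stim_amp else 0

  J_up <- p$V_up / (1 + (p$K_up / s$Cai)^2)
  J_leak <- p$V_leak * (s$CaSR - s$Cai)
  J_rel <- (p$a_rel * s$CaSR^2 / (p$b_rel^2 + s$CaSR^2) + p$c_rel) *
    s$d * s$g * (s$CaSR - s$Cai)
  g_inf <- 1 / (1 + (s$Cai / 0.00035)^6)
  tau_g <- 2

  dTRPN <- p$k_on * s$Cai * (1 - s$TRPN) - p$k_off * s$TRPN
  perm <- 1 / (1 + (p$k_half / max(s$TRPN, 1e-12))^p$n_xb)
  dXB <- p$f_xb * perm * (1 - s$XB) - p$g_xb * s$XB
  F_stress <- p$F_max * s$XB

  bi <- 1 / (1 + k$Buf_c * k$K_bufc / (s$Cai + k$K_bufc)^2)
  bsr <- 1 / (1 + k$Buf_sr * k$K_bufsr / (s$CaSR + k$K_bufsr)^2)
  conv <- p$C_m / (p$V_c * k$F_conv)

  d_state <- c(
    V = if (p$clamp_mode > 0.5) 0 else -(I_ion + I_stim),
    m = (m_inf - s$m) / tau_m,
    h = (h_inf - s$h) / tau_h,
    j = (h_inf - s$j) / tau_j,
    d = (d_inf - s$d) / tau_d,
    f = (f_inf - s$f) / tau_f,
    fca = (fca_inf - s$fca) / tau_fca,
    xr = (xr_inf - s$xr) / tau_xr,
    xs = (xs_inf - s$xs) / tau_xs,
    y = (y_inf - s$y) / tau_y,
    g = (g_inf - s$g) / tau_g,
    Nai = -(I_Na + I_bNa + 3 * I_NaK + 3 * I_NaCa + 0.5 * I_f) * conv,
    Ki = 0,  # bulk intracellular K+ held fixed (see model docs)

    Cai = bi * (-(I_CaL + I_bCa + I_pCa - 2 * I_NaCa) * conv * 0.5 +
                J_leak - J_up + J_rel - p$trpn_tot * dTRPN),
    CaSR = bsr * (p$V_c / p$V_sr) * (J_up - J_rel - J_leak),
    TRPN = dTRPN,
    XB = dXB,
    rto = (rto_inf - s$rto) / tau_rto,
    sto = (sto_inf - s$sto) / tau_sto
  )
  if (p$buffer_ca > 0.5) d_state[c("Cai", "CaSR")] <- 0

  currents <- c(I_Na = I_Na, I_CaL = I_CaL, I_Kr = I_Kr, I_Ks = I_Ks,
                I_K1 = I_K1, I_f = I_f, I_to = I_to, I_NaCa = I_NaCa,
                I_NaK = I_NaK, I_bNa = I_bNa, I_bCa = I_bCa,
                I_pCa = I_pCa,
                I_stim = I_stim, I_ion = I_ion, F_stress = F_stress,
                J_rel = J_rel, J_up = J_up)
  list(derivatives = d_state, currents = currents)
}

#' Time derivative of the cell-model state
#'
#' Evaluates the model's right-hand side at a given state: the rate of
#' change of membrane potential, every gating variable, the intracellular
#' ion concentrations, and the contractile-element states.
#'
#' @param state named numeric state vector (see
#'   \code{\link{cm_initial_state}}).
#' @param params a \code{\link{cm_parameters}} object.
#' @param t time (ms); the model is autonomous, so \code{t} only matters
#'   through the \code{stim_active} flag chosen by the caller.
#' @param stim_active logical; is the stimulus current applied?
#' @return Named numeric vector of d(state)/dt (per ms).
#' @export
cm_derivatives <- function(state, params, t = 0, stim_active = FALSE) {
  stopifnot(inherits(params, "cm_parameters"))
  state <- validate_cm_state(state)
  .cm_rates(state, params, stim_active)$derivatives
}

#' Per-component membrane currents and active force at a state
#'
#' Decomposes the model right-hand side into its component current
#' densities (pA/pF), the total ionic current, the SR Ca2+ fluxes, and
#' the contractile element's active stress.
#'
#' @inheritParams cm_derivatives
#' @return Object of class \code{cm_currents}: named numeric vector with
#'   components \code{I_Na}, \code{I_CaL}, \code{I_Kr}, \code{I_Ks},
#'   \code{I_K1}, \code{I_f}, \code{I_NaCa}, \code{I_NaK}, \code{I_bNa},
#'   \code{I_bCa}, \code{I_pCa}, \code{I_stim}, total \code{I_ion},
#'   \code{F_stress} (mN/mm^2) and fluxes \code{J_rel}, \code{J_up}.
#' @export
cm_currents <- function(state, params, stim_active = FALSE) {
  stopifnot(inherits(params, "cm_parameters"))
  state <- validate_cm_state(state)
  structure(.cm_rates(state, params, stim_active)$currents,
            class = "cm_currents")
}

#' @export
print.cm_currents <- function(x, ...) {
  cat("<cm_currents> (pA/pF; force mN/mm^2; fluxes mM/ms)\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Active force of the contractile element
#'
#' Active stress is proportional to the attached cross-bridge fraction:
#' zero when no cross-bridges are attached, saturating at \code{F_max}.
#'
#' @inheritParams cm_derivatives
#' @param as_mN logical; convert stress (mN/mm^2) to tissue-level force
#'   (mN) using the configured cross-section.
#' @return Active force (mN/mm^2, or mN if \code{as_mN}).
#' @export
active_force <- function(state, params, as_mN = FALSE) {
  stopifnot(inherits(params, "cm_parameters"))
  state <- validate_cm_state(state)
  stress <- params[["F_max"]] * state[["XB"]]
  if (as_mN) stress * params[["cross_section"]] else stress
}
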