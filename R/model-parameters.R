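#' Model parameters for the electromechanical hiPSC-CM cell model
#'
#' Constructs the full parameter set of the cell model: maximum
#' conductances and fluxes of each sarcolemmal and sarcoplasmic-reticulum
#' component, cell geometry, fixed extracellular ion concentrations,
#' stimulus settings, and the rate constants of the contractile element.
#'
#' Two named presets are shipped: \code{"control"}, calibrated so that
#' steady-state 1-Hz pacing reproduces the control engineered-heart-tissue
#' action-potential phenotype (take-off potential about -76 mV, amplitude
#' about 101 mV, APD50 about 155 ms, APD90 about 242 ms), and
#' \code{"hcm_1p5x_ical"}, identical except for a 1.5-fold L-type Ca2+
#' maximum conductance, the in-silico analogue of the elevated I_CaL
#' density measured in the HCM line.
#'
#' @param preset character; \code{"control"} or \code{"hcm_1p5x_ical"}.
#' @param ... named overrides of individual parameters.
#' @return An object of class \code{cm_parameters}: a named numeric vector
#'   with the fields listed in \code{\link{cm_parameter_units}}.
#' @examples
#' p <- cm_parameters("control")
#' p_hcm <- cm_parameters("hcm_1p5x_ical")
#' p_hcm[["g_CaL"]] / p[["g_CaL"]]  # 1.5
#' @export
cm_parameters <- function(preset = c("control", "hcm_1p5x_ical"), ...) {
  preset <- match.arg(preset)
  p <- .cm_base_parameters()
  if (preset == "hcm_1p5x_ical")
    p[["g_CaL"]] <- 1.5 * p[["g_CaL"]]
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  validate_cm_parameters(p)
  structure(p, class = "cm_parameters", preset = preset)
}

# Baseline ("control") parameter values. Conductances in nS/pF against the
# listed driving forces (the L-type term multiplies a GHK flux and has
# composite units, cm^3 uF^-1 ms^-1 scaled); fluxes in mM/ms; see the
# methods vignette for the full unit table.
.cm_base_parameters <- function() {
  c(
    g_Na      = 18,        # fast Na+ conductance (nS/pF)
    g_CaL     = 0.075,     # L-type Ca2+ permeability factor
    g_Kr      = 0.0925,    # rapid delayed rectifier (nS/pF)
    g_Ks      = 0.005,     # slow delayed rectifier (nS/pF)
    g_K1      = 1.90,      # inward rectifier (nS/pF)
    g_f       = 0.025,     # funny current (nS/pF)
    g_to      = 0.8,       # transient outward K+ (nS/pF)
    k_NaCa    = 1000,      # Na/Ca exchanger scale (pA/pF)
    P_NaK     = 5,         # Na/K pump max (pA/pF)
    g_bNa     = 1e-3,      # Na+ background (nS/pF)
    g_bCa     = 5.92e-4,   # Ca2+ background (nS/pF)
    g_pCa     = 0.10,      # sarcolemmal Ca2+ pump (pA/pF)
    V_up      = 8e-4,      # SERCA max uptake (mM/ms)
    K_up      = 2.5e-4,    # SERCA half-activation (mM)
    V_leak    = 2e-5,      # SR leak rate (1/ms)
    a_rel     = 0.08,      # CICR release rate, SR-load-gained (1/ms)
    b_rel     = 2.0,       # release-gain half-saturation SR [Ca2+] (mM)
    c_rel     = 0.002,     # load-independent release rate (1/ms)
    Na_o      = 140,       # extracellular Na+ (mM)
    K_o       = 5.4,       # extracellular K+ (mM)
    Ca_o      = 1.8,       # extracellular Ca2+ (mM)
    temp      = 310.15,    # temperature (K), 37 C
    C_m       = 0.185,     # membrane capacitance scale
    V_c       = 0.016404,  # cytosolic volume scale
    V_sr      = 0.001094,  # SR volume scale
    stim_amp  = 12,        # stimulus amplitude (pA/pF), 1.5x threshold
    stim_dur  = 4,         # stimulus duration (ms), EHT pacing pulse
    k_on      = 40,        # troponin Ca2+ on-rate (1/(mM ms))
    k_off     = 0.04,      # troponin Ca2+ off-rate (1/ms)
    trpn_tot  = 0.07,      # troponin concentration (mM)
    n_xb      = 4,         # cross-bridge activation cooperativity
    k_half    = 0.375,     # troponin occupancy at half activation
    f_xb      = 0.012,     # cross-bridge attachment rate (1/ms)
    g_xb      = 0.015,     # cross-bridge detachment rate (1/ms)
    F_max     = 6,         # stress at full attachment (mN/mm^2)
    cross_section = 0.15,  # EHT cross-section (mm^2) for mN conversion
    E_f       = -17,       # funny-current reversal (mV)
    stim_on   = 0,         # stimulus flag (protocol-controlled)
    clamp_mode = 0,        # voltage-clamp flag (protocol-controlled)
    buffer_ca = 0          # pipette Ca2+ buffering flag
  )
}

#' Units of each model parameter
#'
#' @return Named character vector mapping parameter names to units.
#' @export
cm_parameter_units <- function() {
  c(g_Na = "nS/pF", g_CaL = "cm^3 uF^-1 ms^-1 (GHK scale)", g_Kr = "nS/pF",
    g_Ks = "nS/pF", g_K1 = "nS/pF", g_f = "nS/pF", g_to = "nS/pF",
    k_NaCa = "pA/pF",
    P_NaK = "pA/pF", g_bNa = "nS/pF", g_bCa = "nS/pF", g_pCa = "pA/pF",
    V_up = "mM/ms", K_up = "mM", V_leak = "1/ms", a_rel = "mM/ms",
    b_rel = "mM", c_rel = "mM/ms", Na_o = "mM", K_o = "mM", Ca_o = "mM",
    temp = "K", C_m = "uF (scale)", V_c = "volume scale",
    V_sr = "volume scale", stim_amp = "pA/pF", stim_dur = "ms",
    k_on = "1/(mM ms)", k_off = "1/ms", trpn_tot = "mM",
    n_xb = "dimensionless", k_half = "dimensionless", f_xb = "1/ms",
    g_xb = "1/ms", F_max = "mN/mm^2", cross_section = "mm^2",
    E_f = "mV", stim_on = "flag", clamp_mode = "flag", buffer_ca = "flag")
}

validate_cm_parameters <- function(p) {
  stopifnot(is.numeric(p))
  need <- names(.cm_base_parameters())
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  nonneg <- c("g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_f", "g_to",
              "k_NaCa",
              "P_NaK", "g_bNa", "g_bCa", "g_pCa", "V_up", "V_leak",
              "a_rel", "c_rel", "C_m", "F_max")
  bad <- nonneg[p[nonneg] < 0]
  if (length(bad))
    stop("negative conductance/flux: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pos <- c("Na_o", "K_o", "Ca_o", "temp", "stim_dur", "K_up", "b_rel",
           "V_c", "V_sr", "cross_section")
  bad <- pos[p[pos] <= 0]
  if (length(bad))
    stop("parameter must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.cm_parameters <- function(x, ...) {
  cat("<cm_parameters> electromechanical hiPSC-CM cell model\n")
  preset <- attr(x, "preset")
  if (!is.null(preset)) cat("  preset:", preset, "\n")
  cat("  g_CaL:", format(x[["g_CaL"]], digits = 6),
      " g_Kr:", format(x[["g_Kr"]], digits = 4),
      " g_K1:", format(x[["g_K1"]], digits = 4), "\n")
  cat("  stimulus:", x[["stim_amp"]], "pA/pF for", x[["stim_dur"]], "ms\n")
  cat("  (", length(unclass(x)), "parameters; see cm_parameter_units() )\n")
  invisible(x)
}

# Names of scalable maximum conductances/fluxes, keyed by component.
.cm_components <- function() {
  c(INa = "g_Na", ICaL = "g_CaL", IKr = "g_Kr", IKs = "g_Ks",
    IK1 = "g_K1", If = "g_f", Ito = "g_to", INaCa = "k_NaCa",
    INaK = "P_NaK",
    IbNa = "g_bNa", IbCa = "g_bCa", IpCa = "g_pCa",
    SERCA = "V_up", RyR = "a_rel", leak = "V_leak")
}

.resolve_component <- function(component) {
  comp <- .cm_components()
  if (component %in% names(comp)) return(comp[[component]])
  if (component %in% comp) return(component)
  stop("unknown model component: ", component,
       " (use one of: ", paste(names(comp), collapse = ", "), ")",
       call. = FALSE)
}

#' Scale one maximum conductance or flux
#'
#' Returns a copy of the parameter set in which only the named component's
#' maximum conductance/flux is multiplied by \code{factor}. Scaling
#' \code{"ICaL"} by 1.5 converts the control preset into the HCM in-silico
#' analogue (1.5-fold L-type Ca2+ current density).
#'
#' @param params a \code{\link{cm_parameters}} object.
#' @param component component identifier (e.g. \code{"ICaL"}, \code{"IKr"})
#'   or the underlying parameter name (e.g. \code{"g_CaL"}).
#' @param factor positive multiplier.
#' @return A new \code{cm_parameters} object; the input is not modified.
#' @examples
#' p <- cm_parameters("control")
#' ph <- scale_conductance(p, "ICaL", 1.5)
#' @export
scale_conductance <- function(params, component, factor) {
  stopifnot(inherits(params, "cm_parameters"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a single positive number", call. = FALSE)
  field <- .resolve_component(component)
  out <- params
  out[[field]] <- params[[field]] * factor
  attr(out, "preset") <- NULL
  out
}

#' Specify a fractional channel block
#'
#' A block is either given directly as a fraction \code{b} in [0, 1] of the
#' target component's maximum conductance, or in concentration mode via a
#' Hill relation \code{b = conc^h / (conc^h + ic50^h)}. The package's
#' canonical diltiazem emulation is a pure fractional L-type block whose
#' fraction is calibrated on an observable (see
#' \code{\link{calibrate_block}}), not converted from concentration.
#'
#' @param component target component identifier (e.g. \code{"ICaL"}).
#' @param fraction fractional block in [0, 1].
#' @param conc,ic50,hill concentration-mode fields (same units for
#'   \code{conc} and \code{ic50}); used only when \code{fraction} is NULL.
#' @return An object of class \code{block_spec}.
#' @examples
#' block_spec("ICaL", fraction = 0.3)
#' block_spec("ICaL", conc = 3, ic50 = 10, hill = 1)
#' @export
block_spec <- function(component, fraction = NULL, conc = NULL,
                       ic50 = NULL, hill = 1) {
  field <- .resolve_component(component)
  if (is.null(fraction)) {
    if (is.null(conc) || is.null(ic50))
      stop("give either `fraction` or both `conc` and `ic50`",
           call. = FALSE)
    if (ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
    if (conc < 0) stop("conc must be >= 0", call. = FALSE)
    fraction <- conc^hill / (conc^hill + ic50^hill)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("block fraction must lie in [0, 1]", call. = FALSE)
  structure(list(component = component, field = field,
                 fraction = fraction, conc = conc, ic50 = ic50,
                 hill = hill),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat("<block_spec>", x$component, "block, fraction",
      format(x$fraction, digits = 4), "\n")
  if (!is.null(x$conc))
    cat("  concentration mode: conc", x$conc, "IC50", x$ic50,
        "Hill", x$hill, "\n")
  invisible(x)
}

#' Apply a fractional block to the model parameters
#'
#' The target component's maximum conductance becomes
#' \code{g * (1 - fraction)}; the input parameter set is untouched.
#'
#' @param params a \code{\link{cm_parameters}} object.
#' @param block a \code{\link{block_spec}}.
#' @return A new \code{cm_parameters} object.
#' @export
apply_block <- function(params, block) {
  stopifnot(inherits(params, "cm_parameters"),
            inherits(block, "block_spec"))
  out <- params
  out[[block$field]] <- params[[block$field]] * (1 - block$fraction)
  attr(out, "preset") <- NULL
  out
}
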