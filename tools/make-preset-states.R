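# Regenerates R/preset-states.R: the stored resting and 1-Hz paced
# steady states of the shipped model presets. Run from the repository
# root after any change to the model equations or baseline parameters:
#   Rscript tools/make-preset-states.R
suppressMessages(pkgload::load_all("."))

gate_init <- function(V = -76, Cai = 1e-4) {
  st <- stats::setNames(numeric(19), ehtkit:::.cm_state_names)
  st["V"] <- V
  st["m"] <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  st["h"] <- st["j"] <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  st["d"] <- 1 / (1 + exp((-5 - V) / 7.5))
  st["f"] <- 0.08 + 0.92 / (1 + exp((V + 20) / 7))
  st["fca"] <- 0.92 + 0.08 / (1 + (Cai / 0.0015)^2)
  st["xr"] <- 1 / (1 + exp((-26 - V) / 7))
  st["xs"] <- 1 / (1 + exp((-35 - V) / 6))
  st["y"] <- 1 / (1 + exp((V + 80.6) / 6.8))
  st["g"] <- 1
  st["Nai"] <- 12; st["Ki"] <- 135; st["Cai"] <- Cai; st["CaSR"] <- 1
  st["TRPN"] <- 40 * Cai / (40 * Cai + 0.04)
  st["rto"] <- 1 / (1 + exp((20 - V) / 6))
  st["sto"] <- 1 / (1 + exp((V + 20) / 5))
  st["XB"] <- 0.01
  st
}

fmt <- function(v) paste(sprintf("%.10g", v), collapse = ", ")
out <- c()
for (preset in c("control", "hcm_1p5x_ical")) {
  p <- cm_parameters(preset)
  st <- gate_init()
  m <- ehtkit:::.cm_run(st, p, seq(0, 120000, by = 1000), stim_on = FALSE)
  rest <- m[nrow(m), ehtkit:::.cm_state_names]
  pc <- suppressWarnings(pace_to_steady_state(
    p, pacing_protocol(hz = 1, beats = 300, tol = 1e-3), init = rest))
  paced <- unclass(pc$state)
  cat(preset, "beats:", pc$convergence$beats_run,
      "APD90:", pc$features$ap$APD90_ms, "\n")
  out <- c(out,
           sprintf("    %s_rest = mk(c(\n      %s)),", preset, fmt(rest)),
           sprintf("    %s_paced = mk(c(\n      %s)),", preset,
                   fmt(paced)))
}
out[length(out)] <- sub("\\)\\),$", "))", out[length(out)])
writeLines(c(
  "# Stored preset states. \"rest\" states are the unpaced resting equilibrium",
  "# (120 s relaxation); \"paced\" states are end-diastolic states after 1-Hz",
  "# steady-state pacing. Regenerate with tools/make-preset-states.R after any",
  "# change to the model equations or baseline parameters.",
  "",
  ".cm_preset_states <- function() {",
  "  nm <- .cm_state_names",
  "  mk <- function(v) stats::setNames(v, nm)",
  "  list(", out, "  )", "}"), "R/preset-states.R")
cat("written R/preset-states.R\n")
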