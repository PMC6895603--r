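# Stored preset states. "rest" states are the unpaced resting equilibrium
# (120 s relaxation); "paced" states are end-diastolic states after 1-Hz
# steady-state pacing. Regenerate with tools/make-preset-states.R after any
# change to the model equations or baseline parameters.

.cm_preset_states <- function() {
  nm <- .cm_state_names
  mk <- function(v) stats::setNames(v, nm)
  list(
    control_rest = mk(c(
      -73.80592449, 0.01762973137, 0.3310083353, 0.3310530467, 0.0001036773144, 0.9995779677, 0.9999450416, 0.001080296119, 0.001550454204, 0.2692539509, 0.999997987, 8.875962984, 135, 3.932848396e-05, 0.9075492443, 0.03784099837, 8.295171744e-05, 1.622178642e-07, 0.9999787939)),
    control_paced = mk(c(
      -77.03733703, 0.009350252223, 0.4595199628, 0.4599228028, 6.738135274e-05, 0.9997367035, 0.9997760817, 0.0006772309789, 0.0009050200415, 0.3164542995, 0.9998630133, 12.23362337, 135, 7.946771995e-05, 3.397808401, 0.07362125049, 0.00119767288, 9.452666482e-08, 0.9999889318)),
    hcm_1p5x_ical_rest = mk(c(
      -73.76846533, 0.01775699565, 0.3295919796, 0.3296369132, 0.0001041963771, 0.9995757044, 0.9999435941, 0.001086086091, 0.001560148971, 0.2681717743, 0.9999978236, 8.883988342, 135, 3.984342418e-05, 0.9273377846, 0.0383174472, 8.720744226e-05, 1.632337791e-07, 0.9999786344)),
    hcm_1p5x_ical_paced = mk(c(
      -79.99976027, 0.005124883543, 0.5752602034, 0.5829810425, 4.539144745e-05, 0.9998290102, 0.999680875, 0.0004426743012, 0.0005524596487, 0.3617174243, 0.9996020159, 14.74224303, 135, 9.493209671e-05, 4.76142098, 0.08670102845, 0.002350988358, 5.763586483e-08, 0.9999938941))
  )
}
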