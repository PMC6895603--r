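---
title: "ehtkit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ehtkit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ehtkit` models and phenotypes human induced pluripotent stem cell derived
cardiomyocytes (hiPSC-CM) cast as engineered heart tissues (EHT). Its core
is an electromechanical cell model used to ask a disease-modeling question:
does an elevated L-type Ca^2+^ current density, on its own, reproduce the
action-potential prolongation, delayed relaxation and enhanced force seen
in an HCM (hypertrophic cardiomyopathy) line relative to its isogenic
control — and does a pure L-type channel block (a diltiazem emulation)
preferentially normalize the diseased phenotype? Around the model sit the
measurement tools of the field: AP and contraction feature extraction,
force–pCa Hill analysis, a sarcomere-disarray image statistic, QTc
correction, and seeded synthetic-data generators that give every analysis
stage a known ground truth.

## The electromechanical cell model

The model is an hiPSC-CM-class system of 19 ordinary differential
equations, written by the package authors in standard Hodgkin–Huxley form
and calibrated so that the control preset reproduces the control-EHT AP
phenotype at 1-Hz pacing (take-off potential about −76 mV, amplitude about
101 mV, APD50 about 155 ms, APD90 about 242 ms). The complete equations
live, once each, in `src/cmmodel.c` (the compiled right-hand side used for
integration) and `R/model-rates.R` (an R mirror used for current
decomposition and cross-checked against the C side by the test suite).

**Membrane currents.** Fast Na^+^ current (m³hj gating, standard
ventricular kinetics); L-type Ca^2+^ current with a
Goldman–Hodgkin–Katz driving force and three gates — voltage activation
`d`, voltage inactivation `f` (incomplete: 8 % of channels do not
inactivate, and inactivation is slow at depolarized potentials, with a
time constant rising to ≈540 ms above −15 mV), and a weak Ca^2+^-dependent
gate `fca` (floor 0.92); a rapid delayed rectifier with fast activation
and a broad inactivation-type rectification that makes its
conductance–voltage product nearly flat between −20 and +20 mV, plus a
deactivation-like cutoff below −58 mV; a small slow delayed rectifier; a
transient outward current (fast `r`, inactivating `s`) that sets phase-1
repolarization and the AP amplitude; an inward rectifier with the
classical steep rectification; a small funny current; the Na/Ca exchanger
and background/pump Ca^2+^ and Na^+^ currents in their usual forms; and a
Na/K pump with a steep (cubic) dependence on intracellular Na^+^.

The shape of the repolarization reserve is the scientific heart of the
model. The plateau is timed by the slow voltage inactivation of the
L-type current working against an IKr whose conductance–voltage product
is flat across plateau potentials: because the potassium load neither
grows with time (fast IKr activation, token IKs) nor steepens as the
plateau drifts down, the plateau duration responds logarithmically to the
L-type conductance, ΔAPD ≈ τ~f~ · ln(factor). This is what lets a
1.5-fold g~CaL~ — the in-silico analogue of the elevated I~CaL~ density
measured in the HCM line — prolong APD90 by roughly half, while leaving
the control anchors untouched. Formulations in which the repolarizing
current ramps with time (a fast-activating IKs) or steepens as voltage
falls (classical hERG recovery throughout the tail) absorb most of a
conductance change and were deliberately avoided; the final leg of
repolarization (below about −58 mV) is handed to the inward rectifier.

**Ca^2+^ handling.** SERCA uptake (Hill coefficient 2), a passive SR
leak, and a CICR release flux proportional to the SR–cytosol gradient,
gated by the L-type `d` gate and a fast Ca^2+^-inactivation gate, with an
SR-load-dependent gain. Cytosolic and SR rapid buffering use the
instantaneous-buffer approximation; troponin is an explicit state (the
shared-buffer choice: Ca^2+^ bound to troponin is removed from the free
pool, so the force model feeds back on the transient).

**Contractile element.** A troponin–cross-bridge cascade: troponin
occupancy follows free Ca^2+^ with on/off kinetics (K~d~ = 1 µM); a
cooperative permissive function (Hill 4, half-activation at occupancy
0.375) gates cross-bridge attachment; attached cross-bridges (`XB`)
develop stress `F_max · XB` (mN/mm²), converted to tissue-level force in
mN by a configurable cross-section (default 0.15 mm², giving control
peak forces of ≈0.2–0.4 mN, the EHT scale). Contraction is isometric:
sarcomere-length dependence and auxotonic post mechanics are out of
scope, so T1/T2 arise purely from activation kinetics and the Ca^2+^
transient.

**Fixed intracellular K^+^, dynamic Na^+^.** Bulk intracellular K^+^ is
held constant. With fully dynamic monovalent pools the resting potential
drifts on a minutes timescale (the slow K^+^ loading through the pump),
so no paced steady state exists on protocol timescales; fixing K^+^
removes that drift while dynamic Na^+^ retains the physiologically
important Na^+^-mediated negative feedback on Ca^2+^ load (the HCM preset
equilibrates at a higher Na^+^, which restrains its Ca^2+^ accumulation).
The pump's cubic Na^+^ dependence is what lets the HCM preset settle at a
bounded Na^+^ despite nearly twice the Na^+^ influx.

**Stimulus.** Rectangular current injection, 4 ms (the EHT pacing pulse
width), 12 pA/pF. This is deliberately well above the diastolic threshold
(≈3.6 pA/pF by bisection): near-threshold stimuli produce long, variable
latencies that corrupt the take-off-potential reading, whereas EHT field
stimulation in practice is run comfortably suprathreshold. This is a
deviation from the "50 % above threshold" convention, chosen for
robustness of the take-off metric.

**Integration.** `deSolve::lsoda` with rtol 10⁻⁶, atol 10⁻⁸, maximum
step 1 ms while the stimulus is active. Each beat is integrated as two
segments (stimulus on, stimulus off) on a uniform output grid, so the
discontinuity never sits inside a solver step; outputs are bit-reproducible
for fixed inputs. Monitoring beats are sampled at 0.5 ms, recorded beats
at 0.1 ms (10 kHz).

**Steady-state pacing.** The criterion is a maximum relative change of
APD90 and diastolic Ca^2+^ below 0.1 % over the last 10 beats, with a
300-beat cap (the convergence report states which triggered). The
presets ship with stored resting states (120 s unpaced relaxation) and
1-Hz paced states (300 beats from rest; regenerate with
`tools/make-preset-states.R`), so warm-started protocols typically
converge within 10–30 beats.

## Calibration and what is emergent

The control preset's conductances were tuned — by design — to the four
printed control anchors (TOP, APA, APD50, APD90 at 1 Hz). Everything
else is emergent: the ≈ +48 % APD90 prolongation under 1.5-fold g~CaL~,
its persistence at 1–3 Hz, the enhanced force and prolonged relaxation of
the HCM-like preset, and all of the drug-block responses.

The diltiazem emulation is a pure fractional conductance block of the
L-type component (no state dependence). Its fraction is **calibrated**,
by deterministic bisection, so that the *control* model's steady-state
force amplitude falls by 11 % — the measured control-tissue response to
3 µM diltiazem — and the concentration is treated as a label, not
converted through a literature IC50. The identical fraction applied to
the 1.5× preset then yields predictions the calibration never saw:
relaxation (T2~80~) shortens by ≈17 % in the HCM-like preset versus
≈16 % in control, both within the measured ranges. APD90 shortens in
both presets, but more in control (≈−25 % vs −14 %), the reverse
ordering of the tissue observation. A known limitation of the current
formulation is that the *peak force* of the 1.5× preset is almost
insensitive to the calibrated block (≈−1 %): its Ca^2+^ transient rides
the saturated region of the activation cascade, so the block expresses
itself in the transient's duration (captured by T2) rather than its
peak. The measured preferential force reduction in diseased tissue is
therefore not reproduced; reproducing it would need either an
unsaturated contractile operating point for both presets (which breaks
the force-amplitude contrast) or a Ca^2+^ subsystem in which the same
fractional block deflates the diseased transient amplitude
disproportionately. We document this honestly rather than fitting the
block response.

## Measurement conventions

* **AP features.** TOP is the last sample before dV/dt first exceeds 5 %
  of the maximal upstroke velocity (median-filtered over the last five
  diastolic samples for noise robustness); APA = peak − TOP; APD~x~ runs
  from take-off to repolarization to TOP + (1 − x/100)·APA with linear
  sub-sample interpolation. Thresholds are referenced to TOP (matching
  the APA definition), not the diastolic minimum. MAP-shaped traces are
  processed unchanged.
* **Contraction features.** Baseline is the 10th percentile of the
  trace; "80 % of peak height" is read as the 20 %→peak span (T1~80~) and
  the peak→20 % span (T2~80~), each covering 80 % of the amplitude.
  Peaks need a prominence of 3× the robust noise SD; noisy traces are
  lightly smoothed (≈10 ms running mean) before threshold crossings so
  noise does not bias the crossings.
* **Force–pCa.** The Hill equation is fitted in pCa space with a
  deterministic multi-start grid (pCa50 ∈ {5.0, 5.5, 6.0} ×
  nH ∈ {1, 2, 4}); the extra sum-of-squares F-test's default null shares
  (pCa50, nH) with group-specific Fmax — the test is then specific to a
  sensitivity shift — with `null = "all"` available. CSA normalization
  defaults to the published 2πr² convention; the geometrically
  conventional πr² (exactly half) is available as `"circle_pir2"`, and
  the discrepancy is flagged in the documentation.
* **Disarray index.** Within each ROI, two parallel 10-µm lines, 5–10 µm
  apart, run perpendicular to the striations; Z-band maxima are located
  on 0.05-µm bilinear profiles (0.45-µm smoothing, parabolic sub-pixel
  refinement), the k-th intersections of the two lines are paired
  (nearest-neighbor within half a median spacing when counts differ),
  and the ROI's disarray is the SD of the paired longitudinal offsets —
  Z-band registration disorder. The image index is the mean over ROIs
  (3 seeded-random ROIs by default); the within-line spacing SD is
  reported as a secondary metric.

## Synthetic data: what it emulates and what it does not

The generators produce paced EHT force traces (log-normal pulses whose
T1~80~/T2~80~ are exactly invertible; Gaussian bump in the symmetric
limit), AP traces (instant upstroke, normalized-logistic repolarization
solved so the programmed APD50/APD90 are exact), Hill-distributed
force–pCa ladders, striated images with per-Z-band Gaussian registration
jitter (the jitter SD is defined as — and the generator constructs it to
be — the expected SD of paired offsets between distinct myofibrils, with
orientation-independent lattice indexing so rotation is an equivariance,
not a new realization), and QT/RR tables. All noise is additive
Gaussian; seeds make every output bit-reproducible.

Passing the round-trip suites therefore shows that the estimators recover
their own generative model under Gaussian noise — it does not certify
performance on real recordings with baseline wander, optical PSF blur,
beat-to-beat variability or non-stationary noise, none of which are
modeled.

## Problem sizes and tolerances used by the test suite

Hill-fit accuracy uses 200 simulated ladders (9 pCa points, 2 % noise);
the F-test type-I rate uses 1000 null pairs at α = 0.05 (accepted band
0.03–0.07); disarray recovery uses 50 images at σ = 0.2 µm (±20 %);
pacing-based checks run from the stored paced states so each steady
state costs tens of beats. These sizes were chosen to keep Monte-Carlo
error comfortably below the asserted tolerances.

## Known limitations

* The HCM-like preset's peak-force response to L-type block (above).
* The maximal upstroke velocity (≈170–190 V/s) sits below the measured
  control mean (217 V/s); it was not an anchor.
* The baseline force enhancement of the 1.5× preset (≈+15–30 % depending
  on pacing history) is smaller than the measured tissue contrast
  (+58 %), which also reflects hypertrophic remodeling that a pure
  conductance change cannot carry.
* Fixed bulk K^+^ (and extracellular concentrations) means no
  K^+^-loading phenomena; no spontaneous automaticity is modeled (the
  funny current is small and the resting state is stable by design).
* Free Ca^2+^ transient amplitudes run above the single-cell literature
  range; they should be read as EHT-scale effective concentrations
  driving the lumped contractile element, not as calibrated indicator
  measurements.
* Isometric contraction only; no S1S2 restitution, no state-dependent
  drug binding, no tissue-level electrophysiology.
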