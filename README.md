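# ehtkit

Electromechanical modeling and phenotyping of hiPSC-cardiomyocyte
engineered heart tissues (EHT).

Hypertrophic cardiomyopathy (HCM) lines derived from patient hiPSC show,
relative to isogenic controls, prolonged action potentials, higher
L-type Ca²⁺ current density, stronger contraction with delayed
relaxation, higher myofilament Ca²⁺ sensitivity, and myofibrillar
disarray. `ehtkit` is for researchers who want to test the
electrophysiological arm of that phenotype in silico: whether a single
perturbation — a 1.5-fold L-type Ca²⁺ conductance,
g<sub>CaL</sub> → 1.5·g<sub>CaL</sub> — reproduces the AP prolongation,
delayed relaxation and enhanced force, and how a pure fractional L-type
block b (the diltiazem emulation, g → g·(1−b)) redistributes between the
control and diseased presets.

At its core is an hiPSC-CM-class electromechanical model:

* membrane: I<sub>Na</sub>, I<sub>CaL</sub> (GHK driving force, slow and
  incomplete voltage inactivation, weak Ca²⁺-dependent inactivation),
  I<sub>to</sub>, I<sub>Kr</sub> (flat conductance–voltage product across
  the plateau), token I<sub>Ks</sub>, I<sub>K1</sub>, I<sub>f</sub>,
  NCX, NaK (cubic Na⁺ dependence), backgrounds;
* Ca²⁺ handling: SERCA, SR leak, gradient-driven CICR release with
  load-dependent gain;
* contraction: troponin → cooperative thin-filament activation (Hill 4)
  → two-state cross-bridge pool; stress = F<sub>max</sub>·XB, scaled to
  mN by the EHT cross-section.

The plateau is clocked by I<sub>CaL</sub> inactivation against a flat
I<sub>Kr</sub> load, so APD responds logarithmically to g<sub>CaL</sub>
(ΔAPD ≈ τ<sub>f</sub>·ln factor) — the design feature that makes the
1.5× experiment work. Every equation lives in `src/cmmodel.c` with an
R mirror in `R/model-rates.R`; the two are cross-checked by the tests.

Around the model: AP features (TOP, APA, Vmax, APD50/90), EHT
contraction features (amplitude, T1₈₀, T2₈₀ at 80 % of peak height),
QTc (Bazett/Fridericia), force–pCa Hill fits with extra sum-of-squares
F-tests, a sarcomere disarray index (SD of paired Z-band offsets across
two parallel ROI lines), and seeded synthetic-data generators with
analytic ground truth for all of the above.

## Worked example

```r
library(ehtkit)

ctrl <- pace_to_steady_state(cm_parameters("control"))
ctrl
#> <cm_paced> 1 Hz, 10 beats, converged
#>   AP: TOP -77.0 mV, APA 101.0 mV, APD50 154.8 ms, APD90 238.1 ms
#>   Force: amplitude 0.3606 mN, T1_80 123 ms, T2_80 215 ms

hcm <- pace_to_steady_state(cm_parameters("hcm_1p5x_ical"))
percent_change(ctrl$features$ap$APD90_ms, hcm$features$ap$APD90_ms)
#> [1] 48.49
```

The control preset reproduces the control-EHT action potential measured
at 1-Hz pacing (take-off potential −76 mV, amplitude 101 mV, APD50
155 ms, APD90 242 ms, each within a few percent), and scaling only the
L-type conductance by 1.5 prolongs APD90 by ≈48 % — the AP arm of the
HCM phenotype from a single current-density change.

The diltiazem emulation calibrates a block fraction on the control
force response and applies it, unchanged, to the diseased preset:

```r
res <- diltiazem_protocol(target_force_change = -0.11)
res$table[, c("preset", "force_change_pct", "T2_change_pct")]
#>          preset force_change_pct T2_change_pct
#> 1       control          -11.27        -15.54
#> 2 hcm_1p5x_ical           -0.95        -16.61
```

Relaxation (T2₈₀) shortens in both presets under the same block — the
calibration used force amplitude only, so the T2 responses are emergent
predictions. See the methods vignette
(`vignettes/ehtkit-methods.Rmd`) for the model equations' rationale,
measurement conventions, and known limitations (including the diseased
preset's saturated peak-force response to block).

Other entry points: `rate_dependence()` (APD/force vs pacing rate),
`voltage_clamp_ical()` (whole-cell I<sub>CaL</sub> with pipette-buffer
emulation and nifedipine-style subtraction), `hill_fit()` /
`compare_curves_f_test()` (force–pCa), `disarray_index()` (striation
images), `gen_*()` (synthetic data), and `run_experiment()` for
configuration-driven runs with CSV/JSON artifacts.

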