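Package: ehtkit
Title: Electromechanical Modeling and Phenotyping of hiPSC-Cardiomyocyte
    Engineered Heart Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and phenotypes human induced pluripotent stem
    cell derived cardiomyocytes (hiPSC-CM) and engineered heart tissues
    (EHT). Provides an electromechanical cell model (ionic membrane
    currents, intracellular calcium handling, and a cross-bridge
    contractile element) with conductance scaling and fractional channel
    block; in-silico pacing, rate-dependence, voltage-clamp and drug-block
    calibration protocols; action-potential and contraction feature
    extraction (take-off potential, amplitude, upstroke velocity, APD50/90,
    T1/T2 at 80 percent of peak height) and QTc correction; force-pCa Hill
    fitting with nested-model F-tests; a sarcomere striation disarray
    index from alpha-actinin images; and seeded synthetic-data generators
    with analytic ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
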