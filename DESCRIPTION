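Package: forcedosc
Title: Forced-Oscillation Viscoelasticity of Arterial Strip Preparations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of arterial wall viscoelasticity from swept-sine
    forced-oscillation experiments on suspended strip preparations. Implements
    the Kelvin-Voigt resonance analysis (natural frequency, 3 dB bandwidth,
    octave length, half-power damping ratio, softening/hardening skew), the
    dynamic elastic modulus computed from the resonance frequency and strip
    geometry, the mapping from suspended mass to equivalent intraluminal blood
    pressure, and the regression-comparison statistics (ANCOVA slope/elevation
    tests for linear frequency-pressure relations, extra-sum-of-squares F tests
    for exponential modulus-pressure curves) used to contrast treatment stages
    and animal groups. A physics-based generator of complete synthetic studies
    (chirp-driven Duffing/Kelvin-Voigt element, staged treatment protocol,
    ground-truth bookkeeping) supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
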