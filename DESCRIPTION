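Package: quadcal
Title: Calorimetric Analysis of G-Quadruplex Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic analysis of DNA G-quadruplex unfolding from
    calorimetric and spectroscopic traces. Deconvolves differential scanning
    calorimetry (DSC) thermograms into sums of independent two-state van't
    Hoff transitions ("non-2-state" fits) after cubic baseline correction;
    counts the water molecules taken up on unfolding from osmotic-stress
    (glycerol) melting series; converts pressure-perturbation calorimetry
    (PPC) pulse heats into solute thermal expansion coefficients and
    integrates the transition peak to the unfolding volume change; and
    classifies quadruplex folding topology (parallel, antiparallel, hybrid)
    from circular dichroism band structure. Includes seeded synthetic-trace
    generators with known ground truth for every modality, so the full
    analysis chain can be validated by parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    signal,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
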