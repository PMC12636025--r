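Package: fepland
Title: Free-Energy Profiles, Landscapes and Kinetics for QM/MM Enzyme
    Mechanism Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for QM/MM mechanistic studies of enzyme
    catalysis, built around serine-hydrolase (Ser-Ser-Lys urethanase)
    workflows. Computes mass-weighted path coordinates along intrinsic
    reaction coordinate (IRC) structure sequences, free-energy profiles by
    free energy perturbation (Zwanzig exponential averaging) with
    delta-method and block-average error propagation, harmonic normal-mode
    thermochemistry (zero-point and vibrational free-energy corrections),
    multi-step free-energy landscape assembly with effective
    (rate-determining) barrier determination, Eyring transition-state-theory
    interconversion of rate constants and activation free energies,
    progress-curve kinetics (turnover frequency, total turnover number,
    inactivation plateau), titration-curve fitting of constant-pH simulation
    output, and descriptive trajectory analysis (distances, dihedrals,
    Kabsch-superposed RMSD, water occupancy, unbinding detection). A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
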