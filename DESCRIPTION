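Package: eadwave
Title: Early Afterdepolarizations and Emergent Wave Patterns in Human
    Ventricular Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale simulation and analysis of early afterdepolarization
    (EAD) driven arrhythmias in a modified ten Tusscher-Panfilov 2006 human
    ventricular cell model. Provides the single-cell ionic model with
    EAD-promoting conductance scalings, two-parameter phase diagrams of
    action-potential morphology (normal, EAD, oscillatory), a 2D isotropic
    monodomain tissue solver with plane-wave and S1-S2 initiation protocols
    and non-conducting barrier grids, and an analysis layer that classifies
    emergent patterns (two spiral-fibrillation types and an oscillatory
    phase-wave regime), attributes wavefronts to sodium or L-type calcium
    currents, and computes pseudo-ECGs, averaged temporal power spectra and
    interbeat-interval statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
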