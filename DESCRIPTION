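Package: urmc
Title: Unified Respiratory Motion Correction for TOF PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, end-to-end implementation of unified data-driven
    respiratory motion correction (uRMC) for time-of-flight PET/CT. Includes a
    parametric 4D breathing thoracoabdominal phantom and TOF list-mode
    simulator, centroid-of-distribution (COD) respiratory signal extraction
    from list-mode events restricted to a body-cavity-derived respiratory
    region of interest, amplitude-based equal-count gating, TOF list-mode
    MLEM/OSEM reconstruction with and without attenuation correction, per-gate
    attenuation-map estimation behind a pluggable interface, mutual-information
    reference-gate selection, demons-style non-rigid registration and gate
    consolidation, single-modal PET-CT alignment in attenuation-map space, and
    quantitative evaluation (SUV metrics, lesion size categories, paired
    comparisons, organ motion amplitudes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    signal,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
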