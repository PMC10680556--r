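Package: slimcount
Title: Single-Molecule Stoichiometry, Periodicity and Photophysiology
    Analysis for Slimfield Microscopy
Version: 1.0.0
Authors@R:
    person("slimcount", "developers", email = "slimcount@example.org",
           role = c("aut", "cre"))
Description: Estimates the subunit stoichiometry of fluorescently tagged
    membrane protein complexes from Slimfield single-molecule fluorescence
    microscopy.  Provides ground-truthed synthetic data generators
    (photoelectron-calibrated image stacks with diffusing, photobleaching
    complexes; photobleaching intensity traces; PAM fluorescence and
    electrochromic-shift absorbance time series), spot detection and
    nearest-neighbour tracking inside region-of-interest masks,
    single-molecule brightness calibration from terminal photobleaching
    steps, stoichiometry estimation by backward linear extrapolation of
    track intensity, kernel-density peak-interval periodicity inference
    with bootstrap confidence intervals, and photophysiology metrics
    derived from pulse-amplitude-modulated chlorophyll fluorescence and
    electrochromic-shift measurements (NPQ, Y(II), Fv/Fm, qE, PMF, gH+,
    vH+), together with chlorophyll and specific-growth-rate formulas.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
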