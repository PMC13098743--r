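Package: rbctdo
Title: Hybrid Diffuse-Optics Analysis of Red Blood Cell Transfusion Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of hybrid diffuse-optical monitoring
    (time-resolved near-infrared spectroscopy and diffuse correlation
    spectroscopy) of red blood cell transfusion sessions in critically ill
    patients. Provides closed-form semi-infinite photon-diffusion forward
    models, compiled inverse fitting of photon time-of-flight histograms and
    intensity autocorrelation curves, signal quality control, derivation of
    hemodynamic biomarkers (tissue oxygen saturation, oxygen extraction
    fraction, blood-flow index, hematocrit-corrected metabolic rate of
    oxygen), a seeded synthetic transfusion-session generator, and the
    nonparametric pre/post cohort statistical battery with exact Wilcoxon
    signed-rank inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
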