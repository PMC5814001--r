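Package: cbctcm
Title: Attenuation-Based Tube Current Modulation for Cone-Beam CT
Version: 0.1.0
Authors@R: person("CBCT", "Tools", email = "cbctcm@example.org", role = c("aut", "cre"))
Description: Plans, simulates and evaluates attenuation-based tube current
    modulation (TCM) for kilovoltage cone-beam CT as used in image-guided
    radiation therapy. From a prior attenuation map (synthetic phantom or
    planning CT volume) it computes per-view attenuation factors by Siddon
    ray tracing, derives the minimal per-view tube currents that preserve
    the noise variance of a conventional uniform-current scan, simulates
    Beer-Lambert/Poisson projections with optional bowtie fluence profiles,
    reconstructs with fan-beam filtered backprojection or FDK (including
    displaced-detector redundancy weighting), and quantifies image quality
    (ROI coefficient-of-variation noise, SSIM, line profiles) and a
    primary-fluence dose proxy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
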