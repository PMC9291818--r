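Package: isopixel
Title: Dual Stable-Isotope NanoSIMS Image Analysis for Mycorrhizal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies 13C and 15N enrichment in nanoscale secondary ion mass
    spectrometry (NanoSIMS) count images of ectomycorrhizal root-tip
    cross-sections. Computes per-pixel isotope fractions (at%13C from the C2-
    pairing formula, at%15N from the CN- species) with Poisson counting
    uncertainties, atom-percent-excess (APE) calibration against an unlabelled
    control, mosaic assembly of tile acquisitions with screening for the
    N2-adsorption bias in re-measured overlap areas, region-of-interest tissue
    statistics, and segmented (breakpoint) linear regression of the spatial
    C-N coupling with Davies-type breakpoint testing, bootstrap standard
    errors, and AIC/BIC model selection. A synthetic-scene generator simulates
    ion-count tiles from ground-truth enrichment fields and root-system-scale
    bulk APE tables so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
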