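Package: scatterprint
Title: Multi-Scale Scattering Analysis and Structural Fingerprints of Food Emulsions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale structural characterisation of dairy and
    plant-based emulsions from ultra-small-, small- and wide-angle X-ray
    scattering (USAXS/SAXS/WAXS) together with dynamic light scattering.
    Reads and merges reduced 1D scattering curves, forward-smears and
    iteratively desmears slit-smeared (Bonse-Hart) USAXS data, estimates
    Porod specific surface areas and equivalent droplet radii, detects
    lamellar and triglyceride-polymorph Bragg peaks, builds log-log gradient
    "structural fingerprint" heat maps, correlates intensity read-outs with
    product composition, and implements cumulant polydispersity, Stokes-
    Einstein sizing and Henry/Smoluchowski zeta-potential formulae. A
    synthetic-data generator produces emulsion-like curves and DLS
    correlation functions with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    scales,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
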