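Package: genokrig
Title: Kriged Air-Pollutant Exposure Surfaces and Genotoxicity Biomarker
    Associations in a Simulated Industrial District
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for semi-ecological studies of outdoor air
    pollution and early genotoxic damage in children. Simulates an
    industrial district with anisotropic pollutant fields and hot spots
    around wood-panel factories, places passive-sampler monitoring sites by
    balanced k-medoids clustering of residences, converts multi-campaign
    measurements with missingness into annual site means by the
    difference-method temporal adjustment used in multi-campaign passive
    sampling protocols, fits exponential-class variograms and interpolates
    annual surfaces by ordinary kriging with leave-one-out cross-validated
    model selection, assigns standardized residential exposures, and
    estimates per-1-SD associations with comet-assay markers (weighted
    linear models) and micronucleus-assay counts (negative-binomial
    models), including crude/adjusted batteries and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
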