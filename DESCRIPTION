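Package: requant
Title: Peptide Identity Propagation and Direct Ion Current Extraction for
    Label-Free DDA Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Re-quantification workflow for label-free data-dependent
    acquisition (DDA) proteomics. Aggregates per-sample detected peptide
    features into cross-sample consensus features, estimates data-driven
    retention-time and m/z alignment windows, fits per-sample mass-error
    (random forest) and retention-time drift (generalized additive) models,
    propagates peptide identities between runs, and quantifies every
    consensus feature in every sample by direct ion current extraction
    (DICE) from centroided MS1 ion maps. Reliability of the recovered
    quantifications is controlled with decoy extraction windows: a
    background-noise model, an empirical significance score for ion
    accumulation, and a masking-based estimate of the peak-selection false
    discovery rate. Includes a synthetic DDA experiment generator with
    ground truth, peptide-to-protein rollup (Top3, sum, MaxLFQ), and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    MASS,
    mgcv,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
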