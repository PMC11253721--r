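Package: deutracer
Title: Machine-Learning Detection of Deuterium-Labeled Metabolites in
    Untargeted LC-MS Isotope-Tracing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for global untargeted stable-isotope-traced metabolomics
    with intrinsically deuterium-labeled foods. Candidate isotopologue
    envelopes produced downstream of XCMS-style peak picking are filtered with
    a rule engine, described by per-envelope isotopologue-ratio features
    (with random-forest imputation of missing M1 features and discretization
    of M2/M3 features with an explicit "missing" category), classified with a
    random forest, and aggregated into a per-candidate labeling score
    p_L/(p_U + c) used to rank candidates for manual curation. Includes
    consecutive-isotopologue ratio validation of label incorporation, adduct
    arithmetic linking measured m/z to neutral monoisotopic mass, and a
    synthetic isotopologue-envelope simulator (natural-abundance convolution,
    binomial deuterium enrichment, pool-mixing dilution, multiplicative noise
    and detection-limit censoring) that provides ground-truth benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'annotate.R'
    'classifier.R'
    'deutracer-package.R'
    'features.R'
    'io.R'
    'isotope-distributions.R'
    'metabolite-library.R'
    'pipeline.R'
    'qfilter.R'
    'scoring.R'
    'simulate.R'
    'utils.R'
    'validation.R'
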