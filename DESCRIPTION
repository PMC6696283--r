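Package: tpscreen
Title: Suspect-Target Screening of Drug Transformation Products by
    Accurate-Mass LC/HRMS and EC/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying transformation products (TPs) of small-
    molecule drugs from high-resolution mass spectrometry experiments:
    adduct-aware exact-mass arithmetic over the elements C, H, N, O and Na,
    element-bounded molecular formula decomposition within a ppm tolerance,
    isotope-pattern simulation with a sigma-style goodness-of-fit score for
    candidate ranking, labelling of TPs as combinations of elementary
    transformation reactions (decarboxylation, O-demethylation, dehydration,
    ...), trend screening of electrochemical mass voltammograms, and
    pH-dependent hydrolysis occurrence tables. Ships seeded synthetic-data
    generators that emulate electrochemistry/MS potential ramps and
    acid-catalyzed hydrolysis time series with ground-truth manifests, and a
    curated reference table of monensin transformation products used as the
    worked case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
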