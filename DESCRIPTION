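Package: oasustain
Title: Subtype and Stage Inference for Knee Osteoarthritis Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits mixtures of linear z-score event-based progression models
    (SuStaIn-style subtypes-progression models) to cross-sectional biomarker
    panels, as used to disentangle phenotypic and temporal heterogeneity in
    knee osteoarthritis. Provides control-referenced z-scoring with
    direction handling, z-score event-set construction, greedy and EM
    fitting of subtype progression sequences, Metropolis-Hastings posteriors
    over event orderings, cross-validated information criterion (CVIC)
    selection of the number of subtypes, per-subject subtype and stage
    assignment with a strong-assignment rule, baseline subtypes-only
    (Gaussian mixture) and stages-only models with likelihood-ratio
    comparison, and a synthetic cohort generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
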