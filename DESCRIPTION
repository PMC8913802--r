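Package: acousticSC
Title: Spatial Count Models for Passive Acoustic Detector Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates animal density from counts of vocalisations recorded
    on arrays of passive acoustic sensors, using unmarked spatial count (SC)
    models fitted by data-augmentation Markov chain Monte Carlo. Provides a
    synthetic acoustic-survey generator (model-exact and survey-protocol
    variants), half-normal encounter models with home-range-informed priors,
    a Metropolis-within-Gibbs sampler with adaptive proposals and
    Gelman-Rubin diagnostics, posterior density surfaces with forest-category
    overlays, BACIPS (before-after-control-impact paired series) tests of
    harvest effects, and a reproducible file-based workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
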