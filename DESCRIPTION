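Package: sympdyn
Title: Dynamic Time Warping Analysis of Longitudinal Symptom Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics of multi-symptom
    patient-reported outcome panels. Per-patient band-constrained dynamic
    time warping (symmetric2 step pattern, Sakoe-Chiba band declared in
    visit units) turns 32-item longitudinal symptom profiles into symmetric
    and directed symptom-by-symptom distance matrices; Distatis integrates
    the per-patient matrices into a group compromise space with bootstrap
    confidence envelopes; Ward.D2 hierarchical clustering with an
    elbow criterion extracts symptom clusters; directed symptom networks
    with in-/out-strength centralities summarise lead-lag structure; and a
    split-half congruence analysis quantifies the stability of the group
    network. A synthetic cohort generator with planted cluster and
    driver-follower structure provides a fully controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vegan,
    igraph,
    ape,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
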