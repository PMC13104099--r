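Package: riaimpact
Title: Research Integrity Assessment Impact Pipeline for Systematic Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening randomized controlled trials for research
    integrity concerns and quantifying the downstream impact on systematic
    reviews. Implements the hierarchical six-domain integrity assessment
    workflow (retraction, trial registration, ethics, authorship, plausibility
    of methods, plausibility of results) with multi-assessor adjudication and
    author-correspondence reclassification; linear-weighted Cohen's kappa
    interrater reliability with asymptotic standard errors; fixed-effect and
    DerSimonian-Laird random-effects pooling of 2x2 trial outcome tables for
    sensitivity re-analysis; classification of pooled effects against an
    equivalence range by direction, precision and interpretation; corpus-level
    impact and feasibility reporting; and a calibrated synthetic corpus
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
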