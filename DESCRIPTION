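Package: goodrank
Title: University League Tables Based on Good Research Practice, with
    Rank Uncertainty and Bayesian Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds institutional league tables that reward good research
    practice, scored by fractional counting of author affiliations on
    papers that cite a reporting guideline (CONSORT, PRISMA or STROBE).
    Provides a synthetic Scopus-like corpus generator with known ground
    truth, eligibility filtering (guideline citation, title phrases,
    publication type, DOI, year), rule-based normalization of free-text
    affiliation strings, organisational-level fractional scoring with a
    nominal "Missing" institution, paper-level bootstrap confidence
    intervals for ranks, a bespoke MCMC sampler for a five-component
    Bayesian ordered mixture model that groups institutions into
    clusters, and Bland-Altman / Spearman diagnostics of between-year
    rank agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    Matrix,
    coda,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
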