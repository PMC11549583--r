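Package: pnavax
Title: Personal Network Analysis of Vaccination Assortativity and Media Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for egocentric (personal) network studies of health
    behaviour, centred on COVID-19 vaccination. Provides a three-table
    interchange format for ego, alter and alter-alter tie data; derivation of
    media-use categories, tie binarization and ego-alter intensity; structural
    measures (density, components, normalized betweenness) on the alter graph;
    a per-alter vaccination assortativity score with referral-chain dyad
    concordance; cohort-construction filters; two-level random-intercept
    logistic regression with latent-scale ICC and marginal/conditional R2,
    plus a cluster-robust GLM variant; a synthetic personal-network generator
    with known ground truth; and pipeline orchestration with Table-1-style
    descriptive reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    igraph,
    lme4,
    sandwich,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
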