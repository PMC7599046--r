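Package: nichenb
Title: Hybrid Niche-Neutral Models of Microbiota Species Abundance Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hybrid niche-neutral models to per-sample OTU count data by
    modelling the Relative Species Abundance distribution as a mixture of one
    to three zero-truncated Negative Binomials, each component describing a
    neutral ecological niche with its own birth, death and immigration rates.
    Inference uses a two-step hierarchical Approximate Bayesian Computation
    rejection scheme with Preston-plot (log2 octave) acceptance criteria, and
    yields the Hubbell biodiversity numbers of the rare and abundant niches
    alongside classical alpha-diversity indices (Shannon, Pielou, Simpson,
    Hill numbers). Includes downstream cohort statistics: natural cubic
    spline age-trend regression with per-dataset deviation contrasts,
    covariate adjustment, Mann-Whitney group comparisons, an elderly health
    classifier, a principal-component health score, and leave-one-out
    cross-validated health prediction with ROC AUC. A synthetic-data
    generator produces communities and cohorts with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    biomformat,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
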