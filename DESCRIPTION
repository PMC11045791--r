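Package: agrivar
Title: Case-Only Gene-Environment Variant Prioritization for
    Pesticide-Exposed Parkinson's Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A case-only gene-environment analysis pipeline for targeted
    gene-panel studies of Parkinson's disease in agricultural regions.
    Scores subjects for long-term ambient pesticide exposure using
    toxicity-weighted sums over co-application clusters, estimates
    per-subject disease progression with empirical-Bayes random slopes
    from a linear mixed model of longitudinal UPDRS-III examinations,
    filters panel variant calls and removes cryptically related samples
    via method-of-moments identity-by-descent estimation, tests each
    surviving variant for allele-frequency enrichment against an
    ancestry-matched reference population with a two-proportion z-test,
    and ranks enriched variants by a composite disease-severity by
    pesticide-exposure score. A synthetic-cohort generator reproduces
    the statistical structure of all pipeline inputs (longitudinal
    clinical scores with true random slopes, correlated co-application
    pesticide records, panel variants planted with frequency inflation
    and exposure-biased carriers, related sample pairs) together with
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
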