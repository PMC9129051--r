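Package: kneeclust
Title: Biclustering and Longitudinal Phenotyping of Knee Osteoarthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phenotype discovery for knee osteoarthritis cohort data.
    Prepares mixed-type baseline clinical matrices (skewness-reducing
    transforms, standardization, indicator encoding, complete-case
    filtering), extracts mutually row-exclusive Cheng-Church biclusters by
    mean-squared-residue node deletion and addition, tests bicluster pairs
    for significance with SigClust (Gaussian null, cluster index,
    z-scores), fits group-based trajectory models to longitudinal pain
    change scores (polynomial-mean normal mixtures with a logistic dropout
    extension, BIC model selection, posterior assignment), and classifies
    longitudinal structural outcomes (radiographic progression levels,
    arthroplasty, quantitative joint-space-width percentage loss). A
    seeded synthetic-cohort generator with planted biclusters, a known
    trajectory mixture and linked progression outcomes provides ground
    truth for validation, and a single-call pipeline orchestrates the full
    analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    tools,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
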