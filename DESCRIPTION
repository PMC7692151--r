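Package: vagcomp
Title: Compositional and Quantitative Analysis of Vaginal Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vaginal microbiome cohorts with aerobic
    vaginitis (AV), bacterial vaginosis (BV) and Lactobacillus-dominated
    reference (NL) groups. Implements an ANCOM-style compositional
    differential-abundance test on pairwise log ratios with Wilcoxon
    rank-sum testing, Benjamini-Yekutieli false-discovery-rate control and
    Hodges-Lehmann effect quantification; absolute quantification of qPCR
    measurements through log-linear standard curves with non-detect
    handling and bacteria-to-human load ratios; cohort-level summaries
    (dominance and prevalence profiling, top-genus aggregation,
    Bray-Curtis seriation, score correlations, nonparametric group
    comparisons); and a synthetic-cohort generator with full ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
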