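Package: admixMR
Title: Mendelian Randomization for Genetic Ancestry and Disease Risk in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate the confounder-free effect of individual genetic
    ancestry proportions on disease risk in admixed case-control studies.
    Implements ancestry-informative-marker preselection with the informativeness
    for assignment measure, supervised maximum-likelihood (EM) estimation of
    individual admixture proportions from fixed reference-panel allele
    frequencies, eigenstrat-style principal components, instrument selection
    (exposure association scan, phenome-wide exclusion, explained-variance-ranked
    linkage-disequilibrium pruning, instrument-strength summaries), and
    two-sample Mendelian randomization with inverse-variance-weighted, MR-Egger
    and weighted-median estimators, Cochran's Q heterogeneity diagnostics,
    radial outlier exclusion, stratified analyses and analytic power. A
    simulation module generates reference panels and three-way admixed
    case-control cohorts with a configurable disease model so the whole pipeline
    can be exercised and validated without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
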