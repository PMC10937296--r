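Package: broodmethyl
Title: Carry-Over Effects of Brood Size on Post-Fledging DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing carry-over effects of a brood
    size manipulation on post-fledging phenotypes and erythrocyte CpG
    methylation in great tits (Parus major). Provides a synthetic-data
    generator for cross-foster designs with treatment-dependent recapture
    and planted interaction effects; readers for Bismark-style coverage and
    cytosine-report files with strand merging and a four-stage filtering
    pipeline; a fast binomial logit mixed-model engine (Laplace
    approximation, nested random intercepts) with likelihood-ratio
    screening, Benjamini-Hochberg FDR, overdispersion filtering by highest
    density interval and six-category interaction classification;
    priority-ordered, strand-aware gene-region annotation from GFF3; and
    the phenotype mixed-model stage with backward elimination, type III
    Satterthwaite tests and per-treatment slope contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
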