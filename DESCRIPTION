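Package: retrowas
Title: Retrotranscriptome-Wide Association Analysis with Locus-Resolved Repeat Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide association studies that include
    locus-resolved human endogenous retrovirus (HERV) expression alongside
    canonical genes. Provides expectation-maximisation reassignment of
    ambiguously mapped fragments to repeat loci, expression filtering and
    TMM/logCPM normalisation, covariate and surrogate-variable adjustment,
    genotype and summary-statistic quality control, cis-heritability
    estimation with likelihood-ratio gating, cross-validated SNP weight
    construction (top eQTL, lasso, elastic net, BLUP), summary-statistic
    association, conditional/joint analysis, Bayesian expression
    fine-mapping, and signed co-expression network analysis. A synthetic
    data generator with known ground truth makes every stage testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    edgeR,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
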