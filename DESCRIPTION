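Package: epiwide
Title: Transcriptome-Wide Epistasis and Companion Statistics for Starvation Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for genetic-interaction analysis of bulk RNA-seq
    experiments with two loss-of-function mutants and their double mutant.
    Implements the transcriptome-wide epistasis coefficient (through-origin
    weighted regression of the double mutant's deviation from log-additivity),
    a gene-resampling bootstrap, predefined interaction models (log-additive,
    linear activation, linear suppression) and Bayesian model rejection via
    kernel-density odds ratios. Companion modules provide a transparent
    log-CPM differential-expression front end with TMM normalization,
    gene-set overlap and distribution-shift statistics, quasi-binomial
    starvation-survival curve fits with half-life comparisons and aligned-rank
    factorial ANOVA, positional peptide-cleavage analysis, and negative-binomial
    count simulators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    DESeq2,
    apeglm,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
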