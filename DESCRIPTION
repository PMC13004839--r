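Package: gremnet
Title: Gene Regulatory Network Inference from Chromatin Accessibility and
    Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers transcription-factor (TF) to gene regulatory networks by
    combining chromatin accessibility with expression data. A motif prior is
    built by scanning position weight matrices over accessible peaks and
    linking peaks to nearby transcription start sites; latent TF activities
    are estimated by pseudoinversion of the linear model expression =
    activities x network; a sparse signed network is then inferred per gene
    by exhaustive best-subset regression scored by BIC with model averaging.
    Networks are validated by simulating TF-knockout expression (knockout
    activities times the wild-type network) and scoring agreement with
    observed expression by R-squared, and by classifying genes into
    expression/accessibility concordance classes. A seeded synthetic-data
    generator produces ground-truth networks, activities, genome scaffolds
    and count matrices so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
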