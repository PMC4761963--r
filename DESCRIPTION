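Package: promreg
Title: Promoter Regression Modelling of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers transcription-factor activity from promoter sequence and
    expression data. Promoters are scanned against position weight matrices
    with MATCH-style matrix and core similarity scores; differentially
    up-regulated genes are called against a control condition and partitioned
    between two treatments; the expression of those genes is modelled by
    best-subset linear regression on binding-site counts, with bootstrap
    distributions of regression coefficients tested by one-sample t-tests
    under Bonferroni control; significant, up-regulated factors are assembled
    into a TF-to-target regulatory network exportable to SIF and GraphML.
    Includes a seeded synthetic-data generator (planted motifs, linear
    expression model) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
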