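Package: dcrif
Title: Differential Coexpression Analysis and Regulatory Impact Factor
    Ranking of Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects differentially coexpressed genes (DCGs) and links
    between two sample conditions from a gene-by-sample expression matrix
    using a root-mean-square correlation-change statistic with
    permutation p-values and Benjamini-Hochberg false discovery rate
    control; tests the DCG list for pathway over-representation with the
    hypergeometric distribution; overlays DCGs on a transcription
    factor-to-target regulatory map; and ranks transcription factors by
    the regulatory impact factor (RIF), a statistic combining target
    expression levels with the change in TF-target coexpression between
    conditions.  A synthetic-data generator plants sign-flipping
    coexpression modules with known ground truth so the whole pipeline
    can be validated end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
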