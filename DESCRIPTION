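Package: mlsom
Title: Multi-Layer Self-Organizing Map Portrayal for Transcriptome-Guided
    Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Joint self-organizing map (SOM) portrayal of multiple
    case-control expression datasets ("layers") on one shared metagene
    grid, segmentation of overexpression spots, differential spot calling
    by combined presence/absence and t-test votes, and declaration of drug
    repositioning candidates from antagonistically regulated spots between
    disease and treatment layers.  Includes sample-wise gene-set Z (GSZ)
    scoring, Fisher exact spot annotation, Pathway Signal Flow propagation
    of fold changes through signed pathway topologies, and a synthetic
    multi-layer data generator with planted co-regulated modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
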