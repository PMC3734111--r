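Package: atlasmine
Title: Meta-Analysis of Multi-Tissue Expression Atlases for Core Tissue Signatures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining multi-tissue gene expression atlases of the
    FlyAtlas kind: replicate aggregation with Affymetrix-style detection
    calls, fold-change enrichment against a whole-organism reference,
    consensus core-signature detection across a tissue set, top-N
    tissue-specificity ranking, curated gene-list profiling with
    dominant-isoform selection, and clustering of tissue transcriptomes
    (correlation-distance dendrograms and PCA). Includes a synthetic atlas
    generator with planted gene classes and a recovery evaluator, so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
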