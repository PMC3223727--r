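Package: orfpipe
Title: Enzyme Annotation, Localization Prediction and Structural
    Verification of Predicted ORFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for functional and structural annotation
    of predicted open reading frames (ORFs). Transfers Enzyme Commission
    (EC) numbers onto translated ORF models by reciprocal best hits against
    an EC-labelled enzyme database and extends them to paralogs by
    single-linkage sequence clustering; predicts subcellular localization
    with a k-nearest-neighbor probability model over amino-acid composition,
    with dual-lineage (plant/animal) consolidation; verifies ORF structural
    models from shotgun-style amplicon reads (trim, map, per-base coverage,
    classification) and from paired Sanger-style end reads (vector clipping,
    overlap assembly, end verification); and designs Gateway-tailed
    ORF-specific primer pairs under melting-temperature constraints. A
    fully deterministic synthetic-data generator provides ground-truthed
    inputs for every stage, so the whole pipeline is testable end to end
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
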