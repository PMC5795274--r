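Package: tfanno
Title: Target-Gene-Based Functional Annotation of Transcription Factors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates the biological functions of transcription factors (TFs)
    from the functions of their target genes. Implements TIP-style statistical
    target-gene calling from TSS-anchored ChIP-seq binding-signal matrices, a
    TF-target-gene compendium data model with GMT serialisation, gene-set
    enrichment of target genes under explicitly chosen gene universes with
    per-source Benjamini-Hochberg control, a randomized-compendium null model
    with an empirical false discovery rate, TF-TF and function-function
    sharing networks including a discordance analysis of target-function
    versus target-gene similarity, and uniqueness-weighted effective-number
    (diversity) indices for measuring regulator diversity and functional
    pleiotropy. A synthetic-data generator with planted TF-function structure
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'compendium.R'
    'utils.R'
    'enrichment.R'
    'diversity.R'
    'io.R'
    'nullModel.R'
    'similarity.R'
    'targetCalling.R'
    'simulate.R'
    'pipeline.R'
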