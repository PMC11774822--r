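Package: phosfusion
Title: Bimodal Embedding Fusion for Activity-Enhancing Kinase Phosphosites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies kinase phosphorylation sites that enhance kinase
    activity by fusing two embedding modalities: a masked-autoencoding
    transformer embedder trained on sparse phosphorylation mass-spectrometry
    (phospho-MS) intensity matrices, and precomputed protein-sequence
    embeddings from a protein language model. Provides phospho-MS matrix
    preprocessing (deduplication, detection filtering, minimum-downshift
    imputation, global min-max normalization), flanking-sequence and
    structural feature engineering with PROSITE signature scanning,
    kinase-substrate relation prediction from pooled site embeddings,
    substrate phosphorylation enrichment scoring, a weighted bimodal
    classifier with an under-sampling training protocol, and seeded synthetic
    data generators for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
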