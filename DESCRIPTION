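Package: OrthoDuet
Title: Dual-Pipeline Ortholog Group Inference from Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph- and domain-based orthology inference for sets of
    proteomes. The graph pipeline infers bidirectional-best-hit (BBH)
    orthologs while reducing the all-versus-all alignment cost through
    "essential subsets" (only proteins with an above-threshold hit in the
    first alignment direction can take part in a BBH) and a boosted-stump
    classifier that predicts the faster alignment direction for each
    proteome pair. The domain pipeline tokenizes Pfam-style domain
    architectures into documents, trains distributed bag-of-words
    paragraph-vector embeddings on the fly, and links proteins whose
    architecture embeddings have high cosine similarity, recovering
    orthologs missed by BBH after domain fusion or fission. The two sets
    of species-pair ortholog clusters are merged by rule and Markov
    clustering of the resulting ortholog graph yields multi-species
    ortholog groups. Includes a synthetic-proteome generator with planted
    orthologs, inparalogs and domain fusions so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Matrix,
    igraph,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
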