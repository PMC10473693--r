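Package: novelsim
Title: Controlled Transcript-Novelty Simulation for Long-Read RNA-Seq Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation environment for benchmarking transcriptome reconstruction
    from long-read RNA-seq. Classifies reference transcripts into their potential
    structural categories (FSM, ISM, NIC, NNC, genic-genomic, antisense, fusion,
    intergenic) relative to the rest of the annotation, removes a user-requested
    number of transcripts per category to produce a reduced "ground truth"
    annotation, assigns expression by equal, negative-binomial or empirical
    inverse-transform sampling, simulates long reads with configurable ONT and
    PacBio error profiles, simulates matched paired-end short reads and CAGE
    peaks (including a logistic TSS-support model), and evaluates reconstructed
    transcriptomes against the simulated ground truth with per-category
    sensitivity, precision, F1, PDR and FDR. Includes a seeded synthetic
    genome and annotation generator that guarantees candidates of every
    structural category, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stringi,
    jsonlite,
    Biostrings,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
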