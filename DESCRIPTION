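Package: rnannotate
Title: Bacterial Transcriptome Annotation from Strand-Specific RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns strand-specific RNA-seq nucleotide coverage (differential
    RNA-seq TEX+/TEX- library pairs and fragmented conventional RNA-seq)
    together with a genome sequence and an existing gene annotation into a
    high-resolution transcriptome annotation for bacteria and archaea:
    coverage-based transcripts, transcriptional start sites and RNA
    processing sites under a seven-parameter enrichment model with genetic-
    algorithm parameter optimization against a curated site set,
    rho-independent terminators (convergent-gene hairpin heuristic plus
    coverage-drop confirmation), 5'/3' UTRs, operons and sub-operons, small
    noncoding RNA candidates of five origins, and small ORFs with
    ribosome-binding-site support. A synthetic-data generator plants ground
    truth for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
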