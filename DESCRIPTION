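Package: saltomics
Title: Multi-Level Integration of Transcriptome, Proteome, Splicing and
    miRNA Responses to Salt Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates mRNA-seq, iTRAQ proteomics, alternative-splicing
    and small-RNA profiles for two contrasting genotypes under stress.
    Provides replicate-free exact-binomial differential expression on
    RPKM-normalised counts, iTRAQ ratio differential-abundance calling,
    six-category gene-protein concordance classification with subset
    correlations, alternative-splicing event accounting, plant miRNA
    target complementarity scanning with anticorrelation chains,
    stringent candidate screening rules, protein-protein interaction
    hub analysis with hypergeometric term enrichment, and a synthetic
    multi-omics generator with planted ground truth for end-to-end
    validation by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
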