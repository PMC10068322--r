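Package: pascleave
Title: Transcriptome-Wide Polyadenylation-Site Cleavage-Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pre-mRNA 3'-end processing (polyadenylation-site
    cleavage) efficiency from stranded RNA-seq by counting reads in 500-nt
    windows upstream ("total RNA") and downstream ("uncleaved RNA") of each
    gene's polyadenylation site, and tests per gene whether the
    downstream/upstream ratio changes between two conditions with a
    negative-binomial interaction Wald test. Also provides the companion
    qPCR delta-Ct ratio statistics (uncleaved/total, nucleoplasm/chromatin
    release, RNA-IP enrichment), primer-walk localization of
    co-transcriptional cleavage (CoTC) sites with AT-rich element scanning,
    and seeded synthetic generators (count matrices, stranded alignments,
    primer walks, Ct tables) with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
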