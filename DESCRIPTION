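Package: npmine
Title: Neuropeptidome Mining from Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines assembled nucleotide transcriptomes for neuropeptide and
    protein-hormone precursors and models their post-translational maturation.
    Provides six-frame open reading frame calling with completeness classes, a
    von Heijne style signal-peptide heuristic with an external-annotation
    override, prohormone-convertase cleavage-site scanning under a configurable
    basic-residue grammar, carboxypeptidase trimming with C-terminal amidation
    and pyroglutamate flagging, peptide-family classification by sequence motif,
    cysteine scaffold and annotation keywords, conservation statistics (global
    alignment, consensus motifs, neighbor-joining trees), and RPKM-based
    tissue-contrast expression analysis. A synthetic-data module generates
    ground-truthed precursor proteins, transcripts and negative-binomial read
    counts so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
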