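Package: motiflink
Title: Conserved Linked Transcription-Factor Binding-Site Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics screen for linked transcription-factor
    binding sites in conserved non-coding sequence. Scans a reference genome
    for IUPAC consensus motifs (SOX9, GLI, TCF by default) on both strands,
    filters occurrences by perfect conservation against a partner species in
    multiz-style multiple alignments (MAF), restricts to inter- and intragenic
    non-coding space, pairs motifs under a spacing constraint, assigns pairs to
    genes, and tests gene-set over-representation with exact hypergeometric and
    one-tailed Fisher statistics computed in log-gamma arithmetic. Includes a
    seedable synthetic-data generator that plants perfectly conserved motif
    pairs in multi-species alignments so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
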