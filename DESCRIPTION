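Package: txtailor
Title: Transcript-Model Tailoring: 3' End Extension, Alternative-Splicing
    Classification and Terminal-Signal Analysis for Compact Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining protein-coding gene models in compact,
    gene-dense genomes using 3'-end-biased sequencing evidence. Clusters
    stranded 3'-end read alignments and extends annotated transcript 3'
    ends supported by tag clusters; classifies alternative-splicing
    events among a gene's isoforms into seven classes (intron retention,
    alternative terminal exon, alternative acceptor/donor, exon
    skipping, intronic start/end) and summarises them; compares
    competing annotation sets hierarchically at a coverage threshold and
    computes gene-structure statistics; and profiles polyadenylation
    signals and other motifs around transcript start and termination
    sites. Includes seeded generators for synthetic genomes, isoform
    sets and 3'-end read pileups with known ground truth, so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
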