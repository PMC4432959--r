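# Small in-code fixtures shared across tests.

# one gene from an exon coordinate list: list(c(start, end), ...)
toy_gene <- function(exons, strand = "+", gene_id = "g1", tx_id = "g1.t1",
                     seqid = "sc1", cds = NULL) {
  ex <- tibble::tibble(
    gene_id = gene_id, transcript_id = tx_id, seqid = seqid,
    strand = strand,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2))
  cds_tbl <- if (!is.null(cds))
    tibble::tibble(transcript_id = tx_id, seqid = seqid, strand = strand,
                   start = vapply(cds, `[`, numeric(1), 1),
                   end = vapply(cds, `[`, numeric(1), 2))
  annotation_from_exons(ex, cds = cds_tbl, name = "toy")
}

# merge several annotations (unique gene/transcript ids assumed)
bind_annotations <- function(..., name = "toy") {
  anns <- list(...)
  new_annotation(
    name,
    genes = dplyr::bind_rows(lapply(anns, `[[`, "genes")),
    transcripts = dplyr::bind_rows(lapply(anns, `[[`, "transcripts")),
    exons = dplyr::bind_rows(lapply(anns, `[[`, "exons")),
    cds = dplyr::bind_rows(lapply(anns, `[[`, "cds")))
}

# add an isoform (same gene) to an annotation
add_isoform <- function(ann, gene_id, tx_id, exons) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  ex <- tibble::tibble(
    transcript_id = tx_id, seqid = g$seqid, strand = g$strand,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2))
  ann$exons <- dplyr::bind_rows(ann$exons, ex)
  ann$transcripts <- dplyr::bind_rows(
    ann$transcripts,
    tibble::tibble(transcript_id = tx_id, gene_id = gene_id,
                   seqid = g$seqid, strand = g$strand,
                   start = min(ex$start), end = max(ex$end)))
  txtailor:::recompute_spans(ann)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads tibble shorthand
reads_tbl <- function(starts, ends, strand = "+", seqid = "sc1",
                      sample = "s1") {
  tibble::tibble(seqid = seqid, start = as.integer(starts),
                 end = as.integer(ends), strand = strand, sample = sample)
}

# small deterministic simulation shared by several test files
small_sim <- function(seed = 42L, n_genes = 40L) {
  generate_genome_annotation(sim_config(
    seed = seed, n_scaffolds = 2L,
    scaffold_len_range = c(120000L, 160000L), n_genes = n_genes))
}
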