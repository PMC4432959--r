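#' Read a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS records (via `rtracklayer::import()`;
#' gzip-transparent) into a [new_annotation()] model. Hierarchy is resolved
#' through `ID`/`Parent` attributes, so line order is irrelevant. UTR
#' feature lines, if present, are ignored: UTRs are always derived from the
#' exon minus CDS difference (see [utr_table()]).
#'
#' @param path GFF3 file (optionally gzipped).
#' @param name Annotation-set name; defaults to the file base name.
#' @param genome Optional genome to bounds-check features against.
#' @return A `txa_annotation`.
#' @export
read_gff3 <- function(path, name = NULL, genome = NULL) {
  name <- name %||% sub("\\.(gff3?|gff3\\.gz|gff\\.gz)$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  tb <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p) == 0) NA_character_ else p[[1]], character(1))
  )
  genes <- tb %>%
    filter(.data$type == "gene") %>%
    select(gene_id = "id", "seqid", "strand", "start", "end")
  tx <- tb %>%
    filter(.data$type %in% c("mRNA", "transcript")) %>%
    select(transcript_id = "id", gene_id = "parent", "seqid", "strand",
           "start", "end")
  if (any(is.na(tx$gene_id)) || !all(tx$gene_id %in% genes$gene_id)) {
    bad <- tx$transcript_id[is.na(tx$gene_id) |
                              !tx$gene_id %in% genes$gene_id][1]
    abort(paste0("malformed parentage: transcript ", bad,
                 " has no gene parent in file"))
  }
  part <- function(what) {
    p <- tb %>%
      filter(.data$type == what) %>%
      select(transcript_id = "parent", "seqid", "strand", "start", "end")
    bad <- setdiff(p$transcript_id, tx$transcript_id)
    if (length(bad) > 0 || anyNA(p$transcript_id))
      abort(paste0("malformed parentage: ", what, " feature with parent '",
                   c(bad, "<missing>")[1], "' not an mRNA in file"))
    p
  }
  ann <- new_annotation(name, genes, tx, part("exon"), part("CDS"))
  validate_annotation(ann, genome = genome)
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA, exon and CDS records with `ID`/`Parent` attributes in
#' a stable order (scaffold, gene start, gene id, then feature rank), so
#' two writes of the same model are byte-identical and the output
#' re-parses to an equal model.
#'
#' @param ann A `txa_annotation`.
#' @param path Output file path.
#' @param source String for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "txtailor") {
  gn <- ann$genes %>% arrange(.data$seqid, .data$start, .data$gene_id)
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, source, type, start, end, strand,
            if (type == "CDS") "0" else ".", attrs)
  }
  for (i in seq_len(nrow(gn))) {
    g <- gn[i, ]
    lines <- c(lines, fmt(g$seqid, "gene", g$start, g$end, g$strand,
                          paste0("ID=", g$gene_id)))
    txs <- ann$transcripts %>%
      filter(.data$gene_id == g$gene_id) %>%
      arrange(.data$start, .data$transcript_id)
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      lines <- c(lines, fmt(t$seqid, "mRNA", t$start, t$end, t$strand,
                            paste0("ID=", t$transcript_id,
                                   ";Parent=", g$gene_id)))
      ex <- ann$exons %>%
        filter(.data$transcript_id == t$transcript_id) %>%
        arrange(.data$start)
      lines <- c(lines, fmt(ex$seqid, "exon", ex$start, ex$end, ex$strand,
                            paste0("Parent=", t$transcript_id)))
      cd <- ann$cds %>%
        filter(.data$transcript_id == t$transcript_id) %>%
        arrange(.data$start)
      if (nrow(cd) > 0)
        lines <- c(lines, fmt(cd$seqid, "CDS", cd$start, cd$end, cd$strand,
                              paste0("ID=cds-", t$transcript_id,
                                     ";Parent=", t$transcript_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()]; reading is gzip-transparent.
#'
#' @param path FASTA file.
#' @return `read_genome_fasta()`: a named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname read_genome_fasta
#' @param genome Named `DNAStringSet` or named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write stranded intervals as BED6
#'
#' BED input is parsed with `rtracklayer::import.bed()` (0-based half-open
#' on disk) and returned as a 1-based closed tibble; the `score` column
#' carries read or cluster counts. `sample` ids, when present, are parsed
#' from the BED name field (`<sample>:<n>`); reads without one are
#' assigned sample `"s1"`.
#'
#' @param path BED6 file.
#' @return Tibble with `seqid`, `start`, `end`, `strand`, `name`, `score`,
#'   `sample`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- as.character(gr$name %||% NA_character_)
  tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = nm,
    score = as.numeric(gr$score %||% NA_real_),
    sample = ifelse(grepl(":", nm), sub(":.*$", "", nm), "s1")
  )
}

#' @rdname read_bed6
#' @param x Tibble with at least `seqid`, `start`, `end`, `strand`;
#'   optional `name` and `score`.
#' @export
write_bed6 <- function(x, path) {
  x <- as_tibble(x)
  nm <- if ("name" %in% names(x)) x$name else sprintf("i%d", seq_len(nrow(x)))
  sc <- if ("score" %in% names(x)) x$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   x$seqid, x$start - 1L, x$end, nm, sc, x$strand)
  writeLines(lines, path)
  invisible(path)
}
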