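#' Tidy gene-annotation container
#'
#' A `txa_annotation` bundles four tibbles describing a hierarchical gene
#' annotation anchored on genome coordinates: `genes`, `transcripts`,
#' `exons` and `cds`. All coordinates are 1-based, closed intervals on the
#' forward genomic axis; orientation is carried by `strand` (`"+"` or
#' `"-"`). Exons of a transcript are sorted by genomic start, never overlap,
#' and are separated by gaps of at least 1 bp (the introns).
#'
#' 5' and 3' UTRs are not stored: they are derived on demand from the
#' exon minus CDS difference on the transcript strand (see [utr_table()]),
#' so the model round-trips through GFF3 without redundancy.
#'
#' @param name Label for the annotation set.
#' @param genes,transcripts,exons,cds Tibbles; see Details.
#'
#' @details
#' Expected columns:
#' * `genes`: `gene_id`, `seqid`, `strand`, `start`, `end`
#' * `transcripts`: `transcript_id`, `gene_id`, `seqid`, `strand`,
#'   `start`, `end`
#' * `exons`: `transcript_id`, `seqid`, `strand`, `start`, `end`
#' * `cds`: same as `exons` (zero rows allowed)
#'
#' @return An object of class `txa_annotation`.
#' @seealso [annotation_from_exons()] for the usual constructor,
#'   [read_gff3()] / [write_gff3()] for I/O.
#' @export
new_annotation <- function(name, genes, transcripts, exons,
                           cds = empty_feature_tbl()) {
  ann <- structure(
    list(
      name = name,
      genes = as_tibble(genes),
      transcripts = as_tibble(transcripts),
      exons = dplyr::arrange(as_tibble(exons), .data$transcript_id, .data$start),
      cds = dplyr::arrange(as_tibble(cds), .data$transcript_id, .data$start)
    ),
    class = "txa_annotation"
  )
  ann
}

empty_feature_tbl <- function() {
  tibble(transcript_id = character(), seqid = character(),
         strand = character(), start = integer(), end = integer())
}

#' Build an annotation from an exon table
#'
#' Convenience constructor: derives the transcript and gene tables from a
#' flat exon tibble carrying `gene_id` and `transcript_id` columns. Gene
#' and transcript spans are the min start / max end over their parts.
#'
#' @param exons Tibble with columns `gene_id`, `transcript_id`, `seqid`,
#'   `strand`, `start`, `end`.
#' @param cds Optional tibble with columns `transcript_id`, `start`, `end`
#'   (and optionally `seqid`, `strand`, filled in from the exons if absent).
#' @param name Annotation-set name.
#' @return A [new_annotation()] object.
#' @export
annotation_from_exons <- function(exons, cds = NULL, name = "set") {
  exons <- as_tibble(exons)
  stopifnot(all(c("gene_id", "transcript_id", "seqid", "strand",
                  "start", "end") %in% names(exons)))
  exons <- exons %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  if (nrow(exons) == 0) {
    return(new_annotation(
      name,
      genes = tibble(gene_id = character(), seqid = character(),
                     strand = character(), start = integer(),
                     end = integer()),
      transcripts = tibble(transcript_id = character(),
                           gene_id = character(), seqid = character(),
                           strand = character(), start = integer(),
                           end = integer()),
      exons = empty_feature_tbl()))
  }
  tx <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$seqid, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gn <- tx %>%
    group_by(.data$gene_id, .data$seqid, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  if (is.null(cds)) {
    cds <- empty_feature_tbl()
  } else {
    cds <- as_tibble(cds) %>%
      mutate(start = as.integer(.data$start), end = as.integer(.data$end))
    if (!"seqid" %in% names(cds)) {
      cds <- cds %>%
        left_join(select(tx, "transcript_id", "seqid", "strand"),
                  by = "transcript_id")
    }
  }
  new_annotation(
    name,
    genes = select(gn, "gene_id", "seqid", "strand", "start", "end"),
    transcripts = select(tx, "transcript_id", "gene_id", "seqid", "strand",
                         "start", "end"),
    exons = select(exons, "transcript_id", "seqid", "strand", "start", "end"),
    cds = select(cds, "transcript_id", "seqid", "strand", "start", "end")
  )
}

#' @export
print.txa_annotation <- function(x, ...) {
  cat(sprintf("<txa_annotation> %s: %d gene(s), %d transcript(s), %d exon(s)\n",
              x$name, nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Validate an annotation (and optionally check it against a genome)
#'
#' Checks the structural invariants of the model: unique gene and
#' transcript ids, every transcript anchored to its gene's scaffold and
#' strand, exons sorted and strictly separated by >= 1 bp, CDS contained in
#' exons, spans consistent with parts, and (when `genome` is supplied)
#' every feature inside its scaffold.
#'
#' @param ann A `txa_annotation`.
#' @param genome Optional genome (named `DNAStringSet` or named character
#'   vector of sequences) to check scaffold bounds against.
#' @return `ann`, invisibly; errors describe the first offending feature.
#' @export
validate_annotation <- function(ann, genome = NULL) {
  stopifnot(inherits(ann, "txa_annotation"))
  if (anyDuplicated(ann$genes$gene_id))
    abort("duplicated gene ids in annotation")
  if (anyDuplicated(ann$transcripts$transcript_id))
    abort("duplicated transcript ids in annotation")
  bad <- ann$transcripts %>%
    left_join(ann$genes, by = "gene_id", suffix = c("", ".g")) %>%
    filter(is.na(.data$seqid.g) | .data$seqid != .data$seqid.g |
             .data$strand != .data$strand.g)
  if (nrow(bad) > 0)
    abort(paste0("transcript ", bad$transcript_id[1],
                 " disagrees with (or lacks) its parent gene"))
  orphan <- setdiff(ann$exons$transcript_id, ann$transcripts$transcript_id)
  if (length(orphan) > 0)
    abort(paste0("exon with unknown parent transcript: ", orphan[1]))
  if (any(ann$exons$end < ann$exons$start))
    abort("exon with end < start")
  ov <- ann$exons %>%
    group_by(.data$transcript_id) %>%
    summarise(min_gap = if (n() > 1)
      min(.data$start[-1] - .data$end[-n()]) else NA_integer_,
      .groups = "drop") %>%
    filter(!is.na(.data$min_gap), .data$min_gap < 2L)
  if (nrow(ov) > 0)
    abort(paste0("overlapping or abutting exons in transcript ",
                 ov$transcript_id[1]))
  if (nrow(ann$cds) > 0) {
    for (tid in unique(ann$cds$transcript_id)) {
      cd <- filter(ann$cds, .data$transcript_id == tid)
      ex <- filter(ann$exons, .data$transcript_id == tid)
      cov <- interval_bases(cd$start, cd$end)
      exb <- interval_bases(ex$start, ex$end)
      if (!all(cov %in% exb))
        abort(paste0("CDS outside exons in transcript ", tid))
    }
  }
  if (nrow(ann$exons) == 0) return(invisible(ann))
  sp <- ann$exons %>%
    group_by(.data$transcript_id) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    left_join(ann$transcripts, by = "transcript_id", suffix = c("", ".t")) %>%
    filter(.data$start != .data$start.t | .data$end != .data$end.t)
  if (nrow(sp) > 0)
    abort(paste0("transcript span inconsistent with exons: ",
                 sp$transcript_id[1]))
  if (!is.null(genome)) {
    lens <- scaffold_lengths(genome)
    miss <- setdiff(ann$genes$seqid, names(lens))
    if (length(miss) > 0)
      abort(paste0("gene on scaffold absent from genome: ", miss[1]))
    out <- ann$exons %>%
      mutate(len = unname(lens[.data$seqid])) %>%
      filter(.data$start < 1 | .data$end > .data$len)
    if (nrow(out) > 0)
      abort(paste0("exon outside scaffold bounds in transcript ",
                   out$transcript_id[1]))
  }
  invisible(ann)
}

interval_bases <- function(start, end) {
  if (length(start) == 0) return(integer())
  unlist(Map(seq.int, start, end), use.names = FALSE)
}

#' Scaffold lengths of a genome
#'
#' @param genome A named `Biostrings::DNAStringSet` or a named character
#'   vector of DNA sequences.
#' @return Named integer vector of lengths (bp).
#' @export
scaffold_lengths <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    stats::setNames(nchar(genome), names(genome))
  }
}

#' Infer introns from exon chains
#'
#' Introns are the gaps between consecutive exons of a transcript; a
#' transcript with k exons has k - 1 introns, a single-exon transcript has
#' none.
#'
#' @param ann A `txa_annotation`, or a plain exon tibble with
#'   `transcript_id`, `seqid`, `strand`, `start`, `end`.
#' @return Tibble with `transcript_id`, `seqid`, `strand`, `start`, `end`,
#'   one row per intron, sorted by transcript then start.
#' @export
infer_introns <- function(ann) {
  exons <- if (inherits(ann, "txa_annotation")) ann$exons else as_tibble(ann)
  exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id, .data$seqid, .data$strand) %>%
    filter(n() > 1) %>%
    dplyr::reframe(istart = .data$end[-n()] + 1L,
                   iend = .data$start[-1] - 1L) %>%
    select("transcript_id", "seqid", "strand",
           start = "istart", end = "iend")
}

#' Derive UTR intervals from exons and CDS
#'
#' Exonic bases 5' (resp. 3') of the CDS span on the transcript strand.
#' Transcripts without CDS yield no UTRs (orientation of translation is
#' unknown).
#'
#' @param ann A `txa_annotation`.
#' @param side `"utr5"` or `"utr3"`.
#' @return Tibble `transcript_id`, `seqid`, `strand`, `start`, `end`.
#' @export
utr_table <- function(ann, side = c("utr3", "utr5")) {
  side <- match.arg(side)
  if (nrow(ann$cds) == 0) return(empty_feature_tbl())
  cds_span <- ann$cds %>%
    group_by(.data$transcript_id) %>%
    summarise(cstart = min(.data$start), cend = max(.data$end), .groups = "drop")
  ex <- ann$exons %>%
    dplyr::inner_join(cds_span, by = "transcript_id")
  # genomic-left of CDS is utr5 on "+", utr3 on "-"
  left <- ex %>%
    filter(.data$start < .data$cstart) %>%
    mutate(end = pmin(.data$end, .data$cstart - 1L))
  right <- ex %>%
    filter(.data$end > .data$cend) %>%
    mutate(start = pmax(.data$start, .data$cend + 1L))
  pick <- function(tbl, want_plus_side) {
    filter(tbl, (.data$strand == "+") == want_plus_side)
  }
  out <- if (side == "utr5") {
    bind_rows(pick(left, TRUE), pick(right, FALSE))
  } else {
    bind_rows(pick(right, TRUE), pick(left, FALSE))
  }
  out %>%
    select("transcript_id", "seqid", "strand", "start", "end") %>%
    arrange(.data$transcript_id, .data$start)
}

#' Transcript ids carrying an annotated 3' UTR
#' @param ann A `txa_annotation`.
#' @return Character vector of transcript ids.
#' @export
transcripts_with_utr3 <- function(ann) {
  unique(utr_table(ann, "utr3")$transcript_id)
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' for minus-strand transcripts, yielding the mature (5'->3') sequence.
#'
#' @param ann A `txa_annotation`.
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param transcript_id One transcript id.
#' @return A character scalar (DNA, 5'->3').
#' @export
transcript_seq <- function(ann, genome, transcript_id) {
  ex <- filter(ann$exons, .data$transcript_id == !!transcript_id)
  if (nrow(ex) == 0) abort(paste0("unknown transcript: ", transcript_id))
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  sc <- genome[[ex$seqid[1]]]
  parts <- Biostrings::extractAt(sc, IRanges::IRanges(ex$start, ex$end))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (ex$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Per-gene transcript ids
#' @keywords internal
gene_transcripts <- function(ann, gene_id) {
  ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
}

#' Recompute transcript and gene spans from exons
#' @keywords internal
recompute_spans <- function(ann) {
  tx <- ann$exons %>%
    group_by(.data$transcript_id) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  ann$transcripts <- ann$transcripts %>%
    select(-"start", -"end") %>%
    left_join(tx, by = "transcript_id")
  gn <- ann$transcripts %>%
    group_by(.data$gene_id) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  ann$genes <- ann$genes %>%
    select(-"start", -"end") %>%
    left_join(gn, by = "gene_id")
  ann
}
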