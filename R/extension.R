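#' Cluster stranded 3'-end read alignments
#'
#' Single-linkage merge of reads overlapping by >= 1 bp, per scaffold, per
#' strand and per sample (abutting reads do not merge). Clusters with
#' fewer than `min_cluster_reads` reads are discarded — sub-threshold
#' pileups are treated as noise.
#'
#' @param reads Tibble with `seqid`, `start`, `end`, `strand` and
#'   optionally `sample` (default single sample `"s1"`); 1-based closed
#'   coordinates as from [read_bed6()].
#' @param min_cluster_reads Retention threshold (default 10 reads).
#' @return Tibble `seqid`, `start`, `end`, `strand`, `read_count`,
#'   `samples`, `sample`, sorted by (seqid, start).
#' @export
cluster_reads <- function(reads, min_cluster_reads = 10L) {
  reads <- as_tibble(reads)
  if (!"sample" %in% names(reads)) reads$sample <- "s1"
  if (nrow(reads) == 0) return(empty_cluster_tbl())
  out <- reads %>%
    group_by(.data$sample, .data$seqid, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(d$start, d$end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
      tibble(start = IRanges::start(red), end = IRanges::end(red),
             read_count = lengths(S4Vectors::mcols(red)$revmap))
    }) %>%
    ungroup() %>%
    filter(.data$read_count >= min_cluster_reads) %>%
    mutate(samples = .data$sample) %>%
    select("seqid", "start", "end", "strand", "read_count", "samples",
           "sample") %>%
    arrange(.data$seqid, .data$start)
  out
}

empty_cluster_tbl <- function() {
  tibble(seqid = character(), start = integer(), end = integer(),
         strand = character(), read_count = integer(),
         samples = character(), sample = character())
}

#' Merge per-sample tag clusters across samples
#'
#' Same-strand clusters from different samples that overlap by >= 1 bp are
#' union-merged; read counts are summed and sample sets unioned. Inputs
#' are expected to be already per-sample filtered (see [cluster_reads()]),
#' so a merged cluster may exceed any single sample's count.
#'
#' @param clusters Tibble as from [cluster_reads()] (possibly several
#'   samples row-bound), or a list of such tibbles.
#' @return Tibble `seqid`, `start`, `end`, `strand`, `read_count`,
#'   `samples` (comma-joined sorted sample ids), sorted by (seqid, start).
#' @export
merge_sample_clusters <- function(clusters) {
  if (is.list(clusters) && !is.data.frame(clusters))
    clusters <- bind_rows(clusters)
  if (nrow(clusters) == 0)
    return(select(empty_cluster_tbl(), -"sample"))
  clusters %>%
    group_by(.data$seqid, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(d$start, d$end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
      rv <- S4Vectors::mcols(red)$revmap
      tibble(
        start = IRanges::start(red), end = IRanges::end(red),
        read_count = vapply(rv, function(i) sum(d$read_count[i]), integer(1)),
        samples = vapply(rv, function(i)
          paste(sort(unique(unlist(strsplit(d$samples[i], ",")))),
                collapse = ","), character(1)))
    }) %>%
    ungroup() %>%
    select("seqid", "start", "end", "strand", "read_count", "samples") %>%
    arrange(.data$seqid, .data$start)
}

#' Extend transcript 3' ends supported by tag clusters
#'
#' For every transcript with an annotated 3' UTR, same-strand clusters
#' overlapping its last exon by at least `min_overlap_bp` are collected;
#' if a cluster's far boundary (end on "+", start on "-") lies beyond the
#' annotated 3' end, the transcript 3' end (last exon and hence the
#' derived 3' UTR) is moved out to the farthest such boundary. 5' ends,
#' internal exons and CDS are untouched; gene spans are recomputed.
#' Boundaries past the scaffold end are clamped with a warning.
#'
#' @param ann A `txa_annotation`.
#' @param clusters Merged cluster tibble (see [merge_sample_clusters()]).
#' @param min_overlap_bp Minimum last-exon overlap (default 10 bp).
#' @param require_annotated_utr3 Only transcripts with a derived 3' UTR
#'   are eligible (default TRUE, the published rule).
#' @param genome Optional genome for scaffold-end clamping.
#' @return Object of class `txa_extension`: list with `annotation` (the
#'   extended model) and `report` (tibble `gene_id`, `transcript_id`,
#'   `old_end`, `new_end`, `delta`; one row per extended transcript,
#'   coordinates being the genomic 3'-terminal base). `tidy()` returns the
#'   report, `glance()` the totals.
#' @export
extend_three_prime <- function(ann, clusters, min_overlap_bp = 10L,
                               require_annotated_utr3 = TRUE,
                               genome = NULL) {
  eligible <- if (require_annotated_utr3)
    transcripts_with_utr3(ann) else ann$transcripts$transcript_id
  lens <- if (!is.null(genome)) scaffold_lengths(genome) else NULL
  rep_rows <- list()
  exons <- ann$exons
  for (tid in eligible) {
    idx <- which(exons$transcript_id == tid)
    ex <- exons[idx, ]
    plus <- ex$strand[1] == "+"
    li <- idx[if (plus) which.max(ex$end) else which.min(ex$start)]
    last <- exons[li, ]
    cl <- clusters %>%
      filter(.data$seqid == last$seqid, .data$strand == last$strand,
             pmin(.data$end, last$end) - pmax(.data$start, last$start) + 1L >=
               min_overlap_bp)
    if (nrow(cl) == 0) next
    old_end <- if (plus) last$end else last$start
    if (plus) {
      far <- max(cl$end)
      if (far <= old_end) next
      if (!is.null(lens) && far > lens[[last$seqid]]) {
        warn(sprintf("cluster extends past end of %s; clamped", last$seqid))
        far <- lens[[last$seqid]]
        if (far <= old_end) next
      }
      exons$end[li] <- as.integer(far)
    } else {
      far <- min(cl$start)
      if (far >= old_end) next
      if (far < 1L) {
        warn(sprintf("cluster extends past start of %s; clamped", last$seqid))
        far <- 1L
        if (far >= old_end) next
      }
      exons$start[li] <- as.integer(far)
    }
    gid <- ann$transcripts$gene_id[ann$transcripts$transcript_id == tid]
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      gene_id = gid, transcript_id = tid,
      old_end = old_end, new_end = as.integer(far),
      delta = abs(as.integer(far) - old_end))
  }
  ann$exons <- exons
  ann <- recompute_spans(ann)
  report <- if (length(rep_rows) > 0) bind_rows(rep_rows) else
    tibble(gene_id = character(), transcript_id = character(),
           old_end = integer(), new_end = integer(), delta = integer())
  structure(list(annotation = ann, report = report),
            class = "txa_extension")
}

#' @export
print.txa_extension <- function(x, ...) {
  cat(sprintf("<txa_extension> %d transcript(s) extended, total %d bp\n",
              nrow(x$report), sum(x$report$delta)))
  invisible(x)
}

#' @rdname extend_three_prime
#' @param x A `txa_extension`.
#' @param ... Unused.
#' @export
tidy.txa_extension <- function(x, ...) x$report

#' @rdname extend_three_prime
#' @export
glance.txa_extension <- function(x, ...) {
  tibble(n_extended = nrow(x$report),
         total_bp = sum(x$report$delta),
         mean_delta = ifelse(nrow(x$report) > 0, mean(x$report$delta), NA_real_))
}
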