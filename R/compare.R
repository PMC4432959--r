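#' Fraction of a gene covered by another annotation set
#'
#' Computes, for each query gene, the fraction of its bases covered by
#' same-strand bases of any gene in a target set. By default coverage is
#' measured over exonic bases (the transcribed structure); `mode =
#' "span"` uses whole gene spans instead.
#'
#' @param query A `txa_annotation` (or a single gene id with `gene_id`).
#' @param targets A `txa_annotation` to measure coverage against.
#' @param mode `"exon"` (default) or `"span"`.
#' @param stranded Require matching strand (default TRUE).
#' @param gene_id Optional: restrict to these query genes.
#' @return Tibble `gene_id`, `bases`, `covered`, `fraction`.
#' @export
coverage_fraction <- function(query, targets, mode = c("exon", "span"),
                              stranded = TRUE, gene_id = NULL) {
  mode <- match.arg(mode)
  qf <- gene_bases_tbl(query, mode)
  tf <- gene_bases_tbl(targets, mode)
  if (!is.null(gene_id)) qf <- filter(qf, .data$gene_id %in% !!gene_id)
  if (nrow(qf) == 0)
    return(tibble(gene_id = character(), bases = integer(),
                  covered = integer(), fraction = numeric()))
  strand_of <- function(s) if (stranded) s else "*"
  qgr <- GenomicRanges::GRanges(qf$seqid,
                                IRanges::IRanges(qf$start, qf$end),
                                strand = strand_of(qf$strand))
  tgr <- GenomicRanges::GRanges(tf$seqid,
                                IRanges::IRanges(tf$start, tf$end),
                                strand = strand_of(tf$strand))
  tgr <- GenomicRanges::reduce(tgr)
  hits <- GenomicRanges::findOverlaps(qgr, tgr,
                                      ignore.strand = !stranded)
  ovw <- rep(0L, length(qgr))
  if (length(hits) > 0) {
    w <- GenomicRanges::width(IRanges::pintersect(
      qgr[S4Vectors::queryHits(hits)], tgr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ovw[as.integer(names(agg))] <- as.integer(agg)
  }
  qf$covered <- ovw
  qf$bases <- qf$end - qf$start + 1L
  qf %>%
    group_by(.data$gene_id) %>%
    summarise(bases = sum(.data$bases), covered = sum(.data$covered),
              .groups = "drop") %>%
    mutate(fraction = .data$covered / .data$bases)
}

# per-gene disjoint base intervals (merged exons, or the span)
gene_bases_tbl <- function(ann, mode) {
  if (mode == "span")
    return(select(ann$genes, "gene_id", "seqid", "strand", "start", "end"))
  ex <- ann$exons %>%
    left_join(select(ann$transcripts, "transcript_id", "gene_id"),
              by = "transcript_id")
  ex %>%
    group_by(.data$gene_id, .data$seqid, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble(start = IRanges::start(red), end = IRanges::end(red))
    }) %>%
    ungroup()
}

#' Hierarchical assignment of genes to annotation-overlap regions
#'
#' Compares >= 2 annotation sets at a coverage threshold with a fixed
#' precedence order (the first set is the reference). Every reference
#' gene is assigned to the diagram region named by which lower-precedence
#' sets cover it at >= `threshold`; genes of each non-reference set that
#' are *not* covered by any higher-precedence set are assigned, by the
#' same rule, to regions among the remaining lower-precedence sets. Only
#' the reference set therefore keeps its original cardinality.
#'
#' @param sets Named list of `txa_annotation` objects in precedence
#'   order; names default to each set's `name` field.
#' @param threshold Coverage threshold in (0, 1] (default 0.8).
#' @param mode,stranded Passed to [coverage_fraction()].
#' @return Object of class `txa_venn`: list with `regions` (tibble
#'   `region`, `n`; region is `&`-joined set names) and `assignments`
#'   (tibble `set`, `gene_id`, `region`). `tidy()` returns `regions`.
#' @export
hierarchical_assign <- function(sets, threshold = 0.8,
                                mode = c("exon", "span"), stranded = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 2, threshold > 0, threshold <= 1)
  nms <- names(sets) %||% vapply(sets, function(s) s$name, character(1))
  if (is.null(names(sets))) names(sets) <- nms
  k <- length(sets)
  covered_by <- function(i, j) {
    # gene ids of set i covered >= threshold by set j
    cf <- coverage_fraction(sets[[i]], sets[[j]], mode = mode,
                            stranded = stranded)
    cf$gene_id[cf$fraction >= threshold]
  }
  cov <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    cov[[paste(i, j)]] <- covered_by(i, j)
  assign_rows <- list()
  for (i in seq_len(k)) {
    gid <- sets[[i]]$genes$gene_id
    if (i > 1) {
      higher <- unique(unlist(lapply(seq_len(i - 1), function(j)
        cov[[paste(i, j)]])))
      gid <- setdiff(gid, higher)
    }
    lower <- if (i < k) (i + 1L):k else integer()
    memb <- vapply(gid, function(g) {
      inset <- nms[c(i, lower[vapply(lower, function(j)
        g %in% cov[[paste(i, j)]], logical(1))])]
      paste(inset, collapse = "&")
    }, character(1))
    if (length(gid) > 0)
      assign_rows[[i]] <- tibble(set = nms[i], gene_id = gid,
                                 region = unname(memb))
  }
  assignments <- bind_rows(assign_rows)
  regions <- assignments %>%
    dplyr::count(.data$region, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  structure(list(regions = regions, assignments = assignments,
                 precedence = nms, threshold = threshold),
            class = "txa_venn")
}

#' @export
print.txa_venn <- function(x, ...) {
  cat(sprintf("<txa_venn> precedence: %s (threshold %.2f)\n",
              paste(x$precedence, collapse = " > "), x$threshold))
  print(x$regions)
  invisible(x)
}

#' @rdname hierarchical_assign
#' @param x A `txa_venn`.
#' @param ... Unused.
#' @export
tidy.txa_venn <- function(x, ...) x$regions

#' Many-to-one gene correspondences between two sets
#'
#' Reports, for each query gene covered at >= `threshold` by the target
#' set, the target genes overlapping it, so fragmented or merged loci can
#' be inspected without double-counting them in overlap regions.
#'
#' @param query,targets `txa_annotation` objects.
#' @param threshold Coverage threshold (default 0.8).
#' @param stranded Same-strand overlap only (default TRUE).
#' @return Tibble `query_gene`, `target_genes` (comma-joined), `n_targets`.
#' @export
gene_correspondence <- function(query, targets, threshold = 0.8,
                                stranded = TRUE) {
  cf <- coverage_fraction(query, targets)
  keep <- cf$gene_id[cf$fraction >= threshold]
  qg <- filter(query$genes, .data$gene_id %in% keep)
  if (nrow(qg) == 0)
    return(tibble(query_gene = character(), target_genes = character(),
                  n_targets = integer()))
  qgr <- GenomicRanges::GRanges(qg$seqid, IRanges::IRanges(qg$start, qg$end),
                                strand = if (stranded) qg$strand else "*")
  tg <- targets$genes
  tgr <- GenomicRanges::GRanges(tg$seqid, IRanges::IRanges(tg$start, tg$end),
                                strand = if (stranded) tg$strand else "*")
  hits <- GenomicRanges::findOverlaps(qgr, tgr, ignore.strand = !stranded)
  purrr::map_dfr(seq_len(nrow(qg)), function(i) {
    tids <- tg$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    tibble(query_gene = qg$gene_id[i],
           target_genes = paste(sort(tids), collapse = ","),
           n_targets = length(tids))
  })
}

#' Gene-structure statistics of an annotation set
#'
#' Computes the standard descriptive statistics of a gene annotation:
#' gene counts and span lengths (introns included), genome coverage
#' (union of gene spans over total genome length), isoform/exon/intron
#' counts and lengths, longest-ORF statistics over representative
#' isoforms (when a genome is supplied), UTR counts and lengths, and the
#' median intergenic distance.
#'
#' Exon and intron counts are over distinct intervals per gene (identical
#' exons shared by isoforms count once).
#'
#' @param ann A `txa_annotation`.
#' @param genome Named `DNAStringSet`; enables genome-coverage and ORF
#'   statistics (otherwise reported as `NA`).
#' @param min_orf_len Passed to [find_longest_orf()].
#' @return Object of class `txa_structure_stats`; `tidy()` returns a
#'   two-column tibble (`metric`, `value`).
#' @export
structure_stats <- function(ann, genome = NULL, min_orf_len = 30L) {
  gn <- ann$genes
  glen <- gn$end - gn$start + 1L
  ex <- ann$exons %>%
    left_join(select(ann$transcripts, "transcript_id", "gene_id"),
              by = "transcript_id")
  dex <- distinct(ex, .data$gene_id, .data$seqid, .data$start, .data$end)
  introns <- infer_introns(ann) %>%
    left_join(select(ann$transcripts, "transcript_id", "gene_id"),
              by = "transcript_id")
  dint <- distinct(introns, .data$gene_id, .data$seqid, .data$start,
                   .data$end)
  exons_per_gene <- dex %>% dplyr::count(.data$gene_id)
  u5 <- utr_table(ann, "utr5") %>%
    group_by(.data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  u3 <- utr_table(ann, "utr3") %>%
    group_by(.data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  genome_len <- if (!is.null(genome)) sum(scaffold_lengths(genome)) else NA
  union_span <- if (nrow(gn) > 0) {
    sum(GenomicRanges::width(GenomicRanges::reduce(
      GenomicRanges::GRanges(gn$seqid, IRanges::IRanges(gn$start, gn$end)),
      ignore.strand = TRUE)))
  } else 0L
  orf <- NULL
  if (!is.null(genome) && nrow(gn) > 0) {
    reps <- select_representative(ann, genome, min_len = min_orf_len)
    orf <- reps$orf_length[reps$orf_length > 0]
  }
  igd <- intergenic_distances(ann)
  val <- function(x, f) if (length(x) > 0) f(x) else NA_real_
  stats <- list(
    n_genes = nrow(gn),
    total_gene_length = union_span,
    pct_genome = if (!is.na(genome_len)) 100 * union_span / genome_len
    else NA_real_,
    mean_gene_length = val(glen, mean),
    min_gene_length = val(glen, min),
    max_gene_length = val(glen, max),
    n_isoforms = nrow(ann$transcripts),
    n_exons = nrow(dex),
    mean_exon_length = val(dex$end - dex$start + 1L, mean),
    mean_exons_per_gene = if (nrow(gn) > 0) nrow(dex) / nrow(gn)
    else NA_real_,
    max_exons_per_gene = val(exons_per_gene$n, max),
    n_introns = nrow(dint),
    mean_intron_length = val(dint$end - dint$start + 1L, mean),
    orf_total_length = if (!is.null(orf)) sum(orf) else NA_real_,
    orf_mean_length = if (!is.null(orf)) val(orf, mean) else NA_real_,
    orf_max_length = if (!is.null(orf)) val(orf, max) else NA_real_,
    n_utr5 = nrow(u5), utr5_total_length = sum(u5$len),
    utr5_mean_length = val(u5$len, mean), utr5_max_length = val(u5$len, max),
    n_utr3 = nrow(u3), utr3_total_length = sum(u3$len),
    utr3_mean_length = val(u3$len, mean), utr3_max_length = val(u3$len, max),
    median_intergenic = igd$median
  )
  structure(list(stats = stats, name = ann$name),
            class = "txa_structure_stats")
}

#' @export
print.txa_structure_stats <- function(x, ...) {
  cat(sprintf("<txa_structure_stats> %s\n", x$name))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname structure_stats
#' @param x A `txa_structure_stats`.
#' @param ... Unused.
#' @export
tidy.txa_structure_stats <- function(x, ...) {
  tibble(metric = names(x$stats),
         value = vapply(x$stats, as.numeric, numeric(1)))
}

#' Intergenic distances within an annotation
#'
#' Per scaffold, genes are sorted by span start irrespective of strand
#' and the gap between consecutive gene spans is reported (0 for
#' overlapping or abutting genes). Scaffolds with fewer than two genes
#' contribute no distances; with no distances at all the median is `NA`.
#'
#' @param ann A `txa_annotation`.
#' @return List with `distances` (tibble `seqid`, `upstream_gene`,
#'   `downstream_gene`, `distance`) and `median` (bp, `NA` if undefined).
#' @export
intergenic_distances <- function(ann) {
  d <- ann$genes %>%
    arrange(.data$seqid, .data$start, .data$end) %>%
    group_by(.data$seqid) %>%
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      if (n < 2)
        return(tibble(upstream_gene = character(),
                      downstream_gene = character(), distance = integer()))
      tibble(upstream_gene = g$gene_id[-n],
             downstream_gene = g$gene_id[-1],
             distance = pmax(0L, g$start[-1] - g$end[-n] - 1L))
    }) %>%
    ungroup()
  list(distances = d,
       median = if (nrow(d) > 0) stats::median(d$distance) else NA_real_)
}
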