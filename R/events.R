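#' @rdname summarize_events
#' @format NULL
#' @export
AS_CLASSES <- c("IntRt", "AltTEx", "AltAc", "AltDo", "ExSk", "IntSt", "IntEnd")

#' Classify alternative-splicing differences between two isoforms
#'
#' Compares an alternative isoform against the canonical isoform of the
#' same gene and emits one event per detected structural difference,
#' labelled with one of seven classes. Definitions (all strand-aware;
#' "donor" is the intron boundary nearer the transcript 5' end):
#'
#' * **IntRt** (intron retention): a canonical intron every base of which
#'   is exonic in the alternative isoform, the covering exon also
#'   overlapping both flanking canonical exons. Footprint: the intron.
#' * **ExSk** (exon skipping): a canonical internal exon entirely inside
#'   one alternative intron whose outer splice sites match the flanking
#'   canonical introns' outer sites. Footprint: the skipped exon.
#' * **AltAc** / **AltDo**: an alternative intron sharing its donor
#'   (resp. acceptor) with a canonical intron but not the other boundary,
#'   with the exons distal to the differing boundary overlapping between
#'   isoforms (otherwise the difference is a terminal-exon event).
#'   Footprint: the alternative intron.
#' * **AltTEx** (alternative terminal exon): the alternative isoform's
#'   first or last exon overlaps neither the corresponding canonical
#'   terminal exon nor lies inside a canonical intron, while >= 1 intron
#'   is shared exactly. Footprint: the alternative terminal exon.
#' * **IntSt** / **IntEnd**: the alternative transcript's start (resp.
#'   end), in transcript orientation, lies strictly inside a canonical
#'   intron. Footprint: that canonical intron.
#'
#' A single difference never yields two labels: exon-skipping introns are
#' excluded from donor/acceptor comparison, and termini inside canonical
#' introns are excluded from AltTEx, enforcing the precedence
#' IntRt > ExSk > AltAc/AltDo > AltTEx > IntSt/IntEnd.
#'
#' @param canonical,alternative Exon tibbles (`seqid`, `strand`, `start`,
#'   `end`) of the two isoforms, or transcript ids together with `ann`.
#' @param ann Optional `txa_annotation` to resolve transcript ids.
#' @return Tibble `class`, `seqid`, `strand`, `start`, `end` (the event
#'   footprint), zero rows when the chains are structurally identical.
#' @export
pairwise_events <- function(canonical, alternative, ann = NULL) {
  if (is.character(canonical)) {
    stopifnot(!is.null(ann))
    canonical <- filter(ann$exons, .data$transcript_id == !!canonical)
    alternative <- filter(ann$exons, .data$transcript_id == !!alternative)
  }
  can <- arrange(as_tibble(canonical), .data$start)
  alt <- arrange(as_tibble(alternative), .data$start)
  if (can$strand[1] != alt$strand[1] || can$seqid[1] != alt$seqid[1])
    abort("isoforms must share scaffold and strand")
  strand <- can$strand[1]
  seqid <- can$seqid[1]
  can_in <- exon_gaps(can)
  alt_in <- exon_gaps(alt)
  ev <- list()
  emit <- function(class, start, end) {
    ev[[length(ev) + 1L]] <<- tibble(class = class, seqid = seqid,
                                     strand = strand,
                                     start = as.integer(start),
                                     end = as.integer(end))
  }
  ikey <- function(x) paste(x$start, x$end)
  shared_introns <- intersect(ikey(can_in), ikey(alt_in))

  # IntRt: canonical intron fully exonic in alt, flanks shared
  if (nrow(can_in) > 0) {
    for (i in seq_len(nrow(can_in))) {
      hit <- any(alt$start <= can_in$start[i] - 1L &
                   alt$end >= can_in$end[i] + 1L)
      if (hit) emit("IntRt", can_in$start[i], can_in$end[i])
    }
  }

  # ExSk: canonical internal exon inside an alt intron with matched outer sites
  exsk_introns <- character()
  n_can <- nrow(can)
  if (n_can >= 3 && nrow(alt_in) > 0) {
    for (j in 2:(n_can - 1)) {
      li <- can_in[j - 1, ]   # intron left of exon j
      ri <- can_in[j, ]       # intron right of exon j
      k <- which(alt_in$start == li$start & alt_in$end == ri$end)
      if (length(k) > 0) {
        emit("ExSk", can$start[j], can$end[j])
        exsk_introns <- c(exsk_introns, ikey(alt_in[k[1], ]))
      }
    }
  }

  # AltAc / AltDo: alt intron sharing exactly one boundary with a canonical
  # intron; the differing-side exons must overlap
  overlaps <- function(a_start, a_end, b_start, b_end)
    min(a_end, b_end) >= max(a_start, b_start)
  if (nrow(alt_in) > 0 && nrow(can_in) > 0) {
    for (a in seq_len(nrow(alt_in))) {
      key <- ikey(alt_in[a, ])
      if (key %in% shared_introns || key %in% exsk_introns) next
      for (c in seq_len(nrow(can_in))) {
        same_left <- alt_in$start[a] == can_in$start[c]
        same_right <- alt_in$end[a] == can_in$end[c]
        if (same_left == same_right) next  # exact handled; neither shared
        # exon to the genomic right/left of each intron
        if (same_left) {
          ok <- overlaps(alt$start[a + 1L], alt$end[a + 1L],
                         can$start[c + 1L], can$end[c + 1L])
          cls <- if (strand == "+") "AltAc" else "AltDo"
        } else {
          ok <- overlaps(alt$start[a], alt$end[a],
                         can$start[c], can$end[c])
          cls <- if (strand == "+") "AltDo" else "AltAc"
        }
        if (ok) emit(cls, alt_in$start[a], alt_in$end[a])
      }
    }
  }

  # transcript-orientation termini
  plus <- strand == "+"
  alt_first <- if (plus) alt[1, ] else alt[nrow(alt), ]
  alt_last <- if (plus) alt[nrow(alt), ] else alt[1, ]
  can_first <- if (plus) can[1, ] else can[nrow(can), ]
  can_last <- if (plus) can[nrow(can), ] else can[1, ]
  alt_start_pos <- if (plus) alt$start[1] else alt$end[nrow(alt)]
  alt_end_pos <- if (plus) alt$end[nrow(alt)] else alt$start[1]
  in_intron <- function(pos) {
    if (nrow(can_in) == 0) return(integer())
    which(can_in$start <= pos & pos <= can_in$end)
  }
  start_intron <- in_intron(alt_start_pos)
  end_intron <- in_intron(alt_end_pos)

  # AltTEx: terminal exon overlapping neither the canonical terminal exon
  # nor a canonical intron interior, with >= 1 exactly shared intron
  if (length(shared_introns) > 0) {
    if (!overlaps(alt_first$start, alt_first$end,
                  can_first$start, can_first$end) &&
        length(start_intron) == 0)
      emit("AltTEx", alt_first$start, alt_first$end)
    if (!overlaps(alt_last$start, alt_last$end,
                  can_last$start, can_last$end) &&
        length(end_intron) == 0)
      emit("AltTEx", alt_last$start, alt_last$end)
  }

  # IntSt / IntEnd: terminus strictly inside a canonical intron
  if (length(start_intron) > 0)
    emit("IntSt", can_in$start[start_intron[1]], can_in$end[start_intron[1]])
  if (length(end_intron) > 0)
    emit("IntEnd", can_in$start[end_intron[1]], can_in$end[end_intron[1]])

  if (length(ev) == 0)
    return(tibble(class = character(), seqid = character(),
                  strand = character(), start = integer(), end = integer()))
  distinct(bind_rows(ev))
}

# gaps between consecutive sorted exons (the introns), plain tibble
exon_gaps <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(tibble(start = integer(), end = integer()))
  tibble(start = ex$end[-n] + 1L, end = ex$start[-1] - 1L)
}

#' Classify alternative-splicing events within a gene
#'
#' Runs [pairwise_events()] between the canonical isoform and every other
#' isoform of the gene; events with identical (class, footprint) are
#' merged and their supporting transcript sets unioned. Support counts
#' transcripts exhibiting the *alternative* form; `reference` lists the
#' compared isoforms not supporting the event (the canonical form).
#'
#' @param ann A `txa_annotation`.
#' @param gene_id Gene to classify.
#' @param canonical Canonical transcript id; when `NULL` it is chosen as
#'   the isoform with the longest ORF via [select_representative()]
#'   (requires `genome`).
#' @param genome Genome sequence, needed only when `canonical` is `NULL`.
#' @return Tibble `gene_id`, `class`, `seqid`, `strand`, `start`, `end`,
#'   `n_support`, `supporting`, `reference`, `canonical_id` (supporting /
#'   reference are comma-joined sorted transcript ids).
#' @export
classify_gene <- function(ann, gene_id, canonical = NULL, genome = NULL) {
  tids <- gene_transcripts(ann, gene_id)
  if (length(tids) < 2) return(empty_event_tbl())
  if (is.null(canonical)) {
    canonical <- select_representative(ann, genome,
                                       gene_ids = gene_id)$transcript_id
  }
  stopifnot(canonical %in% tids)
  can_ex <- filter(ann$exons, .data$transcript_id == canonical)
  others <- setdiff(tids, canonical)
  per <- purrr::map_dfr(others, function(tid) {
    alt_ex <- filter(ann$exons, .data$transcript_id == tid)
    ev <- pairwise_events(can_ex, alt_ex)
    if (nrow(ev) > 0) ev$supporter <- tid
    ev
  })
  if (nrow(per) == 0) return(empty_event_tbl())
  per %>%
    group_by(.data$class, .data$seqid, .data$strand, .data$start,
             .data$end) %>%
    summarise(n_support = dplyr::n_distinct(.data$supporter),
              supporting = paste(sort(unique(.data$supporter)),
                                 collapse = ","),
              .groups = "drop") %>%
    mutate(gene_id = gene_id, canonical_id = canonical,
           reference = purrr::map_chr(.data$supporting, function(s)
             paste(sort(setdiff(others, strsplit(s, ",")[[1]])),
                   collapse = ","))) %>%
    select("gene_id", "class", "seqid", "strand", "start", "end",
           "n_support", "supporting", "reference", "canonical_id") %>%
    arrange(.data$start, .data$class)
}

empty_event_tbl <- function() {
  tibble(gene_id = character(), class = character(), seqid = character(),
         strand = character(), start = integer(), end = integer(),
         n_support = integer(), supporting = character(),
         reference = character(), canonical_id = character())
}

#' Classify alternative splicing across a whole annotation
#'
#' @param ann A `txa_annotation`.
#' @param genome Genome sequence (used to pick each gene's canonical
#'   isoform by longest ORF) unless `canonical_map` is given.
#' @param canonical_map Optional tibble `gene_id`, `transcript_id` naming
#'   each gene's canonical isoform.
#' @return Event tibble as in [classify_gene()], all multi-isoform genes
#'   concatenated.
#' @export
classify_annotation <- function(ann, genome = NULL, canonical_map = NULL) {
  multi <- ann$transcripts %>%
    dplyr::count(.data$gene_id) %>%
    filter(.data$n > 1) %>%
    pull(.data$gene_id)
  purrr::map_dfr(multi, function(g) {
    canon <- if (!is.null(canonical_map))
      canonical_map$transcript_id[canonical_map$gene_id == g][1] else NULL
    classify_gene(ann, g, canonical = canon, genome = genome)
  }) %>%
    {
      if (nrow(.) == 0) empty_event_tbl() else .
    }
}

#' Filter events by transcript support
#'
#' Events supported by fewer than `min_support` transcripts are treated
#' as lowly supported and removed; row order is preserved.
#'
#' @param events Event tibble (see [classify_gene()]).
#' @param min_support Minimum supporting-transcript count (default 3).
#' @return Filtered event tibble.
#' @export
filter_events <- function(events, min_support = 3L) {
  stopifnot(min_support >= 1)
  filter(events, .data$n_support >= min_support)
}

#' Summarise alternative-splicing events per class
#'
#' Produces the per-class summary: event count, transcript count, % of AS
#' events, % of AS transcripts, and % of all transcripts, percentages
#' rounded to one decimal. Accepts either an event tibble (from
#' [classify_annotation()], typically after [filter_events()]) or a
#' pre-aggregated count table with columns `class`, `n_events`,
#' `n_transcripts`. With pre-aggregated counts the distinct-AS-transcript
#' denominator cannot be derived, so `% of AS transcripts` is `NA` unless
#' `as_transcript_total` is supplied.
#'
#' @param x Event tibble or per-class count tibble.
#' @param total_transcripts Total transcripts in the annotation
#'   (denominator of `% of all transcripts`).
#' @param as_transcript_total Optional count of distinct alternatively
#'   spliced transcripts (denominator of `% of AS transcripts`).
#' @return Object of class `txa_as_summary`; `tidy()` returns the
#'   per-class tibble, `glance()` the totals.
#' @export
summarize_events <- function(x, total_transcripts,
                             as_transcript_total = NULL) {
  if (all(c("class", "n_events", "n_transcripts") %in% names(x))) {
    counts <- as_tibble(x)
    as_total <- as_transcript_total
  } else {
    supporters <- function(ev) unique(unlist(strsplit(ev$supporting, ",")))
    counts <- x %>%
      group_by(.data$class) %>%
      summarise(n_events = n(),
                n_transcripts = dplyr::n_distinct(
                  unlist(strsplit(.data$supporting, ","))),
                .groups = "drop")
    as_total <- as_transcript_total %||% length(supporters(x))
  }
  counts <- tibble(class = AS_CLASSES) %>%
    left_join(counts, by = "class") %>%
    mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
           n_transcripts = dplyr::coalesce(.data$n_transcripts, 0L))
  tot_ev <- sum(counts$n_events)
  pct <- function(num, den) {
    if (is.null(den) || length(den) == 0 || is.na(den) || den == 0)
      return(rep(NA_real_, length(num)))
    round(100 * num / den, 1)
  }
  out <- counts %>%
    mutate(pct_events = if (tot_ev == 0) 0 else pct(.data$n_events, tot_ev),
           pct_as_transcripts = pct(.data$n_transcripts, as_total),
           pct_all_transcripts = pct(.data$n_transcripts, total_transcripts))
  structure(list(classes = out,
                 total_transcripts = total_transcripts,
                 as_transcript_total = as_total,
                 total_events = tot_ev),
            class = "txa_as_summary")
}

#' @export
print.txa_as_summary <- function(x, ...) {
  cat(sprintf("<txa_as_summary> %d event(s) across %d class(es)\n",
              x$total_events, sum(x$classes$n_events > 0)))
  print(x$classes)
  invisible(x)
}

#' @rdname summarize_events
#' @param ... Unused.
#' @export
tidy.txa_as_summary <- function(x, ...) x$classes

#' @rdname summarize_events
#' @export
glance.txa_as_summary <- function(x, ...) {
  tibble(total_events = x$total_events,
         total_transcripts = x$total_transcripts,
         as_transcript_total = x$as_transcript_total %||% NA_integer_,
         pct_as_of_all = if (!is.null(x$as_transcript_total) &&
                             !is.na(x$total_transcripts))
           round(100 * x$as_transcript_total / x$total_transcripts, 1)
         else NA_real_)
}
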