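#' Find the longest open reading frame in a sequence
#'
#' Scans the sense strand (all three frames) for ATG..stop reading frames
#' and returns the longest; ties are broken by the smallest start
#' position. Lengths include the stop codon. With
#' `allow_open_threeprime = TRUE`, an ATG with no downstream in-frame stop
#' is accepted as an "open 3'" ORF running to the last complete codon;
#' the default rejects such ORFs.
#'
#' @param sequence DNA string (ACGTN; N never matches ATG or stop).
#' @param min_len Minimum ORF length in bp (multiple of 3 recommended).
#' @param allow_open_threeprime Accept ORFs lacking an in-sequence stop.
#' @param both_strands Also scan the reverse complement (six-frame mode);
#'   positions on the minus strand are reported in the coordinates of the
#'   reverse-complemented sequence, with `strand = "-"`.
#' @return One-row tibble `frame`, `start`, `end`, `length`, `strand`
#'   (1-based positions in the input sequence), or a zero-row tibble when
#'   no ORF passes `min_len`.
#' @export
find_longest_orf <- function(sequence, min_len = 30L,
                             allow_open_threeprime = FALSE,
                             both_strands = FALSE) {
  empty <- tibble(frame = integer(), start = integer(), end = integer(),
                  length = integer(), strand = character())
  cand <- orf_candidates(sequence, allow_open_threeprime)
  cand$strand <- rep("+", nrow(cand))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    cand2 <- orf_candidates(rc, allow_open_threeprime)
    if (nrow(cand2) > 0) cand2$strand <- "-"
    cand <- bind_rows(cand, cand2)
  }
  cand <- filter(cand, .data$length >= min_len)
  if (nrow(cand) == 0) return(empty)
  cand %>%
    arrange(dplyr::desc(.data$length), .data$start) %>%
    slice(1)
}

# maximal ATG..stop ORFs: per in-frame stop, the earliest ATG after the
# previous stop (any later ATG gives a strictly shorter ORF)
orf_candidates <- function(sequence, allow_open_threeprime) {
  n <- nchar(sequence)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  if (n >= 3) {
    for (f in 0:2) {
      st <- seq.int(1L + f, n - 2L, by = 3L)
      cods <- substring(sequence, st, st + 2L)
      is_stop <- cods %in% stops
      is_atg <- cods == "ATG"
      if (!any(is_atg)) next
      seg <- cumsum(is_stop)          # segment id after each codon
      atg_i <- which(is_atg)
      atg_seg <- seg[atg_i]           # ATG is never a stop: = stops before it
      first_atg <- tapply(atg_i, atg_seg, min)
      stop_i <- which(is_stop)
      if (length(stop_i) > 0) {
        close_seg <- seg[stop_i] - 1L # segment each stop closes
        m <- match(close_seg, as.integer(names(first_atg)))
        ok <- !is.na(m)
        if (any(ok)) {
          s0 <- st[as.integer(first_atg[m[ok]])]
          e0 <- st[stop_i[ok]] + 2L
          out[[length(out) + 1L]] <- tibble(
            frame = f, start = s0, end = e0, length = e0 - s0 + 1L)
        }
      }
      if (allow_open_threeprime) {
        # ATGs after the last in-frame stop form the unterminated tail
        open_seg <- seg[length(seg)]
        k <- match(open_seg, as.integer(names(first_atg)))
        if (!is.na(k)) {
          s0 <- st[as.integer(first_atg[k])]
          e0 <- s0 + 3L * ((n - s0 + 1L) %/% 3L) - 1L
          out[[length(out) + 1L]] <- tibble(
            frame = f, start = s0, end = e0, length = e0 - s0 + 1L)
        }
      }
    }
  }
  if (length(out) == 0)
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  length = integer()))
  bind_rows(out)
}

#' Select a gene's representative isoform
#'
#' The representative is the isoform with the longest ORF in its spliced
#' sequence; ties go to the longer transcript, then the lexicographically
#' smallest transcript id. Reducing each gene to this isoform removes
#' isoform redundancy before gene-level statistics.
#'
#' @param ann A `txa_annotation`.
#' @param genome Named `DNAStringSet` (required: ORFs are found on spliced
#'   transcript sequences).
#' @param gene_ids Genes to process; default all.
#' @param min_len Passed to [find_longest_orf()].
#' @return Tibble `gene_id`, `transcript_id`, `orf_length`, `tx_length`.
#' @export
select_representative <- function(ann, genome, gene_ids = NULL,
                                  min_len = 30L) {
  if (missing(genome) || is.null(genome))
    abort("select_representative() needs genome sequence to find ORFs")
  gene_ids <- gene_ids %||% ann$genes$gene_id
  tx <- filter(ann$transcripts, .data$gene_id %in% gene_ids)
  per_tx <- purrr::map2_dfr(tx$transcript_id, tx$gene_id, function(tid, gid) {
    s <- transcript_seq(ann, genome, tid)
    orf <- find_longest_orf(s, min_len = min_len)
    tibble(gene_id = gid, transcript_id = tid,
           orf_length = if (nrow(orf) == 0) 0L else orf$length,
           tx_length = nchar(s))
  })
  per_tx %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$orf_length), dplyr::desc(.data$tx_length),
            .data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
}
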