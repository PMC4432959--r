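#' Motif models: IUPAC consensus or position-weight matrix
#'
#' A motif is either an IUPAC consensus string (e.g. the polyadenylation
#' signal `"AWTAAA"`, W = A or T) or a position-probability matrix with 4
#' rows (A, C, G, T) whose columns sum to 1, scanned as a log-odds PWM
#' against a uniform background with a threshold expressed as a
#' percentage of the maximum attainable score.
#'
#' @param consensus IUPAC consensus string, or `NULL`.
#' @param matrix 4 x w probability matrix (rownames A,C,G,T), or `NULL`.
#' @param name Motif label.
#' @param min_score PWM threshold as `"60%"`-style string or fraction of
#'   the maximum log-odds score (default 0.6).
#' @return Object of class `txa_motif`.
#' @export
motif_model <- function(consensus = NULL, matrix = NULL, name = NULL,
                        min_score = 0.6) {
  if (is.null(consensus) && is.null(matrix))
    abort("motif_model() needs a consensus or a matrix")
  if (!is.null(matrix)) {
    stopifnot(nrow(matrix) == 4)
    rownames(matrix) <- c("A", "C", "G", "T")
    if (any(abs(colSums(matrix) - 1) > 1e-3))
      abort("PWM columns must sum to 1")
  }
  structure(list(consensus = consensus, matrix = matrix,
                 name = name %||% consensus %||% "motif",
                 min_score = min_score),
            class = "txa_motif")
}

#' @export
print.txa_motif <- function(x, ...) {
  cat(sprintf("<txa_motif> %s (%s, width %d)\n", x$name,
              if (is.null(x$matrix)) "consensus" else "PWM",
              motif_width(x)))
  invisible(x)
}

motif_width <- function(motif) {
  if (!is.null(motif$matrix)) ncol(motif$matrix) else nchar(motif$consensus)
}

#' Read motifs from MEME minimal text format
#'
#' Parses the `MOTIF` / `letter-probability matrix` blocks of a MEME
#' minimal-format file into a list of PWM [motif_model()] objects.
#'
#' @param path MEME minimal-format text file.
#' @param min_score PWM threshold passed to [motif_model()].
#' @return Named list of `txa_motif` objects.
#' @export
read_meme <- function(path, min_score = 0.6) {
  lines <- readLines(path)
  heads <- grep("^MOTIF\\s", lines)
  if (length(heads) == 0) abort("no MOTIF blocks found in MEME file")
  out <- list()
  for (h in heads) {
    nm <- strsplit(trimws(lines[h]), "\\s+")[[1]][2]
    lp <- h + which(grepl("^letter-probability matrix",
                          lines[(h + 1):length(lines)]))[1]
    if (is.na(lp)) abort(paste0("motif ", nm, " lacks a probability matrix"))
    w <- suppressWarnings(as.integer(
      sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[lp])))
    rows <- lines[(lp + 1):(lp + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    out[[nm]] <- motif_model(matrix = t(m), name = nm,
                             min_score = min_score)
  }
  out
}

#' Scan a sequence for motif matches
#'
#' Reports every start position (1-based) whose window matches the motif:
#' for an IUPAC consensus, every base must be compatible; for a PWM, the
#' log-odds score must reach the motif's threshold. Overlapping matches
#' are all reported.
#'
#' @param sequence DNA string (ACGTN).
#' @param motif A `txa_motif` (or a bare IUPAC string).
#' @return Integer vector of match start positions, sorted.
#' @export
scan_motif <- function(sequence, motif) {
  if (is.character(motif)) motif <- motif_model(consensus = motif)
  subj <- Biostrings::DNAString(sequence)
  if (!is.null(motif$matrix)) {
    # log-odds against a uniform background, small pseudo-probability
    pwm <- log2((motif$matrix + 1e-4) / 0.25)
    sc <- if (is.character(motif$min_score)) motif$min_score
    else sprintf("%g%%", 100 * motif$min_score)
    hits <- Biostrings::matchPWM(pwm, subj, min.score = sc)
    return(sort(IRanges::start(hits)))
  }
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif$consensus),
                                   subj, fixed = FALSE)
  sort(IRanges::start(hits))
}

#' Strict 3' UTR selection
#'
#' Transcripts with an annotated 3' UTR, lying on scaffolds longer than
#' `min_scaffold_len`, whose 3' UTR overlaps at least one same-strand tag
#' cluster. This is the high-confidence set used for terminal-motif
#' analysis (short scaffolds are excluded to avoid signal depletion from
#' missing flanking sequence).
#'
#' @param ann A `txa_annotation`.
#' @param clusters Cluster tibble (see [merge_sample_clusters()]).
#' @param genome Genome (for scaffold lengths).
#' @param min_scaffold_len Strict inequality threshold (default 50,000).
#' @return Character vector of transcript ids.
#' @export
select_strict_utr3 <- function(ann, clusters, genome,
                               min_scaffold_len = 50000L) {
  lens <- scaffold_lengths(genome)
  u3 <- utr_table(ann, "utr3") %>%
    filter(unname(lens[.data$seqid]) > min_scaffold_len)
  if (nrow(u3) == 0 || nrow(clusters) == 0) return(character())
  hit <- u3 %>%
    left_join(clusters, by = c("seqid", "strand"),
              relationship = "many-to-many") %>%
    filter(!is.na(.data$start.y),
           pmin(.data$end.x, .data$end.y) >=
             pmax(.data$start.x, .data$start.y))
  sort(unique(hit$transcript_id))
}

#' Strict TSS selection
#'
#' Transcript start sites on scaffolds longer than `min_scaffold_len`
#' whose promoter window (`promoter_up` bp upstream to `promoter_down` bp
#' downstream of the TSS, in transcript orientation, clamped at scaffold
#' edges) overlaps no *other* gene's span.
#'
#' @param ann A `txa_annotation`.
#' @param genome Genome (for scaffold lengths).
#' @param min_scaffold_len Strict inequality threshold (default 50,000).
#' @param promoter_up,promoter_down Promoter window (default 100/50 bp).
#' @return Character vector of transcript ids.
#' @export
select_strict_tss <- function(ann, genome, min_scaffold_len = 50000L,
                              promoter_up = 100L, promoter_down = 50L) {
  lens <- scaffold_lengths(genome)
  tx <- ann$transcripts %>%
    filter(unname(lens[.data$seqid]) > min_scaffold_len)
  if (nrow(tx) == 0) return(character())
  tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  pstart <- ifelse(tx$strand == "+", tss - promoter_up, tss - promoter_down)
  pend <- ifelse(tx$strand == "+", tss + promoter_down, tss + promoter_up)
  pstart <- pmax(1L, as.integer(pstart))
  pend <- pmin(as.integer(unname(lens[tx$seqid])), as.integer(pend))
  pg <- GenomicRanges::GRanges(tx$seqid, IRanges::IRanges(pstart, pend))
  gg <- GenomicRanges::GRanges(ann$genes$seqid,
                               IRanges::IRanges(ann$genes$start,
                                                ann$genes$end))
  hits <- GenomicRanges::findOverlaps(pg, gg, ignore.strand = TRUE)
  own <- ann$genes$gene_id[S4Vectors::subjectHits(hits)] ==
    tx$gene_id[S4Vectors::queryHits(hits)]
  bad <- unique(S4Vectors::queryHits(hits)[!own])
  sort(tx$transcript_id[setdiff(seq_len(nrow(tx)), bad)])
}

#' Positional motif profile around transcript anchors
#'
#' For each anchored transcript, extracts the coding-strand sequence of a
#' window centred on its TTS (3' terminus) or TSS (5' terminus), scans
#' the motif, and accumulates match start offsets (transcript
#' orientation; negative = upstream of the anchor) into fixed-width bins.
#' Windows truncated by scaffold edges contribute only to the bins they
#' fully cover, so each bin's frequency is hits per contributing
#' sequence.
#'
#' @param ann A `txa_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param motif A `txa_motif` or IUPAC string.
#' @param transcript_ids Anchoring transcripts (e.g. a strict set).
#' @param anchor `"tts"` (default) or `"tss"`.
#' @param window Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 20; must divide `window`).
#' @return Object of class `txa_profile`: tibble `bin_start`,
#'   `bin_center`, `n_hits`, `n_seq`, `frequency` plus attributes.
#'   `tidy()` returns the tibble.
#' @export
positional_profile <- function(ann, genome, motif, transcript_ids,
                               anchor = c("tts", "tss"),
                               window = 2000L, bin = 20L) {
  anchor <- match.arg(anchor)
  if (window %% bin != 0) abort("bin must divide window evenly")
  if (is.character(motif)) motif <- motif_model(consensus = motif)
  lens <- scaffold_lengths(genome)
  breaks <- seq(-window, window, by = bin)
  nb <- length(breaks) - 1L
  hits_per_bin <- integer(nb)
  seqs_per_bin <- integer(nb)
  tx <- filter(ann$transcripts, .data$transcript_id %in% transcript_ids)
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    plus <- t$strand == "+"
    apos <- if (anchor == "tts") (if (plus) t$end else t$start)
    else (if (plus) t$start else t$end)
    # available flank in transcript orientation
    up_avail <- if (plus) apos - 1L else unname(lens[t$seqid]) - apos
    dn_avail <- if (plus) unname(lens[t$seqid]) - apos else apos - 1L
    lo <- -min(window, up_avail)
    hi <- min(window, dn_avail)
    gstart <- if (plus) apos + lo else apos - hi
    gend <- if (plus) apos + hi else apos - lo
    s <- Biostrings::extractAt(genome[[t$seqid]],
                               IRanges::IRanges(gstart, gend))[[1]]
    if (!plus) s <- Biostrings::reverseComplement(s)
    pos <- scan_motif(as.character(s), motif)
    # offset of a match start relative to the anchor (anchor at offset 0)
    off <- pos - 1L + lo
    bi <- findInterval(off, breaks, rightmost.closed = TRUE)
    bi <- bi[bi >= 1 & bi <= nb]
    if (length(bi) > 0) {
      tb <- table(bi)
      hits_per_bin[as.integer(names(tb))] <-
        hits_per_bin[as.integer(names(tb))] + as.integer(tb)
    }
    full <- which(breaks[-length(breaks)] >= lo & breaks[-1] <= hi)
    seqs_per_bin[full] <- seqs_per_bin[full] + 1L
  }
  out <- tibble(
    bin_start = breaks[-length(breaks)],
    bin_center = breaks[-length(breaks)] + bin / 2,
    n_hits = hits_per_bin,
    n_seq = seqs_per_bin,
    frequency = ifelse(seqs_per_bin > 0, hits_per_bin / seqs_per_bin, 0)
  )
  structure(out, class = c("txa_profile", class(out)),
            motif = motif$name, anchor = anchor, window = window, bin = bin)
}

#' @rdname positional_profile
#' @param x A `txa_profile`.
#' @param ... Unused.
#' @export
tidy.txa_profile <- function(x, ...) as_tibble(unclass(x)[
  c("bin_start", "bin_center", "n_hits", "n_seq", "frequency")])

#' Cumulative PAS frequency around strict TSSs
#'
#' For offsets 1..`window`, the cumulative per-TSS count of coding-strand
#' PAS matches whose start lies within that many bp upstream (resp.
#' downstream) of the TSS. In genomes where the PAS drives termination,
#' the upstream curve rises faster than the downstream one: PASs are
#' depleted in the direction of transcription.
#'
#' @param ann A `txa_annotation`.
#' @param genome Named `DNAStringSet`.
#' @param transcript_ids Strict TSS transcripts (see
#'   [select_strict_tss()]).
#' @param pas Motif (default the `"AWTAAA"` PAS consensus).
#' @param window Curve extent in bp (default 500).
#' @return Object of class `txa_cumcurve`: tibble `offset`, `upstream`,
#'   `downstream` (cumulative matches per TSS).
#' @export
cumulative_pas <- function(ann, genome, transcript_ids, pas = "AWTAAA",
                           window = 500L) {
  if (is.character(pas)) pas <- motif_model(consensus = pas)
  lens <- scaffold_lengths(genome)
  up_counts <- integer(window)
  dn_counts <- integer(window)
  tx <- filter(ann$transcripts, .data$transcript_id %in% transcript_ids)
  n_tss <- nrow(tx)
  for (i in seq_len(n_tss)) {
    t <- tx[i, ]
    plus <- t$strand == "+"
    apos <- if (plus) t$start else t$end
    up_avail <- if (plus) apos - 1L else unname(lens[t$seqid]) - apos
    dn_avail <- if (plus) unname(lens[t$seqid]) - apos else apos - 1L
    lo <- -min(window, up_avail)
    hi <- min(window, dn_avail)
    gstart <- if (plus) apos + lo else apos - hi
    gend <- if (plus) apos + hi else apos - lo
    s <- Biostrings::extractAt(genome[[t$seqid]],
                               IRanges::IRanges(gstart, gend))[[1]]
    if (!plus) s <- Biostrings::reverseComplement(s)
    off <- scan_motif(as.character(s), pas) - 1L + lo
    for (o in off) {
      if (o < 0 && -o <= window) up_counts[-o] <- up_counts[-o] + 1L
      if (o > 0 && o <= window) dn_counts[o] <- dn_counts[o] + 1L
    }
  }
  out <- tibble(offset = seq_len(window),
                upstream = cumsum(up_counts) / max(n_tss, 1L),
                downstream = cumsum(dn_counts) / max(n_tss, 1L))
  structure(out, class = c("txa_cumcurve", class(out)), n_tss = n_tss)
}

#' @rdname cumulative_pas
#' @param x A `txa_cumcurve`.
#' @param ... Unused.
#' @export
tidy.txa_cumcurve <- function(x, ...) as_tibble(unclass(x)[
  c("offset", "upstream", "downstream")])
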