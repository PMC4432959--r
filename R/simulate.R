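#' Simulation configuration for synthetic gene-dense genomes
#'
#' Defaults emulate a compact, gene-dense genome: median intergenic gap
#' around 0.6 kb, mean intron length around 330 bp, around 5 exons per
#' gene, exon lengths around 220 bp, and most transcripts carrying a
#' 3' UTR. All distributions are log-normal with the stated medians;
#' lengths are clamped to sensible floors so every feature is
#' well-formed.
#'
#' @param seed Integer seed; the generators are pure functions of
#'   (config, seed).
#' @param n_scaffolds,scaffold_len_range Number of scaffolds and their
#'   uniform length range (bp).
#' @param n_genes Total genes to place (packed scaffold by scaffold).
#' @param intergenic_meanlog,intergenic_sdlog Log-normal intergenic gap;
#'   defaults give a median of 587 bp.
#' @param intron_meanlog,intron_sdlog Log-normal intron length; defaults
#'   give a mean of about 327 bp.
#' @param exon_meanlog,exon_sdlog Log-normal exon length (mean ~ 220 bp).
#' @param exon_lambda Poisson parameter; exons per gene = 1 + Pois
#'   (mean 5.2 with the default 4.2).
#' @param utr3_presence_prob Probability a gene's transcript has a 3'
#'   UTR.
#' @param utr5_meanlog,utr3_meanlog,utr_sdlog Log-normal UTR lengths.
#' @return A list of class `txa_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 3L,
                       scaffold_len_range = c(150000L, 250000L),
                       n_genes = 100L,
                       intergenic_meanlog = log(587), intergenic_sdlog = 0.7,
                       intron_meanlog = log(280), intron_sdlog = 0.55,
                       exon_meanlog = log(200), exon_sdlog = 0.45,
                       exon_lambda = 4.2,
                       utr3_presence_prob = 0.8,
                       utr5_meanlog = log(100), utr3_meanlog = log(160),
                       utr_sdlog = 0.45) {
  structure(as.list(environment()), class = "txa_sim_config")
}

rlnorm_clamped <- function(n, meanlog, sdlog, lo, hi) {
  as.integer(pmin(hi, pmax(lo, round(stats::rlnorm(n, meanlog, sdlog)))))
}

# size-safe sampling: never treats a length-1 numeric as 1:n
resample <- function(x, n = 1L, ...) {
  x[sample.int(length(x), n, ...)]
}

#' Generate a synthetic genome with a ground-truth annotation
#'
#' Places non-overlapping single-isoform genes with sampled intergenic
#' gaps on i.i.d. uniform ACGT scaffolds, then writes each gene's coding
#' sequence (ATG, stop-free codons, terminal stop) into its CDS exon
#' positions so the canonical isoform's longest ORF is the designed one.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named `DNAStringSet`), `annotation`
#'   (a `txa_annotation`, one isoform per gene) and `truth` (list of
#'   tibbles: `genes` with designed spans, TSS/TTS and UTR lengths).
#' @export
generate_genome_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "txa_sim_config"))
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  sc_len <- as.integer(round(stats::runif(
    cfg$n_scaffolds, cfg$scaffold_len_range[1], cfg$scaffold_len_range[2])))
  sc_names <- sprintf("scaf%02d", seq_len(cfg$n_scaffolds))
  seqs <- lapply(sc_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  names(seqs) <- sc_names

  exon_rows <- list()
  cds_rows <- list()
  truth_rows <- list()
  placed <- 0L
  si <- 1L
  pos <- 1L + rlnorm_clamped(1, cfg$intergenic_meanlog, cfg$intergenic_sdlog,
                             50, 10000)
  while (placed < cfg$n_genes) {
    n_ex <- 1L + stats::rpois(1, cfg$exon_lambda)
    ex_len <- rlnorm_clamped(n_ex, cfg$exon_meanlog, cfg$exon_sdlog, 50, 1500)
    in_len <- if (n_ex > 1)
      rlnorm_clamped(n_ex - 1, cfg$intron_meanlog, cfg$intron_sdlog, 40, 3000)
    else integer()
    span <- sum(ex_len) + sum(in_len)
    if (si > cfg$n_scaffolds)
      abort(paste0("cannot place ", cfg$n_genes, " genes on ",
                   cfg$n_scaffolds,
                   " scaffolds; increase scaffold_len_range or n_scaffolds",
                   " or reduce n_genes"))
    if (pos + span + 200L > sc_len[si]) {
      si <- si + 1L
      pos <- 1L + rlnorm_clamped(1, cfg$intergenic_meanlog,
                                 cfg$intergenic_sdlog, 50, 10000)
      next
    }
    placed <- placed + 1L
    gid <- sprintf("g%04d", placed)
    tid <- paste0(gid, ".t1")
    strand <- sample(c("+", "-"), 1)
    starts <- pos + cumsum(c(0L, utils::head(ex_len, -1) + in_len))
    ends <- starts + ex_len - 1L
    tx_len <- sum(ex_len)
    # UTR layout in spliced (5'->3') coordinates; always leave >= 33 bp
    # of CDS, trimming UTRs if the transcript is short
    u5 <- rlnorm_clamped(1, cfg$utr5_meanlog, cfg$utr_sdlog, 20, 800)
    u3 <- if (stats::runif(1) < cfg$utr3_presence_prob)
      rlnorm_clamped(1, cfg$utr3_meanlog, cfg$utr_sdlog, 30, 800) else 0L
    first_len <- if (strand == "+") ex_len[1] else ex_len[n_ex]
    last_len <- if (strand == "+") ex_len[n_ex] else ex_len[1]
    u3 <- min(u3, last_len - 10L, max(0L, tx_len - 53L))
    u5 <- max(0L, min(u5, first_len - 10L, tx_len - u3 - 36L))
    cds_len <- tx_len - u5 - u3
    u5 <- u5 + cds_len %% 3L  # keep the CDS a whole number of codons
    cds_len <- tx_len - u5 - u3
    stopifnot(cds_len >= 30L)
    # spliced sequence: random UTRs around a designed stop-free ORF
    n_cod <- cds_len %/% 3L
    safe_codons <- setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA", "ATG"))
    cds_seq <- paste0("ATG",
                      paste(sample(safe_codons, n_cod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1))
    rnd <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")
    # a stop right before the ATG blocks in-frame read-through from any
    # chance ATG in the 5' UTR, so the designed ORF is the longest one
    u5_seq <- if (u5 >= 3) paste0(rnd(u5 - 3L), "TAA") else rnd(u5)
    spliced <- paste0(u5_seq, cds_seq, rnd(u3))
    genomic <- if (strand == "+") spliced else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
    # write exon pieces into the scaffold
    off <- 0L
    s <- seqs[[si]]
    for (e in seq_len(n_ex)) {
      piece <- substr(genomic, off + 1L, off + ex_len[e])
      substr(s, starts[e], ends[e]) <- piece
      off <- off + ex_len[e]
    }
    seqs[[si]] <- s
    # CDS genomic intervals: spliced positions u5+1 .. u5+cds_len
    cds_iv <- spliced_to_genomic(starts, ends, strand, u5 + 1L, u5 + cds_len)
    exon_rows[[placed]] <- tibble(
      gene_id = gid, transcript_id = tid, seqid = sc_names[si],
      strand = strand, start = starts, end = ends)
    cds_rows[[placed]] <- tibble(
      transcript_id = tid, seqid = sc_names[si], strand = strand,
      start = cds_iv$start, end = cds_iv$end)
    truth_rows[[placed]] <- tibble(
      gene_id = gid, transcript_id = tid, seqid = sc_names[si],
      strand = strand, start = starts[1], end = ends[n_ex],
      n_exons = n_ex, tx_length = tx_len, utr5_len = u5, utr3_len = u3,
      cds_len = cds_len,
      tss = if (strand == "+") starts[1] else ends[n_ex],
      tts = if (strand == "+") ends[n_ex] else starts[1])
    pos <- ends[n_ex] + 1L +
      rlnorm_clamped(1, cfg$intergenic_meanlog, cfg$intergenic_sdlog,
                     50, 10000)
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  ann <- if (placed > 0)
    annotation_from_exons(bind_rows(exon_rows), cds = bind_rows(cds_rows),
                          name = "sim")
  else new_annotation("sim",
                      genes = tibble(gene_id = character(),
                                     seqid = character(),
                                     strand = character(),
                                     start = integer(), end = integer()),
                      transcripts = tibble(transcript_id = character(),
                                           gene_id = character(),
                                           seqid = character(),
                                           strand = character(),
                                           start = integer(),
                                           end = integer()),
                      exons = empty_feature_tbl())
  validate_annotation(ann, genome)
  list(genome = genome, annotation = ann,
       truth = list(genes = if (placed > 0) bind_rows(truth_rows)
                    else tibble()),
       config = cfg)
}

# map a contiguous spliced-coordinate interval to genomic intervals
spliced_to_genomic <- function(starts, ends, strand, sp_start, sp_end) {
  widths <- ends - starts + 1L
  n <- length(starts)
  # spliced coordinate runs 5'->3'; on "-" that is genomic right to left
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  res_s <- integer(); res_e <- integer()
  cum <- 0L
  for (e in ord) {
    w <- widths[e]
    lo <- cum + 1L
    hi <- cum + w
    ov_lo <- max(lo, sp_start)
    ov_hi <- min(hi, sp_end)
    if (ov_lo <= ov_hi) {
      if (strand == "+") {
        res_s <- c(res_s, starts[e] + (ov_lo - lo))
        res_e <- c(res_e, starts[e] + (ov_hi - lo))
      } else {
        res_s <- c(res_s, ends[e] - (ov_hi - lo))
        res_e <- c(res_e, ends[e] - (ov_lo - lo))
      }
    }
    cum <- cum + w
  }
  o <- order(res_s)
  list(start = res_s[o], end = res_e[o])
}

#' Add alternative isoforms carrying known splicing events
#'
#' For a configured fraction of genes, adds isoforms differing from the
#' canonical one by exactly one sampled event of a given class, each
#' replicated `n_support` times (identical structure, distinct ids) so
#' that support filtering can be exercised. A fraction of event genes can
#' be given only two supporting isoforms (`low_support_frac`) to test the
#' removal of lowly supported events. Classes infeasible for a gene's
#' exon count are resampled among the feasible ones.
#'
#' @param sim Output of [generate_genome_annotation()] (or a list with
#'   `annotation` and `genome`).
#' @param mix Named per-class event rates over
#'   `r paste(AS_CLASSES, collapse = ", ")`; a gene hosts an event with
#'   probability `sum(mix)` (capped at 1).
#' @param n_support Supporting isoforms per event (default 3).
#' @param low_support_frac Fraction of event genes given only 2
#'   supporters (default 0).
#' @param seed Integer seed.
#' @return List with `annotation` (isoforms added) and `truth` (tibble
#'   `gene_id`, `class`, `seqid`, `strand`, `start`, `end` (footprint),
#'   `isoforms`, `n_isoforms`, `canonical_id`).
#' @export
spawn_isoforms <- function(sim, mix = c(IntRt = 0.25, AltTEx = 0.1,
                                        AltAc = 0.1, AltDo = 0.1,
                                        ExSk = 0.1, IntSt = 0.05,
                                        IntEnd = 0.05),
                           n_support = 3L, low_support_frac = 0,
                           seed = 1L) {
  ann <- sim$annotation
  stopifnot(all(names(mix) %in% AS_CLASSES), all(mix >= 0), all(mix <= 1))
  lens <- if (!is.null(sim$genome)) scaffold_lengths(sim$genome) else NULL
  withr::with_seed(seed,
                   spawn_impl(ann, mix, n_support, low_support_frac, lens,
                              sim$genome))
}

# longest complete ORF of an exon chain's spliced sequence (0 if none)
chain_orf <- function(genome, ex, strand) {
  ex <- ex[order(ex$start), ]
  sc <- genome[[ex$seqid[1]]]
  parts <- Biostrings::extractAt(sc, IRanges::IRanges(ex$start, ex$end))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  o <- find_longest_orf(as.character(s))
  if (nrow(o) == 0) 0L else o$length
}

spawn_impl <- function(ann, mix, n_support, low_support_frac, lens = NULL,
                       genome = NULL) {
  p_event <- min(1, sum(mix))
  truth_rows <- list()
  new_exons <- list()
  new_tx <- list()
  if (p_event > 0 && nrow(ann$genes) > 0) {
    for (gi in seq_len(nrow(ann$genes))) {
      if (stats::runif(1) >= p_event) next
      g <- ann$genes[gi, ]
      tid <- gene_transcripts(ann, g$gene_id)[1]
      ex <- filter(ann$exons, .data$transcript_id == tid) %>%
        arrange(.data$start)
      # room beyond the gene for alternative terminal exons
      same_sc <- filter(ann$genes, .data$seqid == g$seqid,
                        .data$gene_id != g$gene_id)
      sc_end <- if (!is.null(lens)) lens[[g$seqid]] else Inf
      room_right <- min(c(same_sc$start[same_sc$start > g$end],
                          sc_end + 1)) - g$end - 20L
      room_left <- g$start -
        max(c(same_sc$end[same_sc$end < g$start], 0L)) - 20L
      feas <- feasible_classes(ex, g$strand, room_left, room_right)
      cls_pool <- intersect(names(mix)[mix > 0], feas)
      if (length(cls_pool) == 0) next
      w <- mix[cls_pool] / sum(mix[cls_pool])
      cls <- sample(cls_pool, 1, prob = w)
      alt <- build_alt_isoform(ex, g$strand, cls, room_left, room_right)
      if (is.null(alt)) next
      # the canonical isoform must keep the longest ORF (the rule used to
      # pick representatives); structural edits occasionally create a
      # longer chance ORF in the alternative — skip such genes so the
      # canonical identity in the truth table is unambiguous
      if (!is.null(genome)) {
        can_orf <- chain_orf(genome, ex, g$strand)
        alt_orf <- chain_orf(genome, alt$exons, g$strand)
        can_len <- sum(ex$end - ex$start + 1L)
        alt_len <- sum(alt$exons$end - alt$exons$start + 1L)
        if (!(can_orf > alt_orf ||
                (can_orf == alt_orf && can_len > alt_len))) next
      }
      ns <- if (stats::runif(1) < low_support_frac) 2L else
        as.integer(n_support)
      iso_ids <- sprintf("%s.alt%d", g$gene_id, seq_len(ns))
      for (k in seq_len(ns)) {
        new_exons[[length(new_exons) + 1L]] <- tibble(
          transcript_id = iso_ids[k], seqid = g$seqid, strand = g$strand,
          start = alt$exons$start, end = alt$exons$end)
        new_tx[[length(new_tx) + 1L]] <- tibble(
          transcript_id = iso_ids[k], gene_id = g$gene_id,
          seqid = g$seqid, strand = g$strand,
          start = min(alt$exons$start), end = max(alt$exons$end))
      }
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        gene_id = g$gene_id, class = cls, seqid = g$seqid,
        strand = g$strand, start = alt$footprint[1], end = alt$footprint[2],
        isoforms = paste(iso_ids, collapse = ","), n_isoforms = ns,
        canonical_id = tid)
    }
  }
  if (length(new_tx) > 0) {
    ann$transcripts <- bind_rows(ann$transcripts, bind_rows(new_tx))
    ann$exons <- bind_rows(ann$exons, bind_rows(new_exons)) %>%
      arrange(.data$transcript_id, .data$start)
    ann <- recompute_spans(ann)
  }
  truth <- if (length(truth_rows) > 0) bind_rows(truth_rows) else
    tibble(gene_id = character(), class = character(), seqid = character(),
           strand = character(), start = integer(), end = integer(),
           isoforms = character(), n_isoforms = integer(),
           canonical_id = character())
  list(annotation = ann, truth = truth)
}

feasible_classes <- function(ex, strand, room_left, room_right) {
  n <- nrow(ex)
  gaps <- exon_gaps(ex)
  out <- character()
  if (n >= 2) out <- c(out, "IntRt")
  if (n >= 3) out <- c(out, "ExSk")
  if (n >= 2 && any(ex$end - ex$start + 1L > 40)) out <- c(out, "AltAc",
                                                           "AltDo")
  room_3p <- if (strand == "+") room_right else room_left
  if (n >= 3 && room_3p > 220) out <- c(out, "AltTEx")
  if (n >= 2 && nrow(gaps) > 0 && any(gaps$end - gaps$start + 1L > 60))
    out <- c(out, "IntSt", "IntEnd")
  out
}

# construct one alternative exon chain; returns list(exons, footprint)
build_alt_isoform <- function(ex, strand, cls, room_left, room_right) {
  n <- nrow(ex)
  gaps <- exon_gaps(ex)
  d <- 25L
  pick <- function(idx) resample(idx, 1L)
  switch(cls,
    IntRt = {
      # prefer introns whose length is not a codon multiple, so retention
      # frameshifts the ORF and the canonical isoform keeps the longest one
      ilen <- gaps$end - gaps$start + 1L
      cand <- which(ilen %% 3L != 0L)
      if (length(cand) == 0) cand <- seq_len(n - 1)
      i <- pick(cand)
      alt <- ex
      alt$end[i] <- alt$end[i + 1L]
      alt <- alt[-(i + 1L), ]
      list(exons = alt, footprint = c(gaps$start[i], gaps$end[i]))
    },
    ExSk = {
      j <- pick(2:(n - 1))
      list(exons = ex[-j, ], footprint = c(ex$start[j], ex$end[j]))
    },
    AltAc = {
      # shrink the exon distal to the acceptor; acceptor moves into it
      if (strand == "+") {
        ok <- which(ex$end[-1] - ex$start[-1] + 1L > d + 15L)
        if (length(ok) == 0) return(NULL)
        i <- pick(ok)
        alt <- ex
        alt$start[i + 1L] <- alt$start[i + 1L] + d
        list(exons = alt, footprint = c(gaps$start[i], gaps$end[i] + d))
      } else {
        ok <- which(ex$end[-n] - ex$start[-n] + 1L > d + 15L)
        if (length(ok) == 0) return(NULL)
        i <- pick(ok)
        alt <- ex
        alt$end[i] <- alt$end[i] - d
        list(exons = alt, footprint = c(gaps$start[i] - d, gaps$end[i]))
      }
    },
    AltDo = {
      if (strand == "+") {
        ok <- which(ex$end[-n] - ex$start[-n] + 1L > d + 15L)
        if (length(ok) == 0) return(NULL)
        i <- pick(ok)
        alt <- ex
        alt$end[i] <- alt$end[i] - d
        list(exons = alt, footprint = c(gaps$start[i] - d, gaps$end[i]))
      } else {
        ok <- which(ex$end[-1] - ex$start[-1] + 1L > d + 15L)
        if (length(ok) == 0) return(NULL)
        i <- pick(ok)
        alt <- ex
        alt$start[i + 1L] <- alt$start[i + 1L] + d
        list(exons = alt, footprint = c(gaps$start[i], gaps$end[i] + d))
      }
    },
    AltTEx = {
      w <- 120L
      off <- 60L
      if (strand == "+") {
        if (room_right <= off + w + 20L) return(NULL)
        alt <- ex[-n, ]
        newex <- tibble_row_like(ex, ex$end[n] + off, ex$end[n] + off + w - 1L)
        alt <- bind_rows(alt, newex)
        list(exons = alt, footprint = c(newex$start, newex$end))
      } else {
        if (room_left <= off + w + 20L) return(NULL)
        alt <- ex[-1, ]
        newex <- tibble_row_like(ex, ex$start[1] - off - w + 1L,
                                 ex$start[1] - off)
        alt <- bind_rows(newex, alt)
        list(exons = alt, footprint = c(newex$start, newex$end))
      }
    },
    IntSt = {
      if (strand == "+") trunc_left(ex, gaps, d = 40L)
      else trunc_right(ex, gaps, d = 40L)
    },
    IntEnd = {
      if (strand == "+") trunc_right(ex, gaps, d = 40L)
      else trunc_left(ex, gaps, d = 40L)
    },
    abort(paste0("unknown class: ", cls)))
}

tibble_row_like <- function(ex, start, end) {
  tibble(transcript_id = ex$transcript_id[1] %||% NA_character_,
         seqid = ex$seqid[1], strand = ex$strand[1],
         start = as.integer(start), end = as.integer(end))
}

# drop exons up to a long intron, extend the next exon left into it
trunc_left <- function(ex, gaps, d) {
  long <- which(gaps$end - gaps$start + 1L > d + 20L)
  if (length(long) == 0) return(NULL)
  i <- long[1]
  alt <- ex[-seq_len(i), ]
  alt$start[1] <- alt$start[1] - d
  list(exons = alt, footprint = c(gaps$start[i], gaps$end[i]))
}

# drop genomic-last exon, extend the previous one right into the last intron
trunc_right <- function(ex, gaps, d) {
  long <- which(gaps$end - gaps$start + 1L > d + 20L)
  if (length(long) == 0) return(NULL)
  i <- long[length(long)]
  alt <- ex[seq_len(i), ]
  alt$end[i] <- alt$end[i] + d
  list(exons = alt, footprint = c(gaps$start[i], gaps$end[i]))
}

#' Simulate 3'-end read pileups with known true transcript ends
#'
#' For every transcript carrying a 3' UTR, samples an extension beyond
#' the annotated 3' end (capped so the pile stays clear of the next
#' gene), then tiles `reads_per_end` mutually overlapping reads from
#' just inside the last exon out to the true new end, whose far boundary
#' the resulting tag cluster reproduces exactly. Optional noise clusters
#' carry at most `noise_reads_max` reads (below the retention threshold).
#'
#' @param sim Output of [generate_genome_annotation()] (needs
#'   `annotation` and `genome`).
#' @param reads_per_end Reads per true 3' end (default 12).
#' @param read_len Read length (default 50 bp).
#' @param extension_range Uniform integer range of the sampled extension
#'   beyond the annotated end (default 50..150 bp); a length-1 value
#'   fixes it.
#' @param exon_overlap How far the pile reaches into the last exon
#'   (default 30 bp; must stay >= the 10 bp overlap rule).
#' @param noise_clusters Number of sub-threshold noise pileups.
#' @param noise_reads_max Maximum reads per noise pileup (default 9).
#' @param seed Integer seed.
#' @return List with `reads` (BED6-shaped tibble incl. `sample`) and
#'   `truth` (tibble `transcript_id`, `gene_id`, `strand`, `old_end`,
#'   `new_end`; 3'-terminal genomic coordinates).
#' @export
simulate_3prime_tags <- function(sim, reads_per_end = 12L, read_len = 50L,
                                 extension_range = c(50L, 150L),
                                 exon_overlap = 30L, noise_clusters = 20L,
                                 noise_reads_max = 9L, seed = 1L) {
  ann <- sim$annotation
  lens <- scaffold_lengths(sim$genome)
  if (length(extension_range) == 1)
    extension_range <- rep(extension_range, 2)
  withr::with_seed(seed, {
    read_rows <- list()
    truth_rows <- list()
    if (reads_per_end > 0) {
      for (tid in transcripts_with_utr3(ann)) {
        t <- filter(ann$transcripts, .data$transcript_id == tid)
        g <- filter(ann$genes, .data$gene_id == t$gene_id)
        others <- filter(ann$genes, .data$seqid == g$seqid,
                         .data$gene_id != g$gene_id)
        delta <- resample(seq(extension_range[1], extension_range[2]), 1L)
        if (t$strand == "+") {
          lim <- min(c(others$start[others$start > g$end] - 20L,
                       lens[[g$seqid]]))
          new_end <- min(t$end + delta, lim)
          if (new_end - t$end < 10L) next
          pile_lo <- t$end - exon_overlap
          pile_hi <- new_end
          starts <- unique(round(seq(pile_lo, pile_hi - read_len + 1L,
                                     length.out = reads_per_end)))
          starts <- rep(starts, length.out = reads_per_end)
          read_rows[[length(read_rows) + 1L]] <- tibble(
            seqid = g$seqid, start = as.integer(starts),
            end = as.integer(starts + read_len - 1L), strand = "+",
            sample = "s1")
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            transcript_id = tid, gene_id = g$gene_id, strand = "+",
            old_end = t$end, new_end = as.integer(new_end))
        } else {
          lim <- max(c(others$end[others$end < g$start] + 20L, 1L))
          new_end <- max(t$start - delta, lim)
          if (t$start - new_end < 10L) next
          pile_lo <- new_end
          pile_hi <- t$start + exon_overlap
          ends <- unique(round(seq(pile_hi, pile_lo + read_len - 1L,
                                   length.out = reads_per_end)))
          ends <- rep(ends, length.out = reads_per_end)
          read_rows[[length(read_rows) + 1L]] <- tibble(
            seqid = g$seqid, start = as.integer(ends - read_len + 1L),
            end = as.integer(ends), strand = "-", sample = "s1")
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            transcript_id = tid, gene_id = g$gene_id, strand = "-",
            old_end = t$start, new_end = as.integer(new_end))
        }
      }
    }
    if (noise_clusters > 0) {
      # noise pileups are kept clear of genes and their 3' extensions so
      # they never merge with a true pile and shift its far boundary
      for (k in seq_len(noise_clusters)) {
        for (try in 1:50) {
          sc <- resample(names(lens), 1L)
          p <- sample.int(lens[[sc]] - read_len, 1)
          near <- filter(ann$genes, .data$seqid == sc,
                         .data$start - 400L <= p + read_len,
                         .data$end + 400L >= p)
          if (nrow(near) == 0) break
          p <- NA_integer_
        }
        if (is.na(p)) next
        nr <- sample.int(noise_reads_max, 1)
        read_rows[[length(read_rows) + 1L]] <- tibble(
          seqid = sc, start = rep(as.integer(p), nr),
          end = rep(as.integer(p + read_len - 1L), nr),
          strand = resample(c("+", "-"), 1L), sample = "s1")
      }
    }
    reads <- if (length(read_rows) > 0) bind_rows(read_rows) else
      tibble(seqid = character(), start = integer(), end = integer(),
             strand = character(), sample = character())
    reads$name <- sprintf("s1:%d", seq_len(nrow(reads)))
    reads$score <- 1
    truth <- if (length(truth_rows) > 0) bind_rows(truth_rows) else
      tibble(transcript_id = character(), gene_id = character(),
             strand = character(), old_end = integer(),
             new_end = integer())
    list(reads = reads, truth = truth)
  })
}

#' Implant motifs into 3' UTR sequences
#'
#' Writes concrete instances of the configured motifs (IUPAC ambiguity
#' codes instantiated at random) into each eligible 3' UTR at an offset
#' sampled from the motif's window relative to the TTS (offset 0 = the
#' 3'-terminal transcribed base; negative = upstream, in transcript
#' orientation). Transcripts whose terminal UTR block is too short for a
#' motif's window are skipped and reported.
#'
#' @param sim Output of [generate_genome_annotation()].
#' @param motifs List of specs, each `list(consensus =, offset_range =
#'   c(lo, hi))`; the default implants the `AWTAAA` PAS at -40..-10 and
#'   an AT-rich element at -100..-60.
#' @param seed Integer seed.
#' @return List with `genome` (edited copy), `truth` (tibble
#'   `transcript_id`, `motif`, `offset`, `start`, `end`, `instance`) and
#'   `skipped` (character vector of transcript ids).
#' @export
implant_motifs <- function(sim,
                           motifs = list(
                             pas = list(consensus = "AWTAAA",
                                        offset_range = c(-40L, -10L)),
                             atrich = list(consensus = "TATTTAT",
                                           offset_range = c(-100L, -60L))),
                           seed = 1L) {
  ann <- sim$annotation
  genome <- sim$genome
  if (length(motifs) == 0)
    return(list(genome = genome, truth = tibble(), skipped = character()))
  if (is.null(names(motifs)))
    names(motifs) <- vapply(motifs, `[[`, character(1), "consensus")
  withr::with_seed(seed, {
    u3 <- utr_table(ann, "utr3")
    truth_rows <- list()
    skipped <- character()
    seqs <- as.character(genome)
    for (tid in unique(u3$transcript_id)) {
      ut <- filter(u3, .data$transcript_id == tid)
      plus <- ut$strand[1] == "+"
      # terminal contiguous UTR block and the TTS position
      blk <- if (plus) ut[nrow(ut), ] else ut[1, ]
      tts <- if (plus) blk$end else blk$start
      blk_len <- blk$end - blk$start + 1L
      for (mn in names(motifs)) {
        m <- motifs[[mn]]
        w <- nchar(m$consensus)
        lo <- m$offset_range[1]; hi <- m$offset_range[2]
        # need the whole motif inside the terminal UTR block
        if (blk_len < -lo + 1L) {
          skipped <- c(skipped, tid)
          next
        }
        off <- resample(seq(lo, min(hi, -w)), 1L)
        inst <- instantiate_iupac(m$consensus)
        if (plus) {
          gs <- tts + off
          ge <- gs + w - 1L
          substr(seqs[[blk$seqid]], gs, ge) <- inst
        } else {
          ge <- tts - off
          gs <- ge - w + 1L
          rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(inst)))
          substr(seqs[[blk$seqid]], gs, ge) <- rc
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          transcript_id = tid, motif = mn, offset = as.integer(off),
          start = as.integer(if (plus) gs else gs),
          end = as.integer(if (plus) ge else ge), instance = inst)
      }
    }
    truth <- if (length(truth_rows) > 0) bind_rows(truth_rows) else tibble()
    list(genome = Biostrings::DNAStringSet(seqs),
         truth = truth, skipped = unique(skipped))
  })
}

IUPAC_OPTIONS <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- IUPAC_OPTIONS[[ch]]
    if (is.null(opts)) abort(paste0("not an IUPAC code: ", ch))
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}
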