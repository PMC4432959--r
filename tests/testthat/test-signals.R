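test_that("IUPAC consensus scanning matches PAS semantics", {
  expect_equal(scan_motif("AATAAA", "AWTAAA"), 1L)
  expect_equal(scan_motif("ATTAAA", "AWTAAA"), 1L)   # W = A or T
  expect_equal(length(scan_motif("AGTAAA", "AWTAAA")), 0)
  # overlapping matches are all reported
  expect_equal(scan_motif("AATAAATAAA", "AWTAAA"), c(1L, 5L))
})

test_that("consensus scanning equals the naive sliding-window oracle", {
  withr::with_seed(505, {
    for (rep in 1:30) {
      s <- random_dna(sample(500:2000, 1))
      for (m in c("AWTAAA", "TATTTAT", "RYN")) {
        expect_equal(scan_motif(s, m), oracle_scan(s, m))
      }
    }
  })
})

test_that("PWM scanning honours the score threshold", {
  # near-deterministic AATAAA matrix
  m <- matrix(0.01, nrow = 4, ncol = 6,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", ] <- 0.97; m["A", 3] <- 0.01; m["T", 3] <- 0.97
  mot <- motif_model(matrix = m, name = "pas_pwm", min_score = 0.9)
  expect_equal(scan_motif("GGAATAAAGG", mot), 3L)
  expect_equal(length(scan_motif("GGAACAAAGG", mot)), 0)
})

test_that("MEME minimal format parses into scannable PWMs", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF pas1",
    "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 1e-5",
    " 0.970 0.010 0.010 0.010",
    " 0.970 0.010 0.010 0.010",
    " 0.010 0.010 0.010 0.970",
    " 0.970 0.010 0.010 0.010",
    " 0.970 0.010 0.010 0.010",
    " 0.970 0.010 0.010 0.010"), f)
  motifs <- read_meme(f)
  expect_equal(names(motifs), "pas1")
  expect_equal(ncol(motifs$pas1$matrix), 6)
  expect_equal(scan_motif("GGAATAAAGG", motifs$pas1), 3L)
})

test_that("strict 3' UTR selection needs long scaffolds and cluster support", {
  mk_genome <- function(len) Biostrings::DNAStringSet(
    setNames(c(random_dna(len), random_dna(len)), c("sc1", "sc2")))
  genome60 <- mk_genome(60000)
  ann <- bind_annotations(
    toy_gene(list(c(1001, 2000)), cds = list(c(1101, 1600))),
    toy_gene(list(c(5001, 6000)), gene_id = "g2", tx_id = "g2.t1",
             seqid = "sc2", cds = list(c(5101, 5600))))
  cl <- tibble::tibble(seqid = "sc1", start = 1900L, end = 2100L,
                       strand = "+", read_count = 15L, samples = "s1")
  got <- select_strict_utr3(ann, cl, genome60)
  expect_equal(got, "g1.t1")               # g2's UTR has no cluster

  genome40 <- mk_genome(40000)
  expect_equal(length(select_strict_utr3(ann, cl, genome40)), 0)

  # cluster on the wrong strand does not count
  clm <- dplyr::mutate(cl, strand = "-")
  expect_equal(length(select_strict_utr3(ann, clm, genome60)), 0)
})

test_that("strict TSS selection excludes promoter-overlapped genes", {
  genome <- Biostrings::DNAStringSet(c(sc1 = random_dna(60000),
                                       sc2 = random_dna(30000)))
  iso <- bind_annotations(
    toy_gene(list(c(5001, 6000))),                       # isolated
    toy_gene(list(c(9941, 11000)), gene_id = "g2", tx_id = "g2.t1"),
    toy_gene(list(c(11020, 12000)), gene_id = "g3", tx_id = "g3.t1"),
    toy_gene(list(c(5001, 6000)), gene_id = "g4", tx_id = "g4.t1",
             seqid = "sc2"))                             # short scaffold
  got <- select_strict_tss(iso, genome)
  # g1 isolated -> kept; g3's promoter (10920..11070) overlaps g2 -> out;
  # g2's promoter (9841..9991) overlaps nothing -> kept; g4 scaffold too
  # short -> out
  expect_setequal(got, c("g1.t1", "g2.t1"))
})

test_that("positional profiles localise implanted motifs to their bin", {
  sim <- small_sim(seed = 121L, n_genes = 25L)
  imp <- implant_motifs(sim, motifs = list(
    pas = list(consensus = "AWTAAA", offset_range = c(-20L, -20L))),
    seed = 122L)
  ids <- setdiff(transcripts_with_utr3(sim$annotation), imp$skipped)
  expect_gt(length(ids), 5)
  pr <- positional_profile(sim$annotation, imp$genome, "AWTAAA", ids,
                           anchor = "tts", window = 200L, bin = 20L)
  d <- tidy(pr)
  modal <- d$bin_start[which.max(d$frequency)]
  expect_equal(modal, -20L)               # bin [-20, 0) holds offset -20
  # conservation: sum over bins of hits equals the total hit count
  expect_equal(sum(d$n_hits), sum(d$frequency * d$n_seq))
})

test_that("an empty anchor set yields an all-zero profile", {
  sim <- small_sim(seed = 131L, n_genes = 5L)
  pr <- positional_profile(sim$annotation, sim$genome, "AWTAAA",
                           character(), window = 200L, bin = 20L)
  expect_true(all(tidy(pr)$n_hits == 0))
  expect_true(all(tidy(pr)$n_seq == 0))
})

test_that("background bins match the i.i.d. closed-form expectation", {
  # uniform ACGT background: P(AWTAAA at a position) = 2 * (1/4)^6
  sim <- small_sim(seed = 141L, n_genes = 30L)
  ids <- transcripts_with_utr3(sim$annotation)
  pr <- positional_profile(sim$annotation, sim$genome, "AWTAAA", ids,
                           anchor = "tts", window = 1000L, bin = 20L)
  d <- tidy(pr)
  d <- d[d$n_seq > 0 & d$bin_start >= 200, ]   # well clear of the gene body
  p <- 2 * (1 / 4)^6
  lambda <- p * 20                              # expected hits/seq/bin
  n_obs <- sum(d$n_seq)
  total_rate <- sum(d$n_hits) / n_obs / nrow(d) # mean per bin per seq
  se <- sqrt(lambda / n_obs / nrow(d))
  expect_lt(abs(mean(d$n_hits / d$n_seq) - lambda), 3 * se * sqrt(nrow(d)))
})

test_that("cumulative PAS curves are monotone and detect upstream implants", {
  sim <- small_sim(seed = 151L, n_genes = 25L)
  tss <- select_strict_tss(sim$annotation, sim$genome)
  expect_gt(length(tss), 3)
  cum <- cumulative_pas(sim$annotation, sim$genome, tss, window = 400L)
  d <- tidy(cum)
  expect_true(all(diff(d$upstream) >= 0))
  expect_true(all(diff(d$downstream) >= 0))

  # single TSS with one PAS at -10 and none downstream
  genome <- Biostrings::DNAStringSet(c(sc1 = paste0(
    paste(rep("C", 490), collapse = ""), "AATAAA",    # PAS start at -10
    paste(rep("C", 4), collapse = ""),
    paste(rep("G", 700), collapse = ""))))
  ann <- toy_gene(list(c(501, 900)))
  one <- tidy(cumulative_pas(ann, genome, "g1.t1", window = 100L))
  expect_equal(one$upstream[one$offset == 100], 1)
  expect_equal(max(one$downstream), 0)
  expect_equal(one$upstream[one$offset == 5], 0)
  expect_equal(one$upstream[one$offset == 10], 1)

  # genome without any PAS: both curves identically zero
  g0 <- Biostrings::DNAStringSet(c(sc1 = paste(rep("C", 2000),
                                               collapse = "")))
  z <- tidy(cumulative_pas(toy_gene(list(c(501, 900))), g0, "g1.t1"))
  expect_true(all(z$upstream == 0) && all(z$downstream == 0))
})

test_that("upstream-only PAS implants dominate the downstream curve", {
  sim <- small_sim(seed = 161L, n_genes = 30L)
  # PAS-free background (no chance AWTAAA), then implant a PAS upstream
  # of every TSS so any dominance comes from the implants alone
  lens <- scaffold_lengths(sim$genome)
  seqs <- vapply(lens, function(L)
    paste(rep("C", L), collapse = ""), character(1))
  tx <- sim$annotation$transcripts
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    if (t$strand == "+") {
      p <- t$start - 60
      if (p > 0) substr(seqs[[t$seqid]], p, p + 5) <- "AATAAA"
    } else {
      p <- t$end + 55
      if (p + 5 <= lens[[t$seqid]])
        substr(seqs[[t$seqid]], p, p + 5) <- "TTTATT"
    }
  }
  genome2 <- Biostrings::DNAStringSet(seqs)
  tss <- select_strict_tss(sim$annotation, genome2)
  cum <- tidy(cumulative_pas(sim$annotation, genome2, tss, window = 300L))
  expect_true(all(cum$upstream >= cum$downstream))
  expect_gt(max(cum$upstream - cum$downstream), 0.5)
})

test_that("profiles are invariant under genome reverse-complement", {
  sim <- small_sim(seed = 171L, n_genes = 15L)
  ids <- transcripts_with_utr3(sim$annotation)
  pr1 <- tidy(positional_profile(sim$annotation, sim$genome, "AWTAAA",
                                 ids, window = 400L, bin = 20L))
  # mirror the genome and all annotation coordinates
  lens <- scaffold_lengths(sim$genome)
  rc <- Biostrings::reverseComplement(sim$genome)
  ann <- sim$annotation
  flip <- function(d) dplyr::mutate(
    d, s2 = unname(lens[.data$seqid]) - .data$end + 1L,
    e2 = unname(lens[.data$seqid]) - .data$start + 1L,
    start = .data$s2, end = .data$e2,
    strand = ifelse(.data$strand == "+", "-", "+"),
    s2 = NULL, e2 = NULL)
  ann$genes <- flip(ann$genes)
  ann$transcripts <- flip(ann$transcripts)
  ann$exons <- dplyr::arrange(flip(ann$exons), transcript_id, start)
  ann$cds <- dplyr::arrange(flip(ann$cds), transcript_id, start)
  pr2 <- tidy(positional_profile(ann, rc, "AWTAAA", ids,
                                 window = 400L, bin = 20L))
  expect_equal(pr1$n_hits, pr2$n_hits)
  expect_equal(pr1$n_seq, pr2$n_seq)
})
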