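# canonical 4-exon fixture used throughout: exons 101-200, 301-400,
# 501-600, 701-800 (+ strand unless stated)
can_exons <- function(strand = "+") {
  tibble::tibble(transcript_id = "c", seqid = "sc1", strand = strand,
                 start = c(101L, 301L, 501L, 701L),
                 end = c(200L, 400L, 600L, 800L))
}

alt_exons <- function(coords, strand = "+") {
  tibble::tibble(transcript_id = "a", seqid = "sc1", strand = strand,
                 start = vapply(coords, `[`, numeric(1), 1),
                 end = vapply(coords, `[`, numeric(1), 2))
}

test_that("identical chains yield no events", {
  expect_equal(nrow(pairwise_events(can_exons(), can_exons())), 0)
})

test_that("intron retention is detected with its intron footprint", {
  alt <- alt_exons(list(c(101, 400), c(501, 600), c(701, 800)))
  ev <- pairwise_events(can_exons(), alt)
  expect_equal(ev$class, "IntRt")
  expect_equal(ev$start, 201L)
  expect_equal(ev$end, 300L)
})

test_that("alternative acceptor and donor are strand-aware", {
  # + strand: acceptor is the intron's right boundary
  alt <- alt_exons(list(c(101, 200), c(331, 400), c(501, 600), c(701, 800)))
  ev <- pairwise_events(can_exons(), alt)
  expect_equal(ev$class, "AltAc")
  expect_equal(c(ev$start, ev$end), c(201L, 330L))
  # the same chains on - strand make it a donor shift
  evm <- pairwise_events(can_exons("-"), alt_exons(
    list(c(101, 200), c(331, 400), c(501, 600), c(701, 800)), "-"))
  expect_equal(evm$class, "AltDo")
  # + strand donor shift: intron's left boundary moves
  alt2 <- alt_exons(list(c(101, 170), c(301, 400), c(501, 600),
                         c(701, 800)))
  ev2 <- pairwise_events(can_exons(), alt2)
  expect_equal(ev2$class, "AltDo")
  expect_equal(c(ev2$start, ev2$end), c(171L, 300L))
})

test_that("exon skipping requires shared outer splice sites", {
  alt <- alt_exons(list(c(101, 200), c(501, 600), c(701, 800)))
  ev <- pairwise_events(can_exons(), alt)
  expect_equal(ev$class, "ExSk")
  expect_equal(c(ev$start, ev$end), c(301L, 400L))
})

test_that("alternative terminal exons need a shared junction and no
           overlap with the canonical terminal exon", {
  alt <- alt_exons(list(c(101, 200), c(301, 400), c(501, 600),
                        c(901, 1000)))
  ev <- pairwise_events(can_exons(), alt)
  expect_equal(ev$class, "AltTEx")
  expect_equal(c(ev$start, ev$end), c(901L, 1000L))
})

test_that("intronic start/end fire when a terminus lies inside an intron", {
  # transcript truncated: ends inside canonical intron 3 (601..700)
  alt <- alt_exons(list(c(101, 200), c(301, 400), c(501, 640)))
  ev <- pairwise_events(can_exons(), alt)
  expect_equal(ev$class, "IntEnd")
  expect_equal(c(ev$start, ev$end), c(601L, 700L))
  # starts inside canonical intron 1 (201..300)
  alt2 <- alt_exons(list(c(261, 400), c(501, 600), c(701, 800)))
  ev2 <- pairwise_events(can_exons(), alt2)
  expect_equal(ev2$class, "IntSt")
  expect_equal(c(ev2$start, ev2$end), c(201L, 300L))
  # on the minus strand the same truncation is an intronic *start*
  evm <- pairwise_events(can_exons("-"), alt_exons(
    list(c(101, 200), c(301, 400), c(501, 640)), "-"))
  expect_equal(evm$class, "IntSt")
})

test_that("different strands are rejected", {
  expect_error(pairwise_events(can_exons("+"), can_exons("-")), "strand")
})

test_that("classification is invariant under coordinate translation and
           strand mirroring", {
  shift <- 10000L
  alt <- alt_exons(list(c(101, 400), c(501, 600), c(701, 800)))
  ev0 <- pairwise_events(can_exons(), alt)
  can_s <- dplyr::mutate(can_exons(), start = start + shift,
                         end = end + shift)
  alt_s <- dplyr::mutate(alt, start = start + shift, end = end + shift)
  ev_s <- pairwise_events(can_s, alt_s)
  expect_equal(ev_s$class, ev0$class)
  expect_equal(ev_s$start, ev0$start + shift)
  # mirror around L: + becomes -, classes preserved
  L <- 5000L
  mirror <- function(d) dplyr::mutate(
    d, s2 = L - end + 1L, e2 = L - start + 1L, start = s2, end = e2,
    strand = "-", s2 = NULL, e2 = NULL) |> dplyr::arrange(start)
  ev_m <- pairwise_events(mirror(can_exons()), mirror(alt))
  expect_equal(ev_m$class, ev0$class)
})

test_that("events merge across isoforms and support counts supporters", {
  ann <- toy_gene(list(c(101, 200), c(301, 400), c(501, 600)))
  for (k in 1:3)
    ann <- add_isoform(ann, "g1", paste0("g1.r", k),
                       list(c(101, 400), c(501, 600)))
  ev <- classify_gene(ann, "g1", canonical = "g1.t1")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "IntRt")
  expect_equal(ev$n_support, 3L)
  expect_equal(ev$supporting, "g1.r1,g1.r2,g1.r3")
  expect_equal(ev$reference, "")
  # single-isoform gene -> nothing
  solo <- toy_gene(list(c(1, 100)))
  expect_equal(nrow(classify_gene(solo, "g1", canonical = "g1.t1")), 0)
})

test_that("two distinct events in one gene keep disjoint supporters", {
  ann <- toy_gene(list(c(101, 200), c(301, 400), c(501, 600)))
  ann <- add_isoform(ann, "g1", "g1.a", list(c(101, 400), c(501, 600)))
  ann <- add_isoform(ann, "g1", "g1.b", list(c(101, 200), c(501, 600)))
  ev <- classify_gene(ann, "g1", canonical = "g1.t1")
  expect_equal(sort(ev$class), c("ExSk", "IntRt"))
  sup <- strsplit(ev$supporting, ",")
  expect_equal(length(intersect(sup[[1]], sup[[2]])), 0)
})

test_that("support filtering drops events below the threshold", {
  ev <- tibble::tibble(gene_id = c("a", "b", "c"),
                       class = "IntRt", seqid = "sc1", strand = "+",
                       start = 1L, end = 10L,
                       n_support = c(3L, 2L, 5L),
                       supporting = "", reference = "",
                       canonical_id = "")
  kept <- filter_events(ev)
  expect_equal(kept$n_support, c(3L, 5L))
  expect_equal(nrow(filter_events(ev[0, ])), 0)
  expect_equal(filter_events(ev, min_support = 1), ev)
})

test_that("classification recovers the generator truth with
           precision and recall 1 per class", {
  sim <- small_sim(seed = 71L, n_genes = 60L)
  sp <- spawn_isoforms(sim, mix = c(IntRt = 0.2, AltTEx = 0.15,
                                    AltAc = 0.15, AltDo = 0.15,
                                    ExSk = 0.15, IntSt = 0.1,
                                    IntEnd = 0.1),
                       n_support = 3, seed = 72L)
  ev <- classify_annotation(sp$annotation, genome = sim$genome)
  truth <- sp$truth
  expect_gt(nrow(truth), 20)
  expect_true(all(AS_CLASSES %in% truth$class))
  got_key <- paste(ev$gene_id, ev$class, ev$start, ev$end)
  want_key <- paste(truth$gene_id, truth$class, truth$start, truth$end)
  expect_setequal(got_key, want_key)          # precision = recall = 1
  # supporters are exactly the generated isoforms
  m <- match(want_key, got_key)
  expect_equal(ev$supporting[m], truth$isoforms)
})

test_that("low-support events are classified but filtered out", {
  sim <- small_sim(seed = 81L, n_genes = 50L)
  sp <- spawn_isoforms(sim, mix = c(IntRt = 0.4, ExSk = 0.3),
                       n_support = 3, low_support_frac = 0.4, seed = 82L)
  ev <- classify_annotation(sp$annotation, genome = sim$genome)
  kept <- filter_events(ev, min_support = 3)
  truth_hi <- sp$truth[sp$truth$n_isoforms >= 3, ]
  truth_lo <- sp$truth[sp$truth$n_isoforms == 2, ]
  expect_gt(nrow(truth_lo), 0)
  expect_setequal(paste(kept$gene_id, kept$class),
                  paste(truth_hi$gene_id, truth_hi$class))
  expect_false(any(truth_lo$gene_id %in% kept$gene_id))
})

test_that("summary percentages are computed per class and rounded", {
  # one event, one transcript, ten transcripts total
  ev <- tibble::tibble(gene_id = "g", class = "IntRt", seqid = "s",
                       strand = "+", start = 1L, end = 2L, n_support = 1L,
                       supporting = "t1", reference = "",
                       canonical_id = "c")
  sm <- tidy(summarize_events(ev, total_transcripts = 10))
  expect_equal(sm$pct_events[sm$class == "IntRt"], 100)
  expect_equal(sm$pct_all_transcripts[sm$class == "IntRt"], 10)
  expect_equal(sum(sm$n_events), 1)

  # zero events: all-zero summary, no division error
  z <- tidy(summarize_events(ev[0, ], total_transcripts = 10))
  expect_true(all(z$n_events == 0))
  expect_true(all(z$pct_events == 0))
})

test_that("event percentages sum to 100 within rounding", {
  sim <- small_sim(seed = 91L, n_genes = 40L)
  sp <- spawn_isoforms(sim, mix = c(IntRt = 0.3, AltAc = 0.2, ExSk = 0.2),
                       n_support = 3, seed = 92L)
  ev <- classify_annotation(sp$annotation, genome = sim$genome)
  sm <- tidy(summarize_events(ev,
                              total_transcripts = nrow(sp$annotation$transcripts)))
  expect_lt(abs(sum(sm$pct_events) - 100), 0.4)
})
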