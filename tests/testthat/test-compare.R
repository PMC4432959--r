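test_that("coverage fraction handles identity, disjoint and partial cases", {
  a <- toy_gene(list(c(101, 600), c(801, 1300)))          # 1000 exonic bp
  expect_equal(coverage_fraction(a, a)$fraction, 1.0)

  b <- toy_gene(list(c(5001, 5500)), gene_id = "gb", tx_id = "gb.t1")
  expect_equal(coverage_fraction(a, b)$fraction, 0.0)

  # opposite strand never covers under stranded comparison
  c_ <- toy_gene(list(c(101, 600), c(801, 1300)), strand = "-",
                 gene_id = "gc", tx_id = "gc.t1")
  expect_equal(coverage_fraction(a, c_)$fraction, 0.0)
  expect_equal(coverage_fraction(a, c_, stranded = FALSE)$fraction, 1.0)

  # 800 of 1000 exonic bp covered -> 0.8
  d <- toy_gene(list(c(101, 600), c(801, 1100)), gene_id = "gd",
                tx_id = "gd.t1")
  expect_equal(coverage_fraction(a, d)$fraction, 0.8)
})

test_that("coverage fraction equals the per-base bitmap oracle", {
  withr::with_seed(303, {
    for (rep in 1:6) {
      mk_set <- function(tag, ngene) {
        anns <- lapply(seq_len(ngene), function(i) {
          s <- sample.int(8000, 1)
          n <- sample(1:3, 1)
          ex <- list()
          pos <- s
          for (k in seq_len(n)) {
            w <- sample(50:200, 1)
            ex[[k]] <- c(pos, pos + w)
            pos <- pos + w + sample(50:150, 1)
          }
          toy_gene(ex, strand = sample(c("+", "-"), 1),
                   gene_id = paste0(tag, i), tx_id = paste0(tag, i, ".t"))
        })
        do.call(bind_annotations, anns)
      }
      q <- mk_set("q", 4)
      t_ <- mk_set("t", 6)
      got <- coverage_fraction(q, t_)
      texons <- as.data.frame(t_$exons)
      for (g in got$gene_id) {
        qex <- as.data.frame(q$exons[
          q$exons$transcript_id == paste0(g, ".t"), ])
        o <- oracle_coverage(qex, texons)
        expect_equal(got$covered[got$gene_id == g], unname(o["covered"]))
        expect_equal(got$fraction[got$gene_id == g],
                     unname(o["covered"] / o["total"]))
      }
    }
  })
})

test_that("coverage is monotone non-decreasing as targets are added", {
  a <- toy_gene(list(c(101, 600)))
  t1 <- toy_gene(list(c(101, 300)), gene_id = "t1", tx_id = "t1.t")
  t2 <- bind_annotations(
    t1, toy_gene(list(c(301, 500)), gene_id = "t2", tx_id = "t2.t"))
  expect_lte(coverage_fraction(a, t1)$fraction,
             coverage_fraction(a, t2)$fraction)
})

test_that("hierarchical assignment preserves only the reference count", {
  g1 <- toy_gene(list(c(101, 600)))
  setA <- bind_annotations(
    g1, toy_gene(list(c(2001, 2500)), gene_id = "g2", tx_id = "g2.t"),
    name = "A")
  setA$name <- "A"
  # B matches only g1; C matches only g2; D matches nothing
  setB <- toy_gene(list(c(101, 600)), gene_id = "b1", tx_id = "b1.t")
  setB$name <- "B"
  setC <- toy_gene(list(c(2001, 2500)), gene_id = "c1", tx_id = "c1.t")
  setC$name <- "C"
  vn <- hierarchical_assign(list(A = setA, B = setB, C = setC))
  reg <- vn$regions
  ref_n <- sum(reg$n[grepl("(^|&)A(&|$)", reg$region)])
  expect_equal(ref_n, 2)
  expect_equal(reg$n[reg$region == "A&B"], 1)
  expect_equal(reg$n[reg$region == "A&C"], 1)
  # B and C genes are fully covered by A, so no exclusive regions remain
  expect_false(any(reg$region %in% c("B", "C")))

  # identical sets -> everything in the intersection
  setA2 <- setA; setA2$name <- "A2"
  vn2 <- hierarchical_assign(list(A = setA, A2 = setA2))
  expect_equal(vn2$regions$region, "A&A2")
  expect_equal(vn2$regions$n, 2)

  # disjoint sets -> all exclusive
  vn3 <- hierarchical_assign(list(B = setB, C = setC))
  expect_setequal(vn3$regions$region, c("B", "C"))
})

test_that("three-set toy matches exhaustive enumeration", {
  withr::with_seed(404, {
    mk <- function(tag, spans) {
      anns <- lapply(seq_along(spans), function(i)
        toy_gene(list(spans[[i]]), gene_id = paste0(tag, i),
                 tx_id = paste0(tag, i, ".t")))
      a <- do.call(bind_annotations, anns)
      a$name <- tag
      a
    }
    A <- mk("A", list(c(1, 100), c(201, 300), c(401, 500)))
    B <- mk("B", list(c(1, 100), c(1001, 1100)))
    C <- mk("C", list(c(201, 300), c(1001, 1100), c(2001, 2100)))
    vn <- hierarchical_assign(list(A = A, B = B, C = C))
    # exhaustive expectation: A1 covered by B, A2 by C, A3 by none;
    # B genes covered by A drop out, B2 (1001) shared with C;
    # C genes covered by A or B drop out, C3 exclusive
    want <- c("A&B" = 1, "A&C" = 1, "A" = 1, "B&C" = 1, "C" = 1)
    got <- setNames(vn$regions$n, vn$regions$region)
    expect_equal(got[names(want)], want)
  })
})

test_that("structure statistics match a naive recount on synthetic data", {
  sim <- small_sim(seed = 51L, n_genes = 25L)
  st <- structure_stats(sim$annotation, sim$genome)
  o <- oracle_structure(sim$annotation)
  s <- st$stats
  expect_equal(s$n_genes, o$n_genes)
  expect_equal(s$mean_gene_length, o$mean_gene_length)
  expect_equal(s$n_exons, o$n_exons)
  expect_equal(s$mean_exon_length, o$mean_exon_length)
  expect_equal(s$n_introns, o$n_introns)
  expect_equal(s$mean_intron_length, o$mean_intron_length)
  # ORF stats come from the designed coding sequences
  expect_equal(s$orf_mean_length,
               mean(sim$truth$genes$cds_len))
  # genome coverage equals union of spans over genome length
  expect_equal(s$pct_genome,
               100 * sum(sim$annotation$genes$end -
                           sim$annotation$genes$start + 1) /
                 sum(Biostrings::width(sim$genome)))
})

test_that("a single gene covering half its scaffold gives 50% coverage", {
  genome <- Biostrings::DNAStringSet(c(sc1 = random_dna(1000)))
  ann <- toy_gene(list(c(1, 500)))
  st <- structure_stats(ann, genome)
  expect_equal(st$stats$pct_genome, 50)
  # empty annotation: zero counts, NA means, no errors
  empty <- annotation_from_exons(tibble::tibble(
    gene_id = character(), transcript_id = character(),
    seqid = character(), strand = character(),
    start = integer(), end = integer()))
  st0 <- structure_stats(empty, genome)
  expect_equal(st0$stats$n_genes, 0)
  expect_equal(st0$stats$pct_genome, 0)
})

test_that("intergenic distances use spans irrespective of strand", {
  a <- bind_annotations(
    toy_gene(list(c(1, 100))),
    toy_gene(list(c(301, 400)), strand = "-", gene_id = "g2",
             tx_id = "g2.t"))
  igd <- intergenic_distances(a)
  expect_equal(igd$distances$distance, 200L)
  # overlapping genes -> clamped to 0
  b <- bind_annotations(
    toy_gene(list(c(1, 100))),
    toy_gene(list(c(51, 200)), gene_id = "g2", tx_id = "g2.t"))
  expect_equal(intergenic_distances(b)$distances$distance, 0L)
  # one gene per scaffold -> empty list, NA median
  solo <- toy_gene(list(c(1, 100)))
  igd0 <- intergenic_distances(solo)
  expect_equal(nrow(igd0$distances), 0)
  expect_true(is.na(igd0$median))
})

test_that("intergenic distances equal the naive recomputation", {
  sim <- small_sim(seed = 61L, n_genes = 30L)
  got <- intergenic_distances(sim$annotation)
  want <- oracle_intergenic(as.data.frame(sim$annotation$genes))
  expect_equal(sort(got$distances$distance), sort(want))
  expect_equal(got$median, median(want))
})
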