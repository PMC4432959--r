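# Independent brute-force oracles, deliberately library-free and naive.

# every ATG..first-in-frame-stop pair, by direct codon walking
oracle_all_orfs <- function(seq) {
  n <- nchar(seq)
  res <- list()
  for (s in seq_len(max(0, n - 2))) {
    if (substr(seq, s, s + 2) != "ATG") next
    i <- s
    while (i + 2 <= n) {
      cod <- substr(seq, i, i + 2)
      if (i > s && cod %in% c("TAA", "TAG", "TGA")) {
        res[[length(res) + 1]] <- c(start = s, end = i + 2,
                                    length = i + 2 - s + 1)
        break
      }
      i <- i + 3
    }
  }
  if (length(res) == 0)
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  as.data.frame(do.call(rbind, res))
}

# union-find connected components over the pairwise-overlap graph
oracle_cluster <- function(df) {
  # df: seqid,start,end,strand,sample
  key <- paste(df$sample, df$seqid, df$strand)
  out <- list()
  for (k in unique(key)) {
    d <- df[key == k, ]
    n <- nrow(d)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && d$start[i] <= d$end[j] && d$start[j] <= d$end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      m <- d[roots == r, ]
      out[[length(out) + 1]] <- data.frame(
        seqid = m$seqid[1], start = min(m$start), end = max(m$end),
        strand = m$strand[1], read_count = nrow(m), sample = m$sample[1])
    }
  }
  d <- do.call(rbind, out)
  d[order(d$seqid, d$start, d$strand, d$sample), , drop = FALSE]
}

# per-base boolean bitmap coverage of query exonic bases by target bases
oracle_coverage <- function(q_iv, t_iv, scaffold_len = 100000L) {
  # intervals: data.frames with seqid,strand,start,end
  total <- 0L; covered <- 0L
  for (i in seq_len(nrow(q_iv))) {
    bases <- q_iv$start[i]:q_iv$end[i]
    total <- total + length(bases)
    hit <- rep(FALSE, length(bases))
    for (j in seq_len(nrow(t_iv))) {
      if (t_iv$seqid[j] != q_iv$seqid[i]) next
      if (t_iv$strand[j] != q_iv$strand[i]) next
      hit <- hit | (bases >= t_iv$start[j] & bases <= t_iv$end[j])
    }
    covered <- covered + sum(hit)
  }
  c(total = total, covered = covered)
}

# naive sliding-window IUPAC scan
oracle_scan <- function(seq, consensus) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  w <- nchar(consensus)
  cc <- strsplit(consensus, "")[[1]]
  hits <- integer()
  for (p in seq_len(max(0, nchar(seq) - w + 1))) {
    win <- strsplit(substr(seq, p, p + w - 1), "")[[1]]
    if (all(mapply(function(b, code) b %in% tab[[code]], win, cc)))
      hits <- c(hits, p)
  }
  hits
}

# naive per-feature recount of structure statistics
oracle_structure <- function(ann) {
  glen <- ann$genes$end - ann$genes$start + 1
  ex <- merge(ann$exons, ann$transcripts[, c("transcript_id", "gene_id")],
              by = "transcript_id")
  dex <- unique(ex[, c("gene_id", "seqid", "start", "end")])
  # introns per transcript, then distinct per gene
  ints <- list()
  for (tid in unique(ann$exons$transcript_id)) {
    e <- ann$exons[ann$exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    gid <- ann$transcripts$gene_id[ann$transcripts$transcript_id == tid]
    if (nrow(e) > 1)
      for (i in seq_len(nrow(e) - 1))
        ints[[length(ints) + 1]] <- data.frame(
          gene_id = gid, start = e$end[i] + 1, end = e$start[i + 1] - 1)
  }
  dint <- if (length(ints) > 0) unique(do.call(rbind, ints)) else
    data.frame(start = integer(), end = integer())
  list(n_genes = nrow(ann$genes),
       mean_gene_length = if (length(glen)) mean(glen) else NA,
       n_exons = nrow(dex),
       mean_exon_length = mean(dex$end - dex$start + 1),
       n_introns = nrow(dint),
       mean_intron_length = if (nrow(dint)) mean(dint$end - dint$start + 1)
       else NA)
}

# naive intergenic distances: per scaffold, consecutive sorted spans
oracle_intergenic <- function(genes) {
  out <- integer()
  for (sc in unique(genes$seqid)) {
    g <- genes[genes$seqid == sc, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      for (i in seq_len(nrow(g) - 1))
        out <- c(out, max(0, g$start[i + 1] - g$end[i] - 1))
  }
  out
}
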