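# hand-built hit tables give exact control over the arithmetic
mk_hits <- function(..., seq = strrep("T", 23)) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(read_id = r[["id"]], region = r[["region"]],
               start = as.integer(r[["start"]]),
               length = as.integer(r[["length"]]), strand = r[["strand"]],
               mismatches = 0L, n_hits = as.integer(r[["n_hits"]]),
               count = as.integer(r[["count"]]), seq = seq,
               stringsAsFactors = FALSE)))
}
ref300 <- c(locus = strrep("ACGT", 75))

test_that("weighted coverage deposits count x factor / n_hits per position", {
  h <- mk_hits(list(id = "r1", region = "locus", start = 10, length = 23,
                    strand = "+", n_hits = 1, count = 2))
  cov <- weighted_coverage(h, ref300)$locus
  expect_equal(cov[11:33], rep(2, 23))
  expect_equal(sum(cov != 0), 23)
  # two placements: each gets half the weight
  h2 <- mk_hits(
    list(id = "r1", region = "locus", start = 10, length = 23,
         strand = "+", n_hits = 2, count = 4),
    list(id = "r1", region = "locus", start = 100, length = 23,
         strand = "+", n_hits = 2, count = 4))
  cov2 <- weighted_coverage(h2, ref300)$locus
  expect_equal(cov2[11], 2)
  expect_equal(cov2[101], 2)
  # antisense weight is negative
  h3 <- mk_hits(list(id = "r2", region = "locus", start = 50, length = 23,
                     strand = "-", n_hits = 1, count = 3))
  expect_equal(weighted_coverage(h3, ref300)$locus[51], -3)
  h_bad <- mk_hits(list(id = "r", region = "locus", start = 290,
                        length = 23, strand = "+", n_hits = 1, count = 1))
  expect_error(weighted_coverage(h_bad, ref300), "bounds")
})

test_that("per-read deposited weight is conserved in a simulated library", {
  g <- small_world(13)
  lib <- simulate_library(g, pirna_library_spec(
    n_reads = 2000L, seed = 15L, contaminant_fractions = numeric(0)))
  pr <- process_reads(lib$reads)
  hits <- match_reads(pr$reads, g)
  f <- 0.73
  per_read <- tapply(abs(hits$count * f / hits$n_hits), hits$read_id, sum)
  expected <- pr$reads$count[match(names(per_read), pr$reads$read_id)] * f
  expect_equal(as.numeric(per_read), as.numeric(expected))
  # per-strand coverage totals equal hit weights times lengths (signed
  # coverage cancels where strands overlap, so check strands separately)
  for (str in c("+", "-")) {
    hs <- hits[hits$strand == str, ]
    cov <- weighted_coverage(hs, g, f)$cluster
    expect_equal(sum(abs(cov)),
                 sum(hs$count * f / hs$n_hits * hs$length))
  }
})

test_that("size distribution reports weighted counts per length/strand", {
  h <- mk_hits(list(id = "a", region = "locus", start = 5, length = 26,
                    strand = "+", n_hits = 1, count = 7))
  sd1 <- size_distribution(h, "locus")
  expect_equal(sd1$sense[sd1$length == 26], 7)
  expect_equal(sum(sd1$sense), 7)
  expect_equal(sum(sd1$antisense), 0)
  empty <- size_distribution(h[0, ], "locus")
  expect_true(all(empty$sense == 0) && all(empty$antisense == 0))
})

test_that("simulated size mode is recovered through the pipeline", {
  g <- small_world(14)
  peaked <- c(`24` = 0.1, `25` = 0.7, `26` = 0.2)
  lib <- simulate_library(g, pirna_library_spec(
    n_reads = 2000L, size_dist = peaked, seed = 16L,
    contaminant_fractions = numeric(0)))
  hits <- match_reads(process_reads(lib$reads)$reads, g)
  sd <- size_distribution(hits, "cluster")
  tot <- sd$sense + sd$antisense
  expect_identical(sd$length[which.max(tot)], 25L)
})

test_that("u1 bias is the weighted fraction of T-initial reads", {
  hT <- mk_hits(list(id = "a", region = "locus", start = 5, length = 23,
                     strand = "+", n_hits = 1, count = 3),
                seq = paste0("T", strrep("A", 22)))
  hA <- mk_hits(list(id = "b", region = "locus", start = 50, length = 23,
                     strand = "-", n_hits = 1, count = 3),
                seq = strrep("A", 23))
  expect_equal(u1_bias(hT), 1)
  expect_equal(u1_bias(rbind(hT, hA)), 0.5)
  expect_true(is.na(u1_bias(hT[0, ])))
  # out-of-range lengths are excluded
  h20 <- mk_hits(list(id = "c", region = "locus", start = 5, length = 20,
                      strand = "+", n_hits = 1, count = 1),
                 seq = strrep("G", 20))
  expect_equal(u1_bias(rbind(hT, h20)), 1)
})

test_that("ping-pong histogram counts 5'-overlap pairs exactly", {
  h <- mk_hits(
    list(id = "s", region = "locus", start = 100, length = 26,
         strand = "+", n_hits = 1, count = 1),
    list(id = "a", region = "locus", start = 84, length = 26,
         strand = "-", n_hits = 1, count = 1))  # antisense 5' at 109
  hist <- pingpong_signature(h, "locus", ref300)
  expect_equal(hist[["10"]], 1)
  expect_equal(sum(hist), 1)
  # no antisense reads: empty histogram
  h_s <- h[h$strand == "+", ]
  expect_equal(sum(pingpong_signature(h_s, "locus", ref300)), 0)
})

test_that("ping-pong histogram equals the O(n^2) oracle on random hits", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    h <- data.frame(
      read_id = sprintf("r%03d", 1:n), region = "locus",
      start = sample(0:250, n, replace = TRUE),
      length = sample(23:28, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mismatches = 0L, n_hits = sample(1:3, n, replace = TRUE),
      count = sample(1:5, n, replace = TRUE),
      seq = strrep("A", 23), stringsAsFactors = FALSE)
    h$start <- pmin(h$start, 300 - h$length)
    expect_equal(pingpong_signature(h, "locus", ref300),
                 oracle_pingpong(h, "locus"))
  }
})

test_that("strand handling: relabel flips coverage, involution fixes hist", {
  g <- small_world(15)
  lib <- simulate_library(g, pirna_library_spec(
    n_reads = 500L, pingpong_fraction = 0.6, seed = 18L,
    contaminant_fractions = numeric(0)))
  hits <- match_reads(process_reads(lib$reads)$reads, g)
  L <- Biostrings::width(g$sequences)[1]
  # pure strand relabel: coverage negates, size_hist strands transpose
  flipped <- hits
  flipped$strand <- c("+" = "-", "-" = "+")[hits$strand]
  expect_equal(weighted_coverage(flipped, g)$cluster,
               -weighted_coverage(hits, g)$cluster)
  sd0 <- size_distribution(hits, "cluster")
  sd1 <- size_distribution(flipped, "cluster")
  expect_equal(sd1$sense, sd0$antisense)
  expect_equal(sd1$antisense, sd0$sense)
  # reverse-complement involution: overlap histogram is invariant
  invol <- hits
  invol$strand <- c("+" = "-", "-" = "+")[hits$strand]
  invol$start <- L - (hits$start + hits$length)
  expect_equal(pingpong_signature(invol, "cluster", g),
               pingpong_signature(hits, "cluster", g))
})

test_that("ping-pong z-score standardizes bin 10 against the rest", {
  expect_equal(pingpong_zscore(setNames(rep(4, 28), 1:28)), 0)
  degen <- setNames(c(rep(0, 9), 1, rep(0, 18)), 1:28)
  expect_true(is.na(pingpong_zscore(degen)))
  hist <- setNames(c(rep(2, 9), 40, rep(2, 17), 4), 1:28)
  expect_equal(pingpong_zscore(hist),
               (40 - mean(hist[-10])) / sd(hist[-10]))
})

test_that("TE antisense RPKM follows the unit definition", {
  te <- c(TE1 = strrep("ACGT", 250))  # 1 kb
  h <- mk_hits(list(id = "x", region = "TE1", start = 0, length = 25,
                    strand = "-", n_hits = 1, count = 10))
  tab <- te_antisense_rpkm(h, te, norm_factor = 1, effective_depth = 1e6)
  expect_equal(tab$antisense_norm_count, 10)
  expect_equal(tab$rpkm, 10)
  # zero reads give zero RPKM (and only then)
  tab0 <- te_antisense_rpkm(h[0, ], te, 1, 1e6)
  expect_equal(tab0$rpkm, 0)
  # doubling length halves RPKM
  te2 <- c(TE1 = strrep("ACGT", 500))
  tab2 <- te_antisense_rpkm(h, te2, 1, 1e6)
  expect_equal(tab2$rpkm, tab$rpkm / 2)
  # sense hits never count
  hs <- mk_hits(list(id = "y", region = "TE1", start = 0, length = 25,
                     strand = "+", n_hits = 1, count = 10))
  expect_equal(te_antisense_rpkm(hs, te, 1, 1e6)$rpkm, 0)
})

test_that("GLKD scatter computes log2 coordinates with pseudocount", {
  ctrl <- data.frame(te = c("a", "b"), length = c(1000L, 1000L),
                     antisense_norm_count = c(100, 400), rpkm = c(1, 4),
                     library_id = "c")
  same <- glkd_scatter(ctrl, ctrl)
  expect_equal(same$log2_ratio, c(0, 0))
  quarter <- ctrl
  quarter$antisense_norm_count <- ctrl$antisense_norm_count / 4
  sc <- glkd_scatter(ctrl, quarter)
  expect_true(all(abs(sc$log2_ratio + 2) < 0.1))
  other <- ctrl; other$te <- c("a", "zzz")
  expect_error(glkd_scatter(ctrl, other), "zzz")
})

test_that("simulated knockdown separates depleted TEs in the scatter", {
  # a TE-only world: genome regions double as the TE reference set,
  # so region depletion emulates a germline knockdown of TE piRNAs
  te_names <- paste0("TE", 1:6)
  gspec <- toy_genome_spec(data.frame(name = te_names, length = 1000L,
                                      role = "other"), seed = 19L)
  g <- make_toy_genome(gspec)
  depleted <- te_names[1:3]
  mk <- function(depl, seed) {
    lib <- simulate_library(g, pirna_library_spec(
      n_reads = 4000L, antisense_fraction = 0.9, pingpong_fraction = 0,
      multimap_rate = 0, contaminant_fractions = numeric(0),
      depletion = depl, seed = seed))
    hits <- match_reads(process_reads(lib$reads)$reads, g)
    te_antisense_rpkm(hits, g$sequences, 1, effective_depth = 4000)
  }
  ctrl <- mk(numeric(0), 20L)
  test <- mk(setNames(rep(0.1, 3), depleted), 21L)
  sc <- glkd_scatter(ctrl, test)
  expect_lt(max(sc$log2_ratio[sc$te %in% depleted]),
            min(sc$log2_ratio[!sc$te %in% depleted]))
})
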