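adapter <- "TGGAATTCTCGGGTGCCAAG"

test_that("trim_adapter handles constructed cases", {
  insert24 <- strrep("ACGTTC", 4)
  tr <- trim_adapter(paste0(insert24, adapter))
  expect_identical(tr$status, "ok")
  expect_identical(tr$insert, insert24)
  # adapter alone: zero-length insert
  expect_identical(trim_adapter(adapter)$status, "too_short")
  # partial 3' adapter: >= min_overlap prefix at the read end suffices
  tr2 <- trim_adapter(paste0(insert24, substr(adapter, 1, 9)))
  expect_identical(tr2$insert, insert24)
  # below min_overlap: not recognized
  expect_identical(
    trim_adapter(paste0(insert24, substr(adapter, 1, 7)))$status,
    "no_adapter")
  # length filter and alphabet filter
  expect_identical(trim_adapter(paste0(strrep("A", 18), adapter))$status,
                   "too_short")
  expect_identical(trim_adapter(paste0(strrep("A", 30), adapter))$status,
                   "too_long")
  expect_identical(
    trim_adapter(paste0("ACGTNACGTACGTACGTACGTACG", adapter))$status,
    "non_acgt")
  # leftmost occurrence wins: adapter embedded twice
  tr3 <- trim_adapter(paste0(strrep("C", 20), adapter, "AAAA", adapter))
  expect_identical(tr3$insert, strrep("C", 20))
})

test_that("trim recovers every simulated insert (truth-table check)", {
  g <- tiny_genome(5)
  ann <- make_annotation_sets(seed = 5)
  lib <- simulate_library(g, pirna_library_spec(n_reads = 2000L, seed = 6L),
                          ann)
  tr <- trim_adapter(lib$reads$seq)
  expect_true(all(tr$status == "ok"))
  expect_identical(tr$insert, lib$truth$insert)
})

test_that("collapse_reads tallies like a dictionary", {
  x <- c(strrep("ACG", 8), strrep("ACG", 8), strrep("TTA", 8))
  cc <- collapse_reads(x)
  expect_identical(nrow(cc), 2L)
  expect_identical(sort(cc$count), c(1L, 2L))
  expect_identical(collapse_reads(character(0))$count, integer(0))
  # randomized: counts equal an independent table() tally
  set.seed(42)
  pool <- rand_dna(50, 23)
  draws <- sample(pool, 1000, replace = TRUE)
  cc2 <- collapse_reads(draws)
  ref <- table(draws)
  expect_identical(sum(cc2$count), 1000L)
  expect_identical(cc2$count[match(names(ref), cc2$seq)],
                   as.integer(ref))
  expect_error(collapse_reads("ACGT"), "19-29")
})

test_that("match_reads reports exact and reverse-complement placements", {
  g <- small_world(6)
  s <- as.character(g$sequences[[1]])
  fwd <- substr(s, 101, 123)           # reference[100:123), 0-based
  h <- match_reads(fwd, g)
  h0 <- h[h$mismatches == 0, ]
  expect_true(any(h0$start == 100L & h0$strand == "+"))
  rc <- str_revcomp(substr(s, 51, 76))  # reference[50:76)
  h2 <- match_reads(rc, g)
  h2 <- h2[h2$mismatches == 0, ]
  expect_true(any(h2$start == 50L & h2$strand == "-"))
  # repeat-derived read multimaps
  rep_read <- substr(s, g$repeats$start1[1] + 1L, g$repeats$start1[1] + 25L)
  expect_gte(match_reads(rep_read, g, max_mismatch = 0L)$n_hits[1], 2L)
  expect_error(match_reads("ACGT", c(x = "ACGTNACGT")), "non-ACGT")
})

test_that("best stratum suppresses 1-mismatch placements of perfect reads", {
  ref <- c(chr = paste0(strrep("A", 30), "ACGTACGTACGTACGTACGTACG",
                        strrep("C", 30), "ACGTACGTACGTACGTACGTACA",
                        strrep("G", 30)))
  read <- "ACGTACGTACGTACGTACGTACG"  # perfect at 30, 1-mm at 83
  h1 <- match_reads(read, ref, max_mismatch = 1L)
  expect_true(all(h1$mismatches == 0L))
  mutated <- "ACGTACGTACGTACGTACGTACT"  # 1 mm against both copies
  h2 <- match_reads(mutated, ref, max_mismatch = 1L)
  expect_true(all(h2$mismatches == 1L))
  expect_identical(unique(h2$n_hits), nrow(h2))
})

test_that("aligner equals the exhaustive sliding-window oracle", {
  g <- small_world(7)
  ref_chr <- as.character(g$sequences[[1]])
  set.seed(7)
  # reads drawn from the reference with 0-2 mutations, plus pure noise
  planted <- vapply(1:150, function(i) {
    len <- sample(19:29, 1)
    st <- sample(nchar(ref_chr) - len + 1, 1)
    s <- substr(ref_chr, st, st + len - 1)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      pos <- sample(len, nmut)
      chars <- strsplit(s, "")[[1]]
      chars[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      s <- paste(chars, collapse = "")
    }
    if (runif(1) < 0.5) s else str_revcomp(s)
  }, character(1))
  reads <- c(planted, rand_dna(50, 25))
  for (mm in 0:1) {
    got <- match_reads(reads, g, max_mismatch = mm)
    want <- oracle_match(reads, ref_chr, mm)
    got$idx <- as.integer(sub("^q", "", got$read_id))
    got <- got[order(got$idx, got$strand, got$start),
               c("idx", "start", "strand", "mismatches")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("strand involution: reverse-complemented references swap hits", {
  g <- small_world(8)
  L <- Biostrings::width(g$sequences)[1]
  refs_rc <- Biostrings::reverseComplement(g$sequences)
  set.seed(8)
  st <- sample(L - 30, 40)
  reads <- substring(as.character(g$sequences[[1]]), st, st + 24)
  reads[1:20] <- str_revcomp(reads[1:20])
  h <- match_reads(reads, g)
  h_rc <- match_reads(reads, refs_rc)
  key <- function(x, flip) {
    strand <- if (flip) c("+" = "-", "-" = "+")[x$strand] else x$strand
    start <- if (flip) L - (x$start + x$length) else x$start
    sort(paste(x$read_id, start, strand, x$mismatches, x$n_hits))
  }
  expect_identical(key(h_rc, TRUE), key(h, FALSE))
})

test_that("SAM conversion conventions and round-trip identity hold", {
  g <- small_world(9)
  s <- as.character(g$sequences[[1]])
  reads <- collapse_reads(c(substr(s, 101, 126),
                            str_revcomp(substr(s, 51, 76)),
                            substr(s, 301, 325)))
  hits <- match_reads(reads, g)
  sam <- tempfile(fileext = ".sam")
  write_sam(hits, g, sam)
  imp <- import_sam(sam, reads = reads)
  # POS is 1-based in SAM, start 0-based internally
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 4))
  expect_setequal(pos, hits$start + 1L)
  # reverse-flag record: 5' end at start + length - 1
  rev_hit <- imp[imp$strand == "-", ][1, ]
  expect_identical(five_prime_pos(rev_hit), rev_hit$start + rev_hit$length - 1L)
  cols <- c("read_id", "region", "start", "length", "strand", "mismatches",
            "n_hits", "count", "seq")
  ord <- function(x) {
    x <- x[do.call(order, x[c("read_id", "start", "strand")]), cols]
    rownames(x) <- NULL
    x
  }
  expect_identical(ord(imp), ord(hits))
})

test_that("malformed SAM records are rejected with a line number", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:100",
               "r1\t0\tchr\t5\t255\t20M\t*\t0\t0"), bad)  # 9 fields
  expect_error(import_sam(bad), "line 3")
})

test_that("FASTQ writer and reader round-trip simulated reads", {
  g <- small_world(10)
  lib <- simulate_library(g, pirna_library_spec(
    n_reads = 50L, seed = 12L, contaminant_fractions = numeric(0)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(lib, fq)
  back <- read_fastq(fq)
  expect_identical(back, lib$reads)
})
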