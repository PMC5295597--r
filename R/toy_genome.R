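#' Generate a toy reference genome
#'
#' Builds random nucleotide sequences for each region of a
#' [toy_genome_spec()]. Regions with role `dual_strand_cluster` receive an
#' exact internal repeat (two identical copies of a 60 nt block) so that
#' reads longer than 25 nt drawn from the repeat place at two positions,
#' exercising multi-mapping weight apportionment downstream.
#'
#' @param spec a [toy_genome_spec()].
#' @return An object of class `toy_genome`: a list with `sequences`
#'   (named [Biostrings::DNAStringSet]), `regions` (the spec's region
#'   table) and `repeats` (data.frame of repeat copy coordinates, 0-based
#'   starts, one row per cluster region).
#' @examples
#' g <- make_toy_genome(default_genome_spec(seed = 7))
#' Biostrings::width(g$sequences)
#' @export
make_toy_genome <- function(spec) {
  stopifnot(is(spec, "toy_genome_spec"))
  gc <- spec$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rep_len <- 60L
  with_seed(spec$seed, {
    seqs <- character(nrow(spec$regions))
    repeats <- list()
    for (i in seq_len(nrow(spec$regions))) {
      L <- spec$regions$length[i]
      s <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
      if (spec$regions$role[i] == "dual_strand_cluster") {
        # two exact copies of a 60 nt block, one in each half of the region
        start1 <- 20L
        start2 <- L - rep_len - 20L
        s[(start2 + 1):(start2 + rep_len)] <-
          s[(start1 + 1):(start1 + rep_len)]
        repeats[[length(repeats) + 1L]] <- data.frame(
          region = spec$regions$name[i], start1 = start1, start2 = start2,
          length = rep_len, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- spec$regions$name
    structure(list(sequences = Biostrings::DNAStringSet(seqs),
                   regions = spec$regions,
                   repeats = if (length(repeats)) do.call(rbind, repeats)
                             else data.frame(region = character(0),
                                             start1 = integer(0),
                                             start2 = integer(0),
                                             length = integer(0))),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy genome with", length(x$sequences), "region(s):\n")
  print(data.frame(name = names(x$sequences),
                   length = Biostrings::width(x$sequences),
                   role = x$regions$role))
  invisible(x)
}

#' Generate annotation reference sets
#'
#' Produces small reference collections for the annotation categories used
#' in library classification: `miscRNA` (rRNA/snoRNA-like), `tRNA`, `miRNA`
#' hairpin-arm-like sequences, and `TE` (transposon consensus-like
#' sequences). Sequences are random and carry no biological motif content;
#' they exist so that simulated contaminant reads are classifiable and TE
#' counting has targets.
#'
#' @param seed integer seed.
#' @param n_te number of transposon consensus sequences (default 12).
#' @param te_lengths integer vector recycled over TEs (default
#'   800-4000 nt).
#' @param gc_fraction base composition (default 0.43).
#' @return Named list of [Biostrings::DNAStringSet]: `miscRNA`, `tRNA`,
#'   `miRNA`, `TE`, in annotation priority order.
#' @export
make_annotation_sets <- function(seed = 1L, n_te = 12L,
                                 te_lengths = c(800L, 1500L, 2500L, 4000L),
                                 gc_fraction = 0.43) {
  gc <- gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rand_seq <- function(L) paste(sample(names(base_prob), L, replace = TRUE,
                                       prob = base_prob), collapse = "")
  # decorrelate from make_toy_genome: a shared master seed must not make
  # annotation sequences duplicate genome sequence
  seed <- bitwXor(as.integer(seed), 560689219L)
  with_seed(seed, {
    misc <- vapply(c(120L, 1800L, 150L, 90L), rand_seq, character(1))
    names(misc) <- c("snoRNA1", "rRNA18S", "snoRNA2", "rRNA5S")
    trna <- vapply(rep(75L, 4L), rand_seq, character(1))
    names(trna) <- paste0("tRNA", 1:4)
    mirna <- vapply(rep(22L, 8L), rand_seq, character(1))
    names(mirna) <- paste0("mir", 1:8)
    tel <- rep_len(te_lengths, n_te)
    te <- vapply(tel, rand_seq, character(1))
    names(te) <- paste0("TE", seq_len(n_te))
    list(miscRNA = Biostrings::DNAStringSet(misc),
         tRNA = Biostrings::DNAStringSet(trna),
         miRNA = Biostrings::DNAStringSet(mirna),
         TE = Biostrings::DNAStringSet(te))
  })
}

#' Write reference collections to FASTA
#'
#' @param x a `toy_genome`, [Biostrings::DNAStringSet] or named character
#'   vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(x, path) {
  Biostrings::writeXStringSet(as_references(x), path)
  invisible(path)
}
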