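#' Simulate a small-RNA sequencing library
#'
#' Emits FASTQ-style reads with the statistical structure of a piRNA
#' library, together with a per-read truth table recording each read's
#' origin. Reads are substrings of the toy references (sense or reverse
#' complement) with the 3' adapter appended and constant base quality
#' (`I`). A tunable fraction of genomic reads is emitted as ping-pong
#' pairs: a sense read whose 5' end sits at genomic position `s` and an
#' antisense partner whose 5' end sits at `s + 9`, i.e. a 10 nt 5' overlap.
#' The 5' base of every insert is forced to `T` with probability `u1_bias`
#' (and to a non-T base otherwise), so the realized 1U fraction is exactly
#' Binomial(n, `u1_bias`); this may introduce a single 5' mismatch against
#' the reference, within the 0-1 mismatch tolerance of the aligner.
#' Contaminant reads are substrings of the annotation references.
#'
#' @param genome a `toy_genome` from [make_toy_genome()] (or a
#'   [Biostrings::DNAStringSet]; multi-mapping placement then requires a
#'   `toy_genome` because repeat coordinates are needed).
#' @param spec a [pirna_library_spec()].
#' @param annotations annotation sets from [make_annotation_sets()];
#'   required when `contaminant_fractions` has positive entries.
#' @return An object of class `sim_library`: list with `reads` (data.frame
#'   `read_id`, `seq`, `qual`), `truth` (data.frame `read_id`, `category`,
#'   `region`, `start` 0-based, `strand`, `length`, `insert`, `partner`)
#'   and `spec`.
#' @examples
#' g <- make_toy_genome(default_genome_spec(seed = 1))
#' lib <- simulate_library(g, pirna_library_spec(n_reads = 100, seed = 2,
#'   contaminant_fractions = numeric(0)))
#' head(lib$truth)
#' @export
simulate_library <- function(genome, spec, annotations = NULL) {
  stopifnot(is(spec, "pirna_library_spec"))
  if (is(genome, "toy_genome")) {
    refs <- genome$sequences
    repeats <- genome$repeats
  } else {
    refs <- as_references(genome)
    repeats <- data.frame(region = character(0), start1 = integer(0),
                          start2 = integer(0), length = integer(0))
  }
  region_seq <- as.character(refs)
  region_len <- nchar(region_seq)
  names(region_len) <- names(region_seq)

  if (length(spec$depletion)) {
    unknown <- setdiff(names(spec$depletion), names(region_seq))
    if (length(unknown))
      stop("depletion names not in genome: ", paste(unknown, collapse = ", "))
  }
  cf <- spec$contaminant_fractions
  cf <- cf[cf > 0]
  if (length(cf) && is.null(annotations))
    stop("contaminant_fractions > 0 require annotation sets")
  depl <- setNames(rep(1, length(region_seq)), names(region_seq))
  depl[names(spec$depletion)] <- spec$depletion
  region_w <- region_len * depl
  if (sum(region_w) <= 0) stop("all regions fully depleted")

  lens <- as.integer(names(spec$size_dist))
  lprob <- as.numeric(spec$size_dist)
  # ping-pong pairs are a 23-28 nt phenomenon; restrict pair lengths there
  pp_keep <- lens >= 23L & lens <= 28L
  pp_lens <- if (any(lprob[pp_keep] > 0)) lens[pp_keep] else lens
  pp_prob <- if (any(lprob[pp_keep] > 0)) lprob[pp_keep] else lprob

  n <- spec$n_reads
  with_seed(spec$seed, {
    cats <- if (length(cf)) {
      sample(c(names(cf), "genomic"), n, replace = TRUE,
             prob = c(cf, 1 - sum(cf)))
    } else rep("genomic", n)
    n_gen <- sum(cats == "genomic")
    n_pairs <- floor(spec$pingpong_fraction * n_gen / 2)
    n_single <- n_gen - 2L * n_pairs

    force_u1 <- function(ins) {
      k <- length(ins)
      if (!k) return(ins)
      first <- ifelse(runif(k) < spec$u1_bias, "T",
                      sample(c("A", "C", "G"), k, replace = TRUE))
      substr(ins, 1L, 1L) <- first
      ins
    }

    blocks <- list()

    if (n_single > 0) {
      ridx <- sample(seq_along(region_seq), n_single, replace = TRUE,
                     prob = region_w)
      len <- sample(lens, n_single, replace = TRUE, prob = lprob)
      strand <- ifelse(runif(n_single) < spec$antisense_fraction, "-", "+")
      L <- region_len[ridx]
      start <- floor(runif(n_single) * (L - len + 1))  # 0-based
      # redirect a fraction into the cluster repeat (guaranteed multi-hit)
      if (nrow(repeats) > 0 && spec$multimap_rate > 0) {
        mm <- runif(n_single) < spec$multimap_rate
        for (j in which(mm)) {
          rr <- repeats[sample(nrow(repeats), 1L), ]
          ridx[j] <- match(rr$region, names(region_seq))
          start[j] <- rr$start1 + floor(runif(1) * (rr$length - len[j] + 1))
        }
      }
      ins <- substr(region_seq[ridx], start + 1L, start + len)
      rc <- strand == "-"
      ins[rc] <- revcomp(ins[rc])
      blocks$single <- data.frame(
        category = "genomic", region = names(region_seq)[ridx],
        start = start, strand = strand, length = len,
        insert = force_u1(ins), partner = NA_character_,
        stringsAsFactors = FALSE)
    }

    if (n_pairs > 0) {
      ridx <- sample(seq_along(region_seq), n_pairs, replace = TRUE,
                     prob = region_w)
      ls <- sample(pp_lens, n_pairs, replace = TRUE, prob = pp_prob)
      la <- sample(pp_lens, n_pairs, replace = TRUE, prob = pp_prob)
      L <- region_len[ridx]
      smin <- pmax(0L, la - 10L)
      smax <- L - ls
      if (any(smax < smin)) stop("regions too short for ping-pong pairs")
      s <- smin + floor(runif(n_pairs) * (smax - smin + 1))
      sense_ins <- substr(region_seq[ridx], s + 1L, s + ls)
      # antisense 5' end at genomic position s + 9: covers [s+10-la, s+10)
      a_start <- s + 10L - la
      anti_ins <- revcomp(substr(region_seq[ridx], a_start + 1L, a_start + la))
      blocks$pair_s <- data.frame(
        category = "pingpong", region = names(region_seq)[ridx],
        start = s, strand = "+", length = ls,
        insert = force_u1(sense_ins), partner = NA_character_,
        stringsAsFactors = FALSE)
      blocks$pair_a <- data.frame(
        category = "pingpong", region = names(region_seq)[ridx],
        start = a_start, strand = "-", length = la,
        insert = force_u1(anti_ins), partner = NA_character_,
        stringsAsFactors = FALSE)
    }

    for (cat in names(cf)) {
      k <- sum(cats == cat)
      if (!k) next
      aset <- as.character(annotations[[cat]])
      sidx <- sample(seq_along(aset), k, replace = TRUE)
      len <- pmin(sample(lens, k, replace = TRUE, prob = lprob),
                  nchar(aset)[sidx])
      start <- floor(runif(k) * (nchar(aset)[sidx] - len + 1))
      ins <- substr(aset[sidx], start + 1L, start + len)
      blocks[[cat]] <- data.frame(
        category = cat, region = names(aset)[sidx], start = start,
        strand = "+", length = len, insert = force_u1(ins),
        partner = NA_character_, stringsAsFactors = FALSE)
    }

    truth <- do.call(rbind, blocks)
    rownames(truth) <- NULL
    truth$read_id <- sprintf("r%06d", seq_len(nrow(truth)))
    if (n_pairs > 0) {
      is_s <- truth$category == "pingpong" & truth$strand == "+"
      is_a <- truth$category == "pingpong" & truth$strand == "-"
      truth$partner[is_s] <- truth$read_id[is_a]
      truth$partner[is_a] <- truth$read_id[is_s]
    }
    truth <- truth[, c("read_id", "category", "region", "start", "strand",
                       "length", "insert", "partner")]
    truth$length <- as.integer(nchar(truth$insert))
    raw <- paste0(truth$insert, spec$adapter)
    reads <- data.frame(read_id = truth$read_id, seq = raw,
                        qual = strrep("I", nchar(raw)),
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, spec = spec),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("Simulated small-RNA library:", nrow(x$reads), "reads\n")
  print(table(x$truth$category))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line FASTQ records with constant `I` qualities.
#'
#' @param x a `sim_library` or data.frame with `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  reads <- if (is(x, "sim_library")) x$reads else x
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  rec <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (uncompressed text).
#' @return data.frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  out <- data.frame(read_id = sub("\\s.*$", "", names(x)),
                    seq = as.character(x),
                    qual = as.character(S4Vectors::mcols(x)$qualities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a truth or observation table as TSV
#'
#' @param x data.frame (e.g. `sim_library$truth` or a gonad table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  if (is(x, "sim_library")) x <- x$truth
  write_tsv(x, path)
}
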