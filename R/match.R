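#' Place reads on a compact reference set
#'
#' Exhaustively reports every placement of each read on both strands of
#' every reference region, allowing 0 or `max_mismatch` mismatches (no
#' indels). A best-stratum rule mirrors common short-read mapper behaviour:
#' a read with at least one 0-mismatch placement reports only its
#' 0-mismatch placements. `n_hits` is the number of retained placements of
#' the read within the profiled region set — the divisor used for
#' multi-mapping weight apportionment downstream.
#'
#' Designed for desk-scale references (total length <= 1e6 nt); the inner
#' sliding-window scan is compiled code, exhaustive over every offset and
#' strand (no seeding heuristic, so no placement can be missed).
#'
#' @param reads collapsed read data.frame from [collapse_reads()] (columns
#'   `read_id`, `seq`, `count`), or a character vector of sequences (counts
#'   default to 1).
#' @param references reference collection: `toy_genome`,
#'   [Biostrings::DNAStringSet] or named character vector, ACGT only.
#' @param max_mismatch 0 or 1 mismatches tolerated.
#' @return data.frame of alignment hits: `read_id`, `region`, `start`
#'   (0-based; the hit occupies `[start, start + length)`), `length`,
#'   `strand` (`"+"`/`"-"`), `mismatches`, `n_hits`, `count`, `seq` (read
#'   sequence in read orientation). Zero rows if nothing places.
#' @examples
#' g <- make_toy_genome(default_genome_spec(seed = 1))
#' s <- substr(as.character(g$sequences[["tel3R"]]), 101, 125)
#' match_reads(s, g)
#' @export
match_reads <- function(reads, references, max_mismatch = 1L) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("q%05d", seq_along(reads)),
                        seq = toupper(reads), count = 1L,
                        stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "seq", "count") %in% names(reads)),
            max_mismatch %in% c(0L, 1L))
  refs <- as_references(references)
  if (sum(Biostrings::width(refs)) > 1e6)
    stop("total reference length exceeds the 1e6 nt desk-scale contract")
  ref_names <- names(refs)

  uniq <- unique(reads$seq)
  raw <- .match_reads_cpp(uniq, as.character(refs), as.integer(max_mismatch))
  empty <- data.frame(read_id = character(0), region = character(0),
                      start = integer(0), length = integer(0),
                      strand = character(0), mismatches = integer(0),
                      n_hits = integer(0), count = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (!length(raw$seq_idx)) return(empty)
  # best stratum: a read with any perfect placement reports only those
  min_mm <- ave(raw$mismatches, raw$seq_idx, FUN = min)
  keep <- raw$mismatches == min_mm
  kept <- lapply(raw, `[`, keep)
  n_hits_seq <- tabulate(kept$seq_idx, nbins = length(uniq))
  # expand unique-sequence hits back to one block per input read
  rows_of_seq <- split(seq_along(kept$seq_idx), kept$seq_idx)
  seq_of_read <- match(reads$seq, uniq)
  blocks <- rows_of_seq[as.character(seq_of_read)]
  nb <- lengths(blocks)
  if (!sum(nb)) return(empty)
  flat <- unlist(blocks, use.names = FALSE)
  ridx <- rep(seq_len(nrow(reads)), nb)
  res <- data.frame(read_id = reads$read_id[ridx],
                    region = ref_names[kept$ref_idx[flat]],
                    start = kept$start[flat],
                    length = nchar(reads$seq[ridx]),
                    strand = c("+", "-")[kept$strand[flat] + 1L],
                    mismatches = kept$mismatches[flat],
                    n_hits = n_hits_seq[seq_of_read[ridx]],
                    count = reads$count[ridx],
                    seq = reads$seq[ridx], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' 5' end genomic position of alignment hits
#'
#' For a `+` hit the 5' end is `start`; for a `-` hit it is
#' `start + length - 1` (0-based genome coordinates).
#'
#' @param hits alignment hit data.frame from [match_reads()].
#' @return integer vector of 0-based 5' end positions.
#' @export
five_prime_pos <- function(hits) {
  ifelse(hits$strand == "+", hits$start, hits$start + hits$length - 1L)
}
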