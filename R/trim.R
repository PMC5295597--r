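#' Trim the 3' sequencing adapter from raw reads
#'
#' Finds, in each raw read, the leftmost occurrence of the adapter — a
#' stretch where the read matches a prefix of the adapter exactly (0
#' mismatches) over at least `min_overlap` bases, either running to the end
#' of the read or covering the full adapter internally — and returns the
#' insert preceding it. Reads are then length-filtered: only inserts of
#' `min_len` to `max_len` nt composed of A/C/G/T pass (the small-RNA window
#' retained for analysis is 19-29 nt).
#'
#' @param raw_seq character vector of raw read sequences.
#' @param adapter 3' adapter sequence (default the TruSeq small-RNA
#'   adapter `TGGAATTCTCGGGTGCCAAG`).
#' @param min_overlap minimum exact adapter prefix length (default 8).
#' @param min_len,max_len retained insert length window (defaults 19, 29).
#' @return data.frame with `raw`, `insert` (`NA` when rejected) and
#'   `status`: `"ok"`, `"no_adapter"`, `"too_short"`, `"too_long"` or
#'   `"non_acgt"`.
#' @examples
#' trim_adapter(paste0(strrep("ACGT", 6), "TGGAATTCTCGGGTGCCAAG"))
#' @export
trim_adapter <- function(raw_seq, adapter = "TGGAATTCTCGGGTGCCAAG",
                         min_overlap = 8L, min_len = 19L, max_len = 29L) {
  adapter <- toupper(adapter)
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  if (grepl("[^ACGT]", adapter)) stop("adapter must be over ACGT")
  raw_seq <- toupper(raw_seq)
  n <- length(raw_seq)
  alen <- nchar(adapter)
  rlen <- nchar(raw_seq)
  cut <- rep(NA_integer_, n)  # insert length = adapter position - 1
  # scan candidate start positions left to right, all reads at once
  for (i in seq_len(max(rlen))) {
    todo <- which(is.na(cut) & rlen >= i + min_overlap - 1L)
    if (!length(todo)) break
    k <- pmin(alen, rlen[todo] - i + 1L)
    hit <- substr(raw_seq[todo], i, i + k - 1L) == substr(adapter, 1L, k)
    cut[todo[hit]] <- i - 1L
  }
  insert <- ifelse(is.na(cut), NA_character_, substr(raw_seq, 1L, cut))
  status <- rep("ok", n)
  status[is.na(cut)] <- "no_adapter"
  ok <- status == "ok"
  status[ok & cut < min_len] <- "too_short"
  status[ok & cut > max_len] <- "too_long"
  ok <- status == "ok"
  status[ok & grepl("[^ACGT]", insert)] <- "non_acgt"
  insert[status != "ok"] <- NA_character_
  data.frame(raw = raw_seq, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

#' Collapse identical inserts into counted unique reads
#'
#' One record per distinct sequence with its occurrence count, the unit on
#' which normalization and multi-mapping weights operate. Records are
#' ordered by decreasing count, ties broken by sequence, so output is
#' deterministic.
#'
#' @param inserts character vector of trimmed insert sequences
#'   (19-29 nt each).
#' @return data.frame with `read_id` (`u` + rank), `seq`, `length`,
#'   `count`; `sum(count) == length(inserts)`.
#' @export
collapse_reads <- function(inserts) {
  if (!length(inserts))
    return(data.frame(read_id = character(0), seq = character(0),
                      length = integer(0), count = integer(0),
                      stringsAsFactors = FALSE))
  lens <- nchar(inserts)
  if (any(lens < 19L | lens > 29L))
    stop("collapse_reads expects filtered inserts of 19-29 nt")
  tab <- table(inserts)
  ord <- order(-as.integer(tab), names(tab))
  seqs <- names(tab)[ord]
  data.frame(read_id = sprintf("u%05d", seq_along(seqs)), seq = seqs,
             length = nchar(seqs), count = as.integer(tab)[ord],
             stringsAsFactors = FALSE)
}

#' Trim, filter and collapse a raw read set in one step
#'
#' @param reads data.frame from [read_fastq()] or character vector of raw
#'   sequences.
#' @inheritParams trim_adapter
#' @return list with `reads` (collapsed read data.frame), `trim`
#'   (per-read trim table) and `attrition` (named counts per status).
#' @export
process_reads <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAG",
                          min_overlap = 8L, min_len = 19L, max_len = 29L) {
  raw <- if (is.data.frame(reads)) reads$seq else reads
  tr <- trim_adapter(raw, adapter, min_overlap, min_len, max_len)
  collapsed <- collapse_reads(tr$insert[tr$status == "ok"])
  list(reads = collapsed, trim = tr,
       attrition = c(input = nrow(tr), table(tr$status)))
}
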