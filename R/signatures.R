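#' Weighted stranded coverage of a region set
#'
#' Each alignment hit deposits `count * norm_factor / n_hits` at every
#' position it covers — occurrence-weighted, with multi-mapping reads
#' apportioned equally across their placements within the profiled region
#' set. Sense hits add positive weight, antisense hits negative weight, so
#' a dual-strand locus shows signal on both sides of zero. Summing the
#' absolute deposited weight of one read over all its hits returns exactly
#' `count * norm_factor` (weight conservation).
#'
#' @param hits alignment hit data.frame ([match_reads()]), restricted to
#'   the region set of interest.
#' @param references the profiled region set (for lengths).
#' @param norm_factor library normalization factor (default 1).
#' @return named list of numeric vectors, one per region, length equal to
#'   the region length; positive = sense, negative = antisense.
#' @export
weighted_coverage <- function(hits, references, norm_factor = 1) {
  refs <- as_references(references)
  lens <- setNames(Biostrings::width(refs), names(refs))
  unknown <- setdiff(unique(hits$region), names(lens))
  if (length(unknown))
    stop("hits reference unknown regions: ", paste(unknown, collapse = ", "))
  if (nrow(hits) &&
      any(hits$start < 0 | hits$start + hits$length > lens[hits$region]))
    stop("hit outside region bounds")
  out <- lapply(names(lens), function(rn) {
    cov <- numeric(lens[[rn]])
    h <- hits[hits$region == rn, , drop = FALSE]
    if (!nrow(h)) return(cov)
    w <- h$count * norm_factor / h$n_hits
    w <- w * ifelse(h$strand == "+", 1, -1)
    idx <- sequence(nvec = h$length, from = h$start + 1L)
    agg <- rowsum(rep(w, times = h$length), idx)
    cov[as.integer(rownames(agg))] <- agg[, 1L]
    cov
  })
  names(out) <- names(lens)
  out
}

#' Coverage as a bedGraph-like table
#'
#' Flattens [weighted_coverage()] output to `region`, `start`, `end`
#' (0-based half-open), `weight`, merging runs of equal weight and
#' dropping zero runs.
#'
#' @param coverage list from [weighted_coverage()].
#' @return data.frame in bedGraph column order.
#' @export
coverage_to_bedgraph <- function(coverage) {
  rows <- lapply(names(coverage), function(rn) {
    v <- coverage[[rn]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(region = rn, start = start[keep], end = end[keep],
               weight = r$values[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(0), start = integer(0),
                      end = integer(0), weight = numeric(0))
  out
}

#' Weighted read-size distribution of a region
#'
#' @param hits alignment hit data.frame.
#' @param region region name, or `NULL` for all hits pooled.
#' @param size_range lengths reported (default 20:29; others excluded).
#' @param norm_factor library normalization factor.
#' @return data.frame `length`, `sense`, `antisense` (weighted counts; one
#'   row per length in `size_range`).
#' @export
size_distribution <- function(hits, region = NULL, size_range = 20:29,
                              norm_factor = 1) {
  h <- if (is.null(region)) hits else hits[hits$region == region, ,
                                           drop = FALSE]
  h <- h[h$length %in% size_range, , drop = FALSE]
  w <- if (nrow(h)) h$count * norm_factor / h$n_hits else numeric(0)
  agg <- function(str) {
    x <- tapply(w[h$strand == str], factor(h$length[h$strand == str],
                                           levels = size_range), sum)
    ifelse(is.na(x), 0, x)
  }
  data.frame(length = size_range, sense = as.numeric(agg("+")),
             antisense = as.numeric(agg("-")))
}

#' 1U bias: fraction of reads beginning with uridine
#'
#' Weighted fraction of in-range reads whose first (5') insert base is `T`
#' (DNA proxy for U), measured on the read sequence regardless of genomic
#' strand. piRNAs loaded on Piwi/Aub show a strong 1U preference.
#'
#' @param hits alignment hit data.frame (needs the `seq` column).
#' @param region region name or `NULL` for all.
#' @param size_range lengths considered (default 23:29).
#' @return fraction in `[0,1]`, or `NA` if no in-range reads.
#' @export
u1_bias <- function(hits, region = NULL, size_range = 23:29) {
  h <- if (is.null(region)) hits else hits[hits$region == region, ,
                                           drop = FALSE]
  h <- h[h$length %in% size_range, , drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  w <- h$count / h$n_hits
  sum(w[substr(h$seq, 1L, 1L) == "T"]) / sum(w)
}

#' Ping-pong 5' overlap histogram
#'
#' For every sense read 5' end at genomic position `s` and antisense read
#' 5' end at position `a` (0-based), the pair overlaps `o = a - s + 1`
#' bases. For each `o` in `1..max_overlap` the histogram accumulates the
#' product of the weighted sense 5'-end count at `s` and the weighted
#' antisense 5'-end count at `a = s + o - 1`, over reads of
#' `size_range` nt. Secondary piRNA biogenesis (the Aub/Ago3 ping-pong
#' cycle) produces a sharp excess at `o = 10`.
#'
#' @param hits alignment hit data.frame restricted to one library.
#' @param region region name or `NULL` for all regions (summed).
#' @param references region set (for lengths).
#' @param size_range read lengths entering the pair count (default 23:28).
#' @param max_overlap largest overlap tallied (default 28).
#' @param norm_factor library normalization factor.
#' @return named numeric vector of pair counts for overlaps
#'   `1..max_overlap`.
#' @export
pingpong_signature <- function(hits, region = NULL, references,
                               size_range = 23:28, max_overlap = 28L,
                               norm_factor = 1) {
  refs <- as_references(references)
  regions <- if (is.null(region)) names(refs) else region
  out <- setNames(numeric(max_overlap), seq_len(max_overlap))
  for (rn in regions) {
    L <- Biostrings::width(refs)[match(rn, names(refs))]
    h <- hits[hits$region == rn & hits$length %in% size_range, ,
              drop = FALSE]
    if (!nrow(h)) next
    w <- h$count * norm_factor / h$n_hits
    fp <- five_prime_pos(h) + 1L  # 1-based index into count vectors
    sense <- numeric(L); anti <- numeric(L)
    sp <- h$strand == "+"
    if (any(sp)) {
      a <- rowsum(w[sp], fp[sp]); sense[as.integer(rownames(a))] <- a[, 1L]
    }
    if (any(!sp)) {
      a <- rowsum(w[!sp], fp[!sp]); anti[as.integer(rownames(a))] <- a[, 1L]
    }
    for (o in seq_len(max_overlap)) {
      if (o > L) break
      out[o] <- out[o] + sum(sense[seq_len(L - o + 1L)] * anti[o:L])
    }
  }
  out
}

#' Ping-pong z-score at overlap 10
#'
#' Standardizes the 10 nt bin against the remaining overlap bins:
#' `z = (hist[10] - mean(hist[-10])) / sd(hist[-10])`. A perfectly flat
#' histogram scores 0; any other zero-spread background (e.g. a single
#' nonzero bin) has no defined scale and returns `NA`.
#'
#' @param overlap_hist numeric vector from [pingpong_signature()] (needs
#'   at least bins 1..10 and >= 2 background bins).
#' @return z-score, or `NA`.
#' @export
pingpong_zscore <- function(overlap_hist) {
  stopifnot(length(overlap_hist) >= 11L)
  bg <- overlap_hist[-10L]
  s <- sd(bg)
  if (!is.finite(s) || s == 0) {
    if (isTRUE(all.equal(unname(overlap_hist[[10L]]), mean(bg)))) return(0)
    return(NA_real_)
  }
  (overlap_hist[[10L]] - mean(bg)) / s
}
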