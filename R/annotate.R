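#' Annotate a small-RNA library and compute its effective depth
#'
#' Matches each collapsed read against the annotation categories and the
#' genomic regions, then assigns every matched read exactly one category by
#' the fixed priority order `miscRNA > tRNA > miRNA > TE > genome_other`.
#' Counts are weighted by collapsed occurrence counts. The effective depth —
#' the denominator used for cross-library normalization — is the number of
#' matched reads that are not abundant cellular RNAs:
#' `total_matched - (miscRNA + tRNA)`.
#'
#' @param reads collapsed read data.frame ([collapse_reads()]).
#' @param genome genomic reference collection (`toy_genome` or
#'   [Biostrings::DNAStringSet]); matched reads not claimed by an
#'   annotation category fall into `genome_other`.
#' @param annotations named list of annotation reference sets in priority
#'   order, e.g. from [make_annotation_sets()]; any subset of `miscRNA`,
#'   `tRNA`, `miRNA`, `TE`.
#' @param max_mismatch mismatches tolerated when placing reads (default 1).
#' @param library_id label carried into the stats row.
#' @return list with `stats` (one-row data.frame: `library_id`,
#'   `total_matched`, one column per category, `unmatched`,
#'   `effective_depth`) and `assignments` (per-read `read_id`, `category`,
#'   `count`).
#' @export
annotate_library <- function(reads, genome, annotations,
                             max_mismatch = 1L, library_id = "lib") {
  priority <- c("miscRNA", "tRNA", "miRNA", "TE")
  annotations <- annotations[intersect(priority, names(annotations))]
  category <- rep(NA_character_, nrow(reads))
  for (cat in names(annotations)) {
    hits <- match_reads(reads, annotations[[cat]], max_mismatch)
    idx <- is.na(category) & reads$read_id %in% hits$read_id
    category[idx] <- cat
  }
  ghits <- match_reads(reads, genome, max_mismatch)
  category[is.na(category) & reads$read_id %in% ghits$read_id] <-
    "genome_other"
  category[is.na(category)] <- "unmatched"

  cats <- c(priority, "genome_other", "unmatched")
  per_cat <- vapply(cats, function(cc) sum(reads$count[category == cc]),
                    numeric(1))
  total_matched <- sum(per_cat[setdiff(cats, "unmatched")])
  eff <- total_matched - per_cat[["miscRNA"]] - per_cat[["tRNA"]]
  stats <- data.frame(library_id = library_id,
                      total_matched = total_matched,
                      as.list(per_cat), effective_depth = eff,
                      stringsAsFactors = FALSE, check.names = FALSE)
  list(stats = stats,
       assignments = data.frame(read_id = reads$read_id, category = category,
                                count = reads$count,
                                stringsAsFactors = FALSE))
}

#' Cross-library normalization factors
#'
#' Effective-depth normalization: the library with the lowest effective
#' depth is the reference (factor exactly 1) and every other library is
#' scaled down by `ref_depth / depth`. A second factor is computed
#' analogously from miRNA counts; it is flagged unusable for libraries
#' whose miRNA fraction of matched reads falls below
#' `mirna_min_fraction` (a library with almost no miRNAs — e.g. a carcass
#' sample at ~3.6% — cannot be normalized on them), and the miRNA
#' reference is the lowest miRNA count among usable libraries.
#'
#' @param stats data.frame with one row per library (rbind of
#'   `annotate_library()$stats`).
#' @param mirna_min_fraction minimum miRNA fraction for the miRNA factor
#'   to be considered usable (default 0.10).
#' @return `stats` with added columns `norm_factor_depth`,
#'   `norm_factor_mirna` (`NA` when unusable) and `mirna_usable`.
#' @export
normalization_factors <- function(stats, mirna_min_fraction = 0.10) {
  stopifnot(nrow(stats) >= 1L)
  if (any(stats$effective_depth <= 0))
    stop("all libraries must have positive effective depth")
  ref_depth <- min(stats$effective_depth)
  stats$norm_factor_depth <- ref_depth / stats$effective_depth
  mirna_frac <- stats$miRNA / stats$total_matched
  stats$mirna_usable <- mirna_frac >= mirna_min_fraction & stats$miRNA > 0
  stats$norm_factor_mirna <- NA_real_
  if (any(stats$mirna_usable)) {
    ref_mirna <- min(stats$miRNA[stats$mirna_usable])
    stats$norm_factor_mirna[stats$mirna_usable] <-
      ref_mirna / stats$miRNA[stats$mirna_usable]
  }
  stats
}

#' Apply a normalization factor to a raw count
#'
#' @param raw non-negative raw count (vectorized).
#' @param factor positive normalization factor.
#' @return `raw * factor`.
#' @export
normalized_count <- function(raw, factor) {
  if (any(raw < 0)) stop("raw counts must be non-negative")
  if (any(factor <= 0)) stop("normalization factor must be positive")
  raw * factor
}
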