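#' Per-transposon antisense normalized counts and RPKM
#'
#' Antisense small-RNA abundance is the working proxy for silencing-capable
#' piRNAs against each transposable element (TE). Counts are weighted by
#' occurrence and multi-mapping apportionment (`count / n_hits`), scaled by
#' the library normalization factor, and converted to RPKM with the
#' library's effective depth as the per-million denominator:
#' `rpkm = normalized_count / (te_length/1000) / (effective_depth/1e6)`.
#'
#' @param hits alignment hits of the library's reads against the TE set.
#' @param te_set TE reference collection (for names and lengths).
#' @param norm_factor library normalization factor.
#' @param effective_depth library effective depth (> 0).
#' @param size_range read lengths counted (default 23:29).
#' @param library_id label.
#' @return data.frame `te`, `length`, `antisense_norm_count`, `rpkm`,
#'   `library_id`, one row per TE in `te_set`.
#' @export
te_antisense_rpkm <- function(hits, te_set, norm_factor = 1,
                              effective_depth, size_range = 23:29,
                              library_id = "lib") {
  refs <- as_references(te_set)
  lens <- setNames(Biostrings::width(refs), names(refs))
  if (any(lens == 0)) stop("TE length 0")
  stopifnot(effective_depth > 0)
  h <- hits[hits$strand == "-" & hits$length %in% size_range, ,
            drop = FALSE]
  w <- if (nrow(h)) h$count / h$n_hits else numeric(0)
  nc <- vapply(names(lens),
               function(te) sum(w[h$region == te]) * norm_factor,
               numeric(1))
  data.frame(te = names(lens), length = as.integer(lens),
             antisense_norm_count = as.numeric(nc),
             rpkm = as.numeric(nc / (lens / 1000) / (effective_depth / 1e6)),
             library_id = library_id, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Knockdown-versus-control TE scatter coordinates
#'
#' For each TE, `x = log2(control + pseudocount)` measures how much piRNA
#' targets it in the control library, and
#' `y = log2((test + pseudocount) / (control + pseudocount))` measures the
#' knockdown effect — the lower the ratio, the stronger the dependency of
#' that TE's piRNAs on the knocked-down gene.
#'
#' @param control,test data.frames from [te_antisense_rpkm()] over the
#'   same TE set.
#' @param pseudocount positive offset guarding zero counts (default 1).
#' @param use `"antisense_norm_count"` (default) or `"rpkm"`.
#' @return data.frame `te`, `log2_control`, `log2_ratio`.
#' @export
glkd_scatter <- function(control, test, pseudocount = 1,
                         use = c("antisense_norm_count", "rpkm")) {
  use <- match.arg(use)
  stopifnot(pseudocount > 0)
  only <- c(setdiff(control$te, test$te), setdiff(test$te, control$te))
  if (length(only))
    stop("TE present in only one table: ", paste(only, collapse = ", "))
  idx <- match(control$te, test$te)
  c0 <- control[[use]] + pseudocount
  t0 <- test[[use]][idx] + pseudocount
  data.frame(te = control$te, log2_control = log2(c0),
             log2_ratio = log2(t0 / c0), stringsAsFactors = FALSE)
}
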