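#' @importFrom methods is
#' @importFrom stats ave rbinom runif sd setNames
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib pirnadev, .registration = TRUE
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce references to a named DNAStringSet; reject non-ACGT letters.
as_references <- function(references, strict_acgt = TRUE) {
  if (is(references, "toy_genome")) references <- references$sequences
  if (is.character(references)) {
    if (is.null(names(references)) || anyDuplicated(names(references)))
      stop("references must have unique names")
    references <- Biostrings::DNAStringSet(references)
  }
  if (!is(references, "DNAStringSet"))
    stop("references must be a DNAStringSet, named character vector, ",
         "or toy_genome")
  if (strict_acgt) {
    freq <- Biostrings::alphabetFrequency(references)
    bad <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T")),
                        drop = FALSE]) > 0
    if (any(bad))
      stop("reference sequences contain non-ACGT characters: ",
           paste(names(references)[bad], collapse = ", "))
  }
  references
}

# Deterministic hash of an R object (config provenance in reports).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
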