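#' Write alignment hits as a SAM file
#'
#' Minimal SAM dialect: `@HD`/`@SQ` header, the 11 mandatory fields, FLAG
#' bits 4 and 16, CIGAR `<len>M`, and `NM`/`NH` tags. The SEQ field is
#' stored in reference-forward orientation (reverse-complemented for
#' minus-strand hits), per the SAM convention.
#'
#' @param hits alignment hit data.frame from [match_reads()].
#' @param references the reference collection the hits were made against
#'   (for `@SQ` lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, references, path) {
  refs <- as_references(references)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs),
                   Biostrings::width(refs)))
  if (nrow(hits)) {
    seq_fwd <- hits$seq
    neg <- hits$strand == "-"
    seq_fwd[neg] <- revcomp(seq_fwd[neg])
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                   hits$read_id, ifelse(neg, 16L, 0L), hits$region,
                   hits$start + 1L, hits$length, seq_fwd, hits$mismatches,
                   hits$n_hits)
  } else rec <- character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Import alignments from a SAM file
#'
#' Reads single-segment, unspliced SAM records (CIGAR `<len>M`) into the
#' internal alignment-hit representation: 1-based SAM `POS` becomes the
#' 0-based `start`, FLAG bit 16 becomes strand `-`, and the stored
#' sequence is reverse-complemented back to read orientation for
#' minus-strand records. Mismatch counts are taken from the `NM` tag
#' (0 when absent). Multi-mapping counts come from the `NH` tag when
#' present; otherwise they are recomputed as the number of imported
#' placements of each read within `region_set`.
#'
#' Parsing is delegated to Rsamtools after a light structural pre-scan
#' that reports malformed records by line number.
#'
#' @param path SAM file path.
#' @param region_set optional character vector restricting hits (and the
#'   recomputed `n_hits`) to these reference names; default all.
#' @param reads optional collapsed read data.frame supplying `count` per
#'   `read_id` (default count 1).
#' @return alignment hit data.frame as from [match_reads()].
#' @export
import_sam <- function(path, region_set = NULL, reads = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 11L))
    stop("malformed SAM record at line ", body[which(nfield < 11L)[1L]],
         ": fewer than 11 fields")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
    tag = c("NM", "NH"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(b$flag, 4L)
  if (!any(mapped))
    return(match_reads(character(0), Biostrings::DNAStringSet()))
  cigar <- b$cigar[mapped]
  if (any(!grepl("^\\d+M$", cigar)))
    stop("import_sam supports only single-segment unspliced records ",
         "(CIGAR <len>M); offending CIGAR: ",
         cigar[which(!grepl("^\\d+M$", cigar))[1L]])
  len <- as.integer(sub("M$", "", cigar))
  strand <- ifelse(bitwAnd(b$flag[mapped], 16L) > 0L, "-", "+")
  seq <- as.character(b$seq)[mapped]
  seq[strand == "-"] <- revcomp(seq[strand == "-"])
  h <- data.frame(read_id = b$qname[mapped],
                  region = as.character(b$rname)[mapped],
                  start = b$pos[mapped] - 1L, length = len, strand = strand,
                  mismatches = {
                    nm <- b$tag$NM[mapped]
                    if (is.null(nm)) rep(0L, sum(mapped))
                    else ifelse(is.na(nm), 0L, as.integer(nm))
                  },
                  seq = seq, stringsAsFactors = FALSE)
  nh <- b$tag$NH[mapped]
  h$n_hits <- if (is.null(nh)) NA_integer_ else as.integer(nh)
  if (!is.null(region_set)) {
    h <- h[h$region %in% region_set, , drop = FALSE]
    h$n_hits <- NA_integer_  # NH scope unknown once restricted; recompute
  }
  if (anyNA(h$n_hits)) {
    tab <- table(h$read_id)
    h$n_hits <- as.integer(tab[h$read_id])
  }
  counts <- if (!is.null(reads)) setNames(reads$count, reads$read_id)
  h$count <- if (is.null(counts)) 1L else {
    cc <- counts[h$read_id]
    ifelse(is.na(cc), 1L, as.integer(cc))
  }
  rownames(h) <- NULL
  h[, c("read_id", "region", "start", "length", "strand", "mismatches",
        "n_hits", "count", "seq")]
}
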