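# Shared fixtures and independent oracles. Oracles are deliberately
# written in plain R, without touching the code paths they check.

tiny_genome <- function(seed = 1L) make_toy_genome(default_genome_spec(seed))

# Single 2 kb cluster world: fast to align against, still multimappable.
small_world <- function(seed = 1L) {
  make_toy_genome(toy_genome_spec(
    regions = data.frame(name = "cluster", length = 2000L,
                         role = "dual_strand_cluster"),
    seed = seed))
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

str_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(lapply(strsplit(x, ""), rev), paste,
                                character(1), collapse = ""))
}

# Exhaustive sliding-window aligner: every offset, both strands, mismatch
# count by vectorized integer comparison; best stratum applied at the end.
oracle_match <- function(seqs, ref_chr, max_mm) {
  stopifnot(length(ref_chr) == 1L)
  ref_int <- utf8ToInt(ref_chr)
  L <- length(ref_int)
  hits <- list()
  for (i in seq_along(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[i] else str_revcomp(seqs[i])
      p <- utf8ToInt(s)
      len <- length(p)
      if (len > L) next
      n_off <- L - len + 1L
      win <- matrix(ref_int[outer(seq_len(len) - 1L, seq_len(n_off), "+")],
                    nrow = len)
      mm <- colSums(win != p)
      ok <- which(mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          idx = i, start = ok - 1L, strand = strand,
          mismatches = as.integer(mm[ok]))
    }
  }
  if (!length(hits))
    return(data.frame(idx = integer(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  h <- do.call(rbind, hits)
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$idx), function(ii) {
    if (any(h$mismatches[ii] == 0L)) ii[h$mismatches[ii] == 0L] else ii
  }))
  h <- h[sort(keep), , drop = FALSE]
  h[order(h$idx, h$strand, h$start), ]
}

# O(n^2) double loop over hit pairs: the brute-force ping-pong pair count.
oracle_pingpong <- function(hits, region, size_range = 23:28,
                            max_overlap = 28L) {
  h <- hits[hits$region == region & hits$length %in% size_range, ,
            drop = FALSE]
  out <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (!nrow(h)) return(out)
  w <- h$count / h$n_hits
  fp <- ifelse(h$strand == "+", h$start, h$start + h$length - 1L)
  for (i in seq_len(nrow(h))) {
    if (h$strand[i] != "+") next
    for (j in seq_len(nrow(h))) {
      if (h$strand[j] != "-") next
      o <- fp[j] - fp[i] + 1L
      if (o >= 1L && o <= max_overlap) out[o] <- out[o] + w[i] * w[j]
    }
  }
  out
}

# Exact homogeneous-clone probability under the resampling plastic model:
# enumerate every resample history of the binary division tree (heap
# indexing, non-root nodes carry a resample bit). Leaves sharing their
# most recent resampled ancestor share one Bernoulli(r) draw.
oracle_plastic_homog <- function(r, switch_rate, divisions) {
  n_nodes <- 2L^(divisions + 1L) - 1L
  leaves <- (2L^divisions):(2L^(divisions + 1L) - 1L)
  edges <- 2:n_nodes
  total <- 0
  for (mask in 0:(2L^length(edges) - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_along(edges)]
    p_mask <- prod(ifelse(bits == 1L, switch_rate, 1 - switch_rate))
    if (p_mask == 0) next
    origin <- vapply(leaves, function(lf) {
      node <- lf
      while (node > 1L && bits[node - 1L] == 0L) node <- node %/% 2L
      node
    }, integer(1))
    m <- length(unique(origin))
    total <- total + p_mask * (r^m + (1 - r)^m)
  }
  total
}

# Exhaustive ovariole phenotype distribution: enumerate GSC counts, GFP
# and beta-GAL assignments (per-chamber under plastic), classify each.
oracle_ovariole_freq <- function(p_two_gsc, r, flipout, model,
                                 cysts_per_gsc = 3L) {
  levs <- c("overlap", "exclusion", "mixed3", "mixed4", "uninformative")
  acc <- setNames(numeric(5), levs)
  for (n_gsc in 2:3) {
    p_n <- if (n_gsc == 2L) p_two_gsc else 1 - p_two_gsc
    if (p_n == 0) next
    for (gmask in 0:(2L^n_gsc - 1L)) {
      gfp_gsc <- as.integer(intToBits(gmask))[seq_len(n_gsc)] == 1L
      p_g <- prod(ifelse(gfp_gsc, flipout, 1 - flipout))
      if (p_g == 0) next
      n_b <- if (model == "lock") n_gsc else n_gsc * cysts_per_gsc
      for (bmask in 0:(2L^n_b - 1L)) {
        bgal_units <- as.integer(intToBits(bmask))[seq_len(n_b)] == 1L
        p_b <- prod(ifelse(bgal_units, 1 - r, r))  # bGAL+ iff not repressed
        if (p_b == 0) next
        gfp <- rep(gfp_gsc, each = cysts_per_gsc)
        bgal <- if (model == "lock") rep(bgal_units, each = cysts_per_gsc)
                else bgal_units
        ph <- classify_ovariole(gfp, bgal)
        acc[ph] <- acc[ph] + p_n * p_g * p_b
      }
    }
  }
  inf <- acc[1:4]
  inf / sum(inf)
}
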