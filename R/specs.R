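#' Toy genome specification
#'
#' Describes a compact reference collection standing in for the profiled
#' loci of a piRNA study: a dual-strand piRNA cluster, a subtelomeric
#' region, a reporter transgene, or any other region. Dual-strand cluster
#' regions are guaranteed to contain an exact internal repeat so that
#' multi-mapping reads can be simulated.
#'
#' @param regions data.frame with columns `name` (unique), `length`
#'   (>= 200 nt) and `role` (one of `"dual_strand_cluster"`,
#'   `"subtelomere"`, `"transgene"`, `"other"`).
#' @param gc_fraction base composition: probability that a position is G or
#'   C. Default 0.43, a typical genome-wide GC content for an insect genome.
#' @param seed integer seed controlling sequence generation.
#' @return An object of class `toy_genome_spec`.
#' @seealso [make_toy_genome()]
#' @export
toy_genome_spec <- function(regions, gc_fraction = 0.43, seed = 1L) {
  if (is.list(regions) && !is.data.frame(regions))
    regions <- do.call(rbind, lapply(regions, as.data.frame))
  stopifnot(is.data.frame(regions),
            all(c("name", "length", "role") %in% names(regions)))
  regions$name <- as.character(regions$name)
  regions$length <- as.integer(regions$length)
  regions$role <- as.character(regions$role)
  if (anyDuplicated(regions$name)) stop("region names must be unique")
  if (any(regions$length < 200L)) stop("region lengths must be >= 200 nt")
  ok_roles <- c("dual_strand_cluster", "subtelomere", "transgene", "other")
  if (!all(regions$role %in% ok_roles))
    stop("region role must be one of: ", paste(ok_roles, collapse = ", "))
  if (!is_fraction(gc_fraction)) stop("gc_fraction must be in [0,1]")
  structure(list(regions = regions, gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "toy_genome_spec")
}

#' Default toy genome layout
#'
#' Three profiled loci mirroring the shape of a typical piRNA-cluster study:
#' a 5 kb dual-strand cluster, a 3 kb subtelomeric region and a 2 kb
#' reporter transgene.
#'
#' @inheritParams toy_genome_spec
#' @return A `toy_genome_spec`.
#' @export
default_genome_spec <- function(seed = 1L, gc_fraction = 0.43) {
  toy_genome_spec(
    regions = data.frame(
      name   = c("cluster42", "tel3R", "transgeneRS"),
      length = c(5000L, 3000L, 2000L),
      role   = c("dual_strand_cluster", "subtelomere", "transgene")),
    gc_fraction = gc_fraction, seed = seed)
}

#' Small-RNA library simulation parameters
#'
#' Parameters of a synthetic piRNA-like small-RNA library. Reads are genomic
#' substrings (sense or antisense) with a sequencing adapter appended; a
#' tunable fraction is emitted as ping-pong pairs whose 5' ends sit exactly
#' 10 nt apart on opposite strands, and contaminant reads are drawn from
#' annotation reference sets (miRNA, rRNA/snoRNA "miscRNA", tRNA).
#'
#' Defaults describe a healthy germline piRNA library: a size distribution
#' peaking at 25-26 nt within 23-29 nt, strong 1U bias (0.75), roughly
#' strand-balanced cluster output, a moderate ping-pong fraction and modest
#' contamination.
#'
#' @param n_reads number of reads to emit.
#' @param size_dist named numeric vector of probabilities over read lengths;
#'   names must be lengths in 19..29 and probabilities must sum to 1.
#' @param pingpong_fraction fraction of genomic reads emitted as members of
#'   10-nt 5'-overlap sense/antisense pairs.
#' @param u1_bias probability that a read's 5' base is U (T in DNA space).
#' @param antisense_fraction probability that a non-pair genomic read is
#'   antisense to the reference.
#' @param contaminant_fractions named fractions for `miRNA`, `miscRNA`,
#'   `tRNA` contaminant reads; must sum to <= 1 together (remainder of the
#'   library is genomic).
#' @param multimap_rate fraction of single genomic reads drawn from inside a
#'   cluster's internal repeat, guaranteeing multiple placements.
#' @param depletion named multiplicative factors in `[0,1]` applied to region
#'   sampling weights (a germline-knockdown effect: 0.1 means the region
#'   yields 10x fewer reads).
#' @param adapter 3' sequencing adapter appended to every read
#'   (>= 10 nt).
#' @param seed integer seed.
#' @return An object of class `pirna_library_spec`.
#' @seealso [simulate_library()]
#' @export
pirna_library_spec <- function(n_reads = 10000L,
                               size_dist = default_size_dist(),
                               pingpong_fraction = 0.3,
                               u1_bias = 0.75,
                               antisense_fraction = 0.5,
                               contaminant_fractions = c(miRNA = 0.05,
                                                         miscRNA = 0.05,
                                                         tRNA = 0.02),
                               multimap_rate = 0.1,
                               depletion = numeric(0),
                               adapter = "TGGAATTCTCGGGTGCCAAG",
                               seed = 1L) {
  stopifnot(is_count(n_reads, min = 1L))
  lens <- as.integer(names(size_dist))
  if (any(is.na(lens)) || any(lens < 19L | lens > 29L))
    stop("size_dist names must be read lengths in 19..29")
  if (any(size_dist < 0) || abs(sum(size_dist) - 1) > 1e-8)
    stop("size_dist probabilities must be non-negative and sum to 1")
  for (f in c(pingpong_fraction, u1_bias, antisense_fraction, multimap_rate))
    if (!is_fraction(f)) stop("fractions must be in [0,1]")
  if (length(contaminant_fractions)) {
    if (!all(names(contaminant_fractions) %in% c("miRNA", "miscRNA", "tRNA")))
      stop("contaminant categories must be miRNA, miscRNA, tRNA")
    if (any(contaminant_fractions < 0) || sum(contaminant_fractions) > 1)
      stop("contaminant fractions must be >= 0 and sum to <= 1")
  }
  if (length(depletion)) {
    if (is.null(names(depletion)) || !all(nzchar(names(depletion))))
      stop("depletion must be a named vector of region factors")
    if (!all(depletion >= 0 & depletion <= 1))
      stop("depletion factors must be in [0,1]")
  }
  adapter <- toupper(adapter)
  if (nchar(adapter) < 10L || grepl("[^ACGT]", adapter))
    stop("adapter must be >= 10 nt over ACGT")
  structure(list(n_reads = as.integer(n_reads), size_dist = size_dist,
                 pingpong_fraction = pingpong_fraction, u1_bias = u1_bias,
                 antisense_fraction = antisense_fraction,
                 contaminant_fractions = contaminant_fractions,
                 multimap_rate = multimap_rate, depletion = depletion,
                 adapter = adapter, seed = as.integer(seed)),
            class = "pirna_library_spec")
}

#' Default piRNA read-length distribution
#'
#' A unimodal distribution over 23-29 nt peaking at 25-26 nt, the canonical
#' piRNA size range. Figure-only in the source literature, so these weights
#' are a package choice, not measured values.
#'
#' @return named numeric vector of probabilities summing to 1.
#' @export
default_size_dist <- function() {
  p <- c(`23` = 0.06, `24` = 0.13, `25` = 0.24, `26` = 0.24, `27` = 0.17,
         `28` = 0.11, `29` = 0.05)
  p / sum(p)
}

#' Gonad clone simulation parameters
#'
#' Parameters of a clonal lineage simulation of primordial germ cells
#' (PGCs). Each gonad starts with `pgc_init` embryonic PGCs; each is
#' independently repressed with probability `r` and carries a heritable
#' flip-out lineage label (GFP) with probability `flipout_prob`. PGCs then
#' undergo `divisions` rounds of mitosis. Under the `lock` model the
#' repression state is copied to daughters; under the `plastic` model each
#' daughter, with probability `switch_rate` per division, re-draws its state
#' from Bernoulli(`r`) — at `switch_rate = 1` final states are fully
#' independent with marginal `r`, the plastic-repression null.
#'
#' Defaults are the biology of the assay: ~10 PGCs per late-embryonic gonad,
#' ~3 mitoses between embryo and late third instar (so clones of
#' 2^3 = 8 cells), and a mean repression fraction r = 0.6647.
#'
#' @param n_gonads number of gonads to simulate.
#' @param pgc_init embryonic PGCs per gonad (default 10).
#' @param divisions mitoses between embryo and observation (default 3).
#' @param r repression fraction in `[0,1]` (default 0.6647).
#' @param model `"lock"` (state inherited) or `"plastic"` (state re-drawn).
#' @param switch_rate per-division probability that a daughter re-draws its
#'   repression state (plastic only; the lock model forces 0).
#' @param flipout_prob probability that an embryonic PGC is GFP-labelled.
#' @param seed integer seed.
#' @return An object of class `clone_sim_spec`.
#' @seealso [simulate_clones()]
#' @export
clone_sim_spec <- function(n_gonads = 100L, pgc_init = 10L, divisions = 3L,
                           r = 0.6647, model = c("lock", "plastic"),
                           switch_rate = 0, flipout_prob = 0.1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(is_count(n_gonads, 1L), is_count(pgc_init, 1L),
            is_count(divisions, 0L))
  if (!is_fraction(r)) stop("r must be in [0,1]")
  if (!is_fraction(switch_rate)) stop("switch_rate must be in [0,1]")
  if (!is_fraction(flipout_prob)) stop("flipout_prob must be in [0,1]")
  if (model == "lock" && switch_rate != 0)
    stop("lock model implies switch_rate = 0")
  structure(list(n_gonads = as.integer(n_gonads),
                 pgc_init = as.integer(pgc_init),
                 divisions = as.integer(divisions), r = r, model = model,
                 switch_rate = switch_rate, flipout_prob = flipout_prob,
                 seed = as.integer(seed)),
            class = "clone_sim_spec")
}

#' @export
print.toy_genome_spec <- function(x, ...) {
  cat("Toy genome spec:", nrow(x$regions), "region(s), GC",
      x$gc_fraction, "\n")
  print(x$regions)
  invisible(x)
}

#' @export
print.pirna_library_spec <- function(x, ...) {
  cat(sprintf(
    "piRNA library spec: %d reads, ping-pong %.2f, 1U %.2f, seed %d\n",
    x$n_reads, x$pingpong_fraction, x$u1_bias, x$seed))
  invisible(x)
}

#' @export
print.clone_sim_spec <- function(x, ...) {
  cat(sprintf(
    "Clone sim spec: %d gonads x %d PGCs, %d divisions, r=%.4f, %s model\n",
    x$n_gonads, x$pgc_init, x$divisions, x$r, x$model))
  invisible(x)
}
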