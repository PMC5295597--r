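#' Percentage of repressed germ cells
#'
#' Repression of the reporter is scored as the number of repressed PGCs
#' (GFP-negative cells) divided by the total number of PGCs counted
#' (VASA-positive cells), as a percentage.
#'
#' @param total_pgc total PGCs counted (> 0).
#' @param gfp_positive number of reporter-expressing (non-repressed) cells;
#'   must not exceed `total_pgc`.
#' @return percentage in `[0, 100]` (vectorized).
#' @examples
#' repression_percent(100, 10)  # 90
#' @export
repression_percent <- function(total_pgc, gfp_positive) {
  if (any(total_pgc <= 0)) stop("total_pgc must be > 0")
  if (any(gfp_positive > total_pgc) || any(gfp_positive < 0))
    stop("gfp_positive must be in [0, total_pgc]")
  100 * (total_pgc - gfp_positive) / total_pgc
}

#' Is a gonad's βGAL staining compatible with clonal homogeneity?
#'
#' Under the epigenetic-lock hypothesis, all descendants of one embryonic
#' GFP-labelled PGC share a repression state, so among the GFP-positive
#' cells of a gonad the βGAL-positive count should be 0 (one fully
#' repressed clone), equal to the GFP-positive count (one fully expressing
#' clone), or exactly half of it (two homogeneous clones of equal size,
#' the 50:50 case). Any other split is scored incompatible — even when a
#' three-clone or unequal-division explanation exists.
#'
#' @param gfp_pos_cells GFP-positive (lineage-labelled) cell count per
#'   gonad (>= 1; vectorized).
#' @param bgal_pos_among_gfp βGAL-positive cells among those.
#' @return character vector, `"compatible"` or `"incompatible"`.
#' @examples
#' classify_clone_homogeneity(8, 8)    # compatible
#' classify_clone_homogeneity(14, 5)   # incompatible
#' @export
classify_clone_homogeneity <- function(gfp_pos_cells, bgal_pos_among_gfp) {
  if (any(gfp_pos_cells < 1)) stop("gfp_pos_cells must be >= 1")
  if (any(bgal_pos_among_gfp > gfp_pos_cells) || any(bgal_pos_among_gfp < 0))
    stop("bgal_pos_among_gfp must be in [0, gfp_pos_cells]")
  ok <- bgal_pos_among_gfp == 0 | bgal_pos_among_gfp == gfp_pos_cells |
    (gfp_pos_cells %% 2 == 0 & bgal_pos_among_gfp == gfp_pos_cells / 2)
  ifelse(ok, "compatible", "incompatible")
}

#' Closed-form probability of the observed clone states under the
#' plastic-repression null
#'
#' If the repression state of every PGC is completely independent
#' (the extreme plastic hypothesis) with repression probability `r`, then
#' a clone of `k` cells is all-repressed with probability `r^k` and
#' all-expressing with probability `(1-r)^k`. Observing `g_plus`
#' all-repressed clones and `g_minus` all-expressing clones therefore has
#' probability `P = (r^k)^g_plus * ((1-r)^k)^g_minus`. Computed in log
#' space to survive magnitudes around 1e-22.
#'
#' @param r repression fraction in `[0,1]`.
#' @param k clone size (cells per clone).
#' @param g_plus number of all-repressed clones.
#' @param g_minus number of all-expressing (non-repressed) clones.
#' @return list with `probability` and `log10_probability` (`-Inf` when
#'   the probability is 0, e.g. `r = 1` with `g_minus > 0`).
#' @examples
#' plastic_null_probability(0.6647, 8, 7, 3)$probability  # ~4.76e-22
#' @export
plastic_null_probability <- function(r, k, g_plus, g_minus) {
  stopifnot(is_fraction(r), is_count(k, 1L), is_count(g_plus, 0L),
            is_count(g_minus, 0L))
  terms <- c(
    if (g_plus > 0) k * g_plus * log(r) else 0,
    if (g_minus > 0) k * g_minus * log1p(-r) else 0)
  lp <- sum(terms)  # log(0) = -Inf propagates correctly at r in {0,1}
  list(probability = exp(lp), log10_probability = lp / log(10))
}

#' Classify an ovariole's egg-chamber staining pattern
#'
#' An ovariole is informative only if its egg chambers are heterogeneous
#' for both the GFP lineage label and the βGAL repression reporter. The
#' distinct (GFP, βGAL) states then define the phenotype: two states that
#' are (+,+)/(−,−) are an `overlap` pattern, two states that are
#' (+,−)/(−,+) are an `exclusion` pattern — both expected when each
#' germline stem cell transmits a fixed repression state — while three or
#' four distinct states (`mixed3`, `mixed4`) indicate states decoupled
#' from lineage.
#'
#' @param gfp logical vector of per-egg-chamber GFP states (>= 2
#'   chambers).
#' @param bgal logical vector of per-egg-chamber βGAL states, same
#'   length.
#' @return one of `"overlap"`, `"exclusion"`, `"mixed3"`, `"mixed4"`,
#'   `"uninformative"`.
#' @examples
#' classify_ovariole(c(TRUE, FALSE), c(TRUE, FALSE))   # overlap
#' classify_ovariole(c(TRUE, FALSE), c(FALSE, TRUE))   # exclusion
#' @export
classify_ovariole <- function(gfp, bgal) {
  stopifnot(length(gfp) == length(bgal), length(gfp) >= 2L,
            is.logical(gfp), is.logical(bgal))
  if (length(unique(gfp)) < 2L || length(unique(bgal)) < 2L)
    return("uninformative")
  states <- unique(paste0(ifelse(gfp, "+", "-"), ifelse(bgal, "+", "-")))
  if (length(states) == 2L) {
    if (setequal(states, c("++", "--"))) return("overlap")
    if (setequal(states, c("+-", "-+"))) return("exclusion")
    # two states sharing a marker value are impossible here: that marker
    # would be homogeneous and the ovariole uninformative
    stop("unreachable two-state combination: ",
         paste(states, collapse = ","))
  }
  if (length(states) == 3L) "mixed3" else "mixed4"
}

#' Classify a long-format ovariole observation table
#'
#' @param obs data.frame with columns `ovariole_id`, `gfp`, `bgal`
#'   (logical or 0/1), one row per egg chamber.
#' @return data.frame `ovariole_id`, `phenotype`.
#' @export
classify_ovariole_table <- function(obs) {
  stopifnot(all(c("ovariole_id", "gfp", "bgal") %in% names(obs)))
  ids <- unique(obs$ovariole_id)
  data.frame(
    ovariole_id = ids,
    phenotype = vapply(ids, function(i) {
      x <- obs[obs$ovariole_id == i, ]
      classify_ovariole(as.logical(x$gfp), as.logical(x$bgal))
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected ovariole phenotype distribution under lock or plastic
#' repression
#'
#' Monte-Carlo simulation of adult ovarioles. Each germarium carries two
#' germline stem cells (GSCs) with probability `p_two_gsc`, otherwise
#' three. Every GSC is independently GFP-labelled (probability `flipout`)
#' and repressed (probability `r`; βGAL-positive iff not repressed). Each
#' GSC emits `cysts_per_gsc` egg chambers: under the `lock` model every
#' chamber copies its GSC's states; under the `plastic` model the βGAL
#' state of each chamber is re-drawn independently from Bernoulli(`1 - r`)
#' while GFP (a true lineage label) is still copied. Phenotype frequencies
#' are reported over informative ovarioles. With at most three GSCs the
#' lock model can never produce a four-state ovariole.
#'
#' @param p_two_gsc probability a germarium has two (not three) GSCs
#'   (default 0.5, as estimated by spectrosome staining).
#' @param r repression fraction (default 0.6647).
#' @param flipout per-GSC GFP labelling probability (default 0.5, the
#'   late-larval heat-shock regime).
#' @param model `"lock"` or `"plastic"`.
#' @param n_sim number of ovarioles (>= 1).
#' @param seed integer seed.
#' @param cysts_per_gsc egg chambers observed per GSC lineage (default 3).
#' @return list with `frequencies` (named frequencies over informative
#'   ovarioles: overlap, exclusion, mixed3, mixed4), `counts` (including
#'   uninformative) and `n_informative`.
#' @export
expected_ovariole_distribution <- function(p_two_gsc = 0.5, r = 0.6647,
                                           flipout = 0.5,
                                           model = c("lock", "plastic"),
                                           n_sim = 10000L, seed = 1L,
                                           cysts_per_gsc = 3L) {
  model <- match.arg(model)
  stopifnot(is_fraction(p_two_gsc), is_fraction(r), is_fraction(flipout),
            is_count(n_sim, 1L), is_count(cysts_per_gsc, 1L))
  levs <- c("overlap", "exclusion", "mixed3", "mixed4", "uninformative")
  with_seed(seed, {
    phen <- vapply(seq_len(n_sim), function(i) {
      n_gsc <- if (runif(1) < p_two_gsc) 2L else 3L
      gsc_gfp <- runif(n_gsc) < flipout
      gsc_bgal <- runif(n_gsc) >= r  # expressed iff not repressed
      gfp <- rep(gsc_gfp, each = cysts_per_gsc)
      bgal <- if (model == "lock") rep(gsc_bgal, each = cysts_per_gsc)
              else runif(n_gsc * cysts_per_gsc) >= r
      classify_ovariole(gfp, bgal)
    }, character(1))
    counts <- table(factor(phen, levels = levs))
    informative <- phen[phen != "uninformative"]
    freq <- if (length(informative))
      table(factor(informative, levels = levs[1:4])) / length(informative)
    else setNames(rep(NA_real_, 4L), levs[1:4])
    list(frequencies = as.numeric(freq) |>
           setNames(levs[1:4]),
         counts = counts, n_informative = length(informative))
  })
}

#' Summarize a gonad observation table under the clonal-memory test
#'
#' Applies [classify_clone_homogeneity()] to every gonad, reports the
#' compatible fraction, and evaluates the plastic null for the subset of
#' gonads carrying a single clone of exactly `k` GFP-positive cells
#' (all-repressed clones contribute `g_plus`, all-expressing clones
#' `g_minus`).
#'
#' @param obs data.frame with `gonad_id`, `gfp_pos_cells`,
#'   `bgal_pos_among_gfp` (e.g. from [tally_gonads()] or a TSV).
#' @param r repression fraction for the null (default 0.6647).
#' @param k single-clone size for the null (default 8 = one embryonic PGC
#'   after 3 divisions).
#' @return list with `classification` (obs + `compatible` column),
#'   `compatible_fraction`, `single_clone_tally`
#'   (`g_plus`/`g_minus`/`other` among gonads with `k` GFP+ cells),
#'   `plastic_null` (from [plastic_null_probability()], `NULL` when no
#'   such gonads) and `n_excluded_no_gfp` (gonads dropped for carrying no
#'   GFP-labelled cell — a real experiment cannot score them).
#' @export
clone_memory_test <- function(obs, r = 0.6647, k = 8L) {
  stopifnot(all(c("gonad_id", "gfp_pos_cells", "bgal_pos_among_gfp") %in%
                  names(obs)))
  n_no_gfp <- sum(obs$gfp_pos_cells == 0)
  obs <- obs[obs$gfp_pos_cells > 0, , drop = FALSE]
  if (!nrow(obs)) stop("no gonad carries a GFP-labelled cell")
  cls <- classify_clone_homogeneity(obs$gfp_pos_cells,
                                    obs$bgal_pos_among_gfp)
  obs$compatible <- cls
  single <- obs[obs$gfp_pos_cells == k, , drop = FALSE]
  g_plus <- sum(single$bgal_pos_among_gfp == 0)
  g_minus <- sum(single$bgal_pos_among_gfp == k)
  null <- if (nrow(single))
    plastic_null_probability(r, k, g_plus, g_minus) else NULL
  list(classification = obs,
       compatible_fraction = mean(cls == "compatible"),
       single_clone_tally = c(g_plus = g_plus, g_minus = g_minus,
                              other = nrow(single) - g_plus - g_minus),
       plastic_null = null, n_excluded_no_gfp = n_no_gfp)
}
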