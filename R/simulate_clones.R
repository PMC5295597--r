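#' Simulate clonal repression states in developing gonads
#'
#' Lineage simulation of primordial germ cells (PGCs). Each gonad starts
#' with `pgc_init` embryonic PGCs; each founder is independently assigned a
#' repression state (repressed with probability `r`) and a heritable
#' flip-out lineage label (GFP-positive with probability `flipout_prob`,
#' inherited clonally). Founders then divide `divisions` times. Under the
#' `lock` model daughters copy the repression state; under the `plastic`
#' model each daughter re-draws its state from Bernoulli(`r`) with
#' probability `switch_rate` at every division (at `switch_rate = 1` the
#' final cell states are fully independent — the plastic-repression null).
#'
#' The βGAL reporter is silenced in repressed cells, so a cell is
#' βGAL-positive iff it is not repressed. The clone id is ground truth
#' that a real experiment cannot observe; classification operations (see
#' [tally_gonads()], [classify_clone_homogeneity()]) must not read it.
#'
#' @param spec a [clone_sim_spec()].
#' @return data.frame with one row per cell: `gonad`, `clone` (embryonic
#'   founder index within the gonad), `cell`, `gfp` (logical flip-out
#'   label), `repressed` (logical repression state). Each gonad has
#'   `pgc_init * 2^divisions` rows.
#' @examples
#' cells <- simulate_clones(clone_sim_spec(n_gonads = 5, seed = 3))
#' table(cells$repressed) / nrow(cells)
#' @export
simulate_clones <- function(spec) {
  stopifnot(is(spec, "clone_sim_spec"))
  n_found <- spec$n_gonads * spec$pgc_init
  clone_size <- 2L^spec$divisions
  with_seed(spec$seed, {
    founder_state <- runif(n_found) < spec$r
    founder_gfp <- runif(n_found) < spec$flipout_prob
    # expand generation by generation; each row is one current cell
    state <- founder_state
    if (spec$divisions > 0) {
      for (d in seq_len(spec$divisions)) {
        state <- rep(state, each = 2L)
        if (spec$model == "plastic" && spec$switch_rate > 0) {
          resample <- runif(length(state)) < spec$switch_rate
          state[resample] <- runif(sum(resample)) < spec$r
        }
      }
    }
    founder_of_cell <- rep(seq_len(n_found), each = clone_size)
    data.frame(
      gonad = (founder_of_cell - 1L) %/% spec$pgc_init + 1L,
      clone = (founder_of_cell - 1L) %% spec$pgc_init + 1L,
      cell = sequence(rep(clone_size, n_found)),
      gfp = founder_gfp[founder_of_cell],
      repressed = state)
  })
}

#' Summarize simulated or observed cells into per-gonad observations
#'
#' Collapses a per-cell table to what immunostaining actually measures:
#' the number of GFP-positive cells per gonad and, among those, the number
#' that are βGAL-positive (i.e. not repressed). The truth-only `clone`
#' column is deliberately ignored.
#'
#' @param cells data.frame from [simulate_clones()] (needs `gonad`, `gfp`,
#'   `repressed`).
#' @return data.frame with `gonad_id`, `total_pgc`, `gfp_pos_cells`,
#'   `bgal_pos_among_gfp`.
#' @export
tally_gonads <- function(cells) {
  stopifnot(all(c("gonad", "gfp", "repressed") %in% names(cells)))
  ids <- sort(unique(cells$gonad))
  do.call(rbind, lapply(ids, function(g) {
    x <- cells[cells$gonad == g, ]
    data.frame(gonad_id = as.character(g),
               total_pgc = nrow(x),
               gfp_pos_cells = sum(x$gfp),
               bgal_pos_among_gfp = sum(x$gfp & !x$repressed),
               stringsAsFactors = FALSE)
  }))
}

#' Fraction of homogeneous clones in a simulated cell table
#'
#' Truth-side measurement for calibration: the fraction of clones whose
#' cells share one repression state. Under the fully independent plastic
#' null this converges to `r^k + (1-r)^k` for clones of `k` cells; under
#' the lock model it is exactly 1.
#'
#' @param cells data.frame from [simulate_clones()].
#' @return numeric fraction in `[0,1]`.
#' @export
homogeneous_clone_fraction <- function(cells) {
  key <- paste(cells$gonad, cells$clone)
  homog <- tapply(cells$repressed, key, function(s) all(s) || !any(s))
  mean(homog)
}
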