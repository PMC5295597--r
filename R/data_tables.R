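#' Bundled late-L3 gonad clone observations
#'
#' Per-gonad immunostaining tallies from the embryonic flip-out
#' clonal-lineage experiment: 23 late third-instar gonads, each with the
#' number of GFP-positive (lineage-labelled) PGCs and how many of those
#' are βGAL-positive (expressing the repression reporter). Ten gonads
#' carry a single 8-cell clone (3 fully βGAL-positive, 7 fully negative);
#' thirteen carry two clones. GFP-cell totals for the fully homogeneous
#' and 50:50 two-clone gonads are not individually reported in the source
#' tallies and are transcribed as 16 (two clones of eight); the
#' homogeneity classification is invariant to that choice.
#'
#' @return data.frame with `gonad_id`, `n_embryonic_clones`,
#'   `gfp_pos_cells`, `bgal_pos_among_gfp`.
#' @seealso [clone_memory_test()]
#' @export
l3_gonad_observations <- function() {
  read_tsv(system.file("extdata", "l3_gonad_clones.tsv",
                       package = "pirnadev", mustWork = TRUE))
}

#' Bundled adult ovariole staining observations
#'
#' Egg-chamber (GFP, βGAL) state lists for the 61 adult ovarioles showing
#' simultaneous heterogeneity for both markers in the larval flip-out
#' experiment, encoded from the reported pattern tallies: 28 overlap, 11
#' exclusion and 22 three-state ovarioles (no four-state ovariole was
#' observed).
#'
#' @return long data.frame with `ovariole_id`, `chamber`, `gfp`, `bgal`
#'   (0/1).
#' @seealso [classify_ovariole_table()]
#' @export
adult_ovariole_observations <- function() {
  read_tsv(system.file("extdata", "adult_ovariole_states.tsv",
                       package = "pirnadev", mustWork = TRUE))
}
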