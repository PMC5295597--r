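#' Configuration for an end-to-end signature run
#'
#' Bundles every tunable of the small-RNA signature pipeline: the
#' libraries to process (simulation specs or FASTQ paths), the reference
#' world, the size windows (global length filter 19-29 nt; 1U and TE-RPKM
#' windows 23-29 nt; ping-pong window 23-28 nt), the normalization mode
#' and the GLKD pseudocount. The seed is recorded in every output.
#'
#' @param libraries named list; each element a [pirna_library_spec()] (the
#'   library is simulated) or a FASTQ file path.
#' @param control name of the control library for knockdown comparisons,
#'   or `NULL` for none.
#' @param genome a `toy_genome`, [toy_genome_spec()] or `NULL` (default
#'   layout seeded from `seed`).
#' @param annotations annotation sets ([make_annotation_sets()]) or `NULL`
#'   (generated from `seed`).
#' @param out_dir output directory (created if missing).
#' @param norm `"depth"` or `"mirna"` normalization.
#' @param pseudocount GLKD scatter pseudocount (default 1).
#' @param size_filter,u1_range,pingpong_range,rpkm_range length windows;
#'   must nest within 19..29 (ping-pong within 23..28).
#' @param max_mismatch aligner mismatch tolerance (0 or 1).
#' @param min_overlap adapter trim minimum overlap.
#' @param seed integer master seed.
#' @return list of class `signature_run_config`.
#' @export
signature_run_config <- function(libraries, control = NULL, genome = NULL,
                                 annotations = NULL, out_dir = tempfile(),
                                 norm = c("depth", "mirna"),
                                 pseudocount = 1,
                                 size_filter = c(19L, 29L),
                                 u1_range = c(23L, 29L),
                                 pingpong_range = c(23L, 28L),
                                 rpkm_range = c(23L, 29L),
                                 max_mismatch = 1L, min_overlap = 8L,
                                 seed = 1L) {
  norm <- match.arg(norm)
  stopifnot(is.list(libraries), length(libraries) >= 1L,
            !is.null(names(libraries)), all(nzchar(names(libraries))))
  if (!is.null(control) && !control %in% names(libraries))
    stop("control must name one of the libraries")
  win_ok <- function(w, lo, hi) length(w) == 2L && w[1] >= lo && w[2] <= hi &&
    w[1] <= w[2]
  if (!win_ok(size_filter, 19L, 29L) || !win_ok(u1_range, 19L, 29L) ||
      !win_ok(pingpong_range, 19L, 29L) || !win_ok(rpkm_range, 19L, 29L))
    stop("size windows must nest within 19..29")
  structure(list(libraries = libraries, control = control, genome = genome,
                 annotations = annotations, out_dir = out_dir, norm = norm,
                 pseudocount = pseudocount, size_filter = size_filter,
                 u1_range = u1_range, pingpong_range = pingpong_range,
                 rpkm_range = rpkm_range, max_mismatch = max_mismatch,
                 min_overlap = min_overlap, seed = as.integer(seed)),
            class = "signature_run_config")
}

#' Run the small-RNA signature pipeline end to end
#'
#' simulate/load -> trim -> collapse -> place -> annotate -> normalize ->
#' locus signatures -> TE RPKM -> knockdown comparison. All tables are
#' written under `config$out_dir` together with a manifest carrying the
#' seed and a hash of the configuration; a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [signature_run_config()].
#' @return (invisibly) the report bundle: list with `genome`,
#'   `library_stats`, per-library `signatures` (coverage, size
#'   distributions, 1U, ping-pong histogram and z-score), `te_rpkm`,
#'   `glkd` and `manifest`.
#' @export
run_signature_pipeline <- function(config) {
  stopifnot(is(config, "signature_run_config"))
  for (lib in config$libraries)
    if (is.character(lib) && !file.exists(lib))
      stop("missing input FASTQ: ", lib)
  genome <- config$genome
  if (is.null(genome)) genome <- default_genome_spec(seed = config$seed)
  if (is(genome, "toy_genome_spec")) genome <- make_toy_genome(genome)
  annotations <- config$annotations %||% make_annotation_sets(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  libs <- list()
  for (nm in names(config$libraries)) {
    src <- config$libraries[[nm]]
    raw <- if (is(src, "pirna_library_spec")) {
      sim <- simulate_library(genome, src, annotations)
      sim$reads
    } else read_fastq(src)
    pr <- process_reads(raw, min_overlap = config$min_overlap,
                        min_len = config$size_filter[1],
                        max_len = config$size_filter[2])
    say("[%s] %d raw reads; %d pass trim+filter (%d unique)", nm,
        nrow(pr$trim), sum(pr$trim$status == "ok"), nrow(pr$reads))
    ann <- annotate_library(pr$reads, genome, annotations,
                            config$max_mismatch, library_id = nm)
    hits <- match_reads(pr$reads, genome, config$max_mismatch)
    te_hits <- match_reads(pr$reads, annotations$TE, config$max_mismatch)
    say("[%s] %d placements on profiled loci, %d on TE set", nm,
        nrow(hits), nrow(te_hits))
    libs[[nm]] <- list(reads = pr$reads, stats = ann$stats, hits = hits,
                       te_hits = te_hits)
  }

  stats <- normalization_factors(do.call(rbind, lapply(libs, `[[`, "stats")))
  rownames(stats) <- NULL
  factor_of <- function(nm) {
    i <- match(nm, stats$library_id)
    f <- if (config$norm == "depth") stats$norm_factor_depth[i]
         else stats$norm_factor_mirna[i]
    if (is.na(f))
      stop("miRNA normalization unusable for library ", nm,
           " (miRNA fraction below threshold)")
    f
  }

  signatures <- list(); te_tabs <- list()
  for (nm in names(libs)) {
    f <- factor_of(nm)
    h <- libs[[nm]]$hits
    cov <- weighted_coverage(h, genome, f)
    per_region <- lapply(names(genome$sequences), function(rn) {
      hist <- pingpong_signature(
        h, rn, genome,
        size_range = config$pingpong_range[1]:config$pingpong_range[2],
        norm_factor = f)
      list(region = rn,
           size_dist = size_distribution(h, rn, norm_factor = f),
           u1 = u1_bias(h, rn,
                        size_range = config$u1_range[1]:config$u1_range[2]),
           pingpong = hist, zscore = pingpong_zscore(hist))
    })
    names(per_region) <- names(genome$sequences)
    signatures[[nm]] <- list(coverage = cov, regions = per_region)
    te_tabs[[nm]] <- te_antisense_rpkm(
      libs[[nm]]$te_hits, annotations$TE, f,
      effective_depth = stats$effective_depth[match(nm, stats$library_id)],
      size_range = config$rpkm_range[1]:config$rpkm_range[2],
      library_id = nm)
  }

  glkd <- list()
  if (!is.null(config$control)) {
    for (nm in setdiff(names(libs), config$control))
      glkd[[nm]] <- glkd_scatter(te_tabs[[config$control]], te_tabs[[nm]],
                                 config$pseudocount)
  }

  manifest <- list(seed = config$seed, norm = config$norm,
                   pseudocount = config$pseudocount,
                   size_filter = config$size_filter,
                   u1_range = config$u1_range,
                   pingpong_range = config$pingpong_range,
                   rpkm_range = config$rpkm_range,
                   max_mismatch = config$max_mismatch,
                   libraries = names(config$libraries),
                   control = config$control,
                   config_hash = config_hash(
                     unclass(config)[setdiff(names(unclass(config)),
                                             "out_dir")]))

  od <- config$out_dir
  write_tsv(stats, file.path(od, "library_stats.tsv"))
  for (nm in names(libs)) {
    write_tsv(coverage_to_bedgraph(signatures[[nm]]$coverage),
              file.path(od, paste0("coverage_", nm, ".tsv")))
    pp <- do.call(rbind, lapply(signatures[[nm]]$regions, function(x)
      data.frame(region = x$region, overlap = seq_along(x$pingpong),
                 pairs = as.numeric(x$pingpong))))
    write_tsv(pp, file.path(od, paste0("pingpong_", nm, ".tsv")))
    sm <- do.call(rbind, lapply(signatures[[nm]]$regions, function(x)
      data.frame(region = x$region, u1_bias = x$u1,
                 pingpong_zscore = x$zscore)))
    write_tsv(sm, file.path(od, paste0("signature_summary_", nm, ".tsv")))
    write_tsv(te_tabs[[nm]], file.path(od, paste0("te_rpkm_", nm, ".tsv")))
  }
  for (nm in names(glkd))
    write_tsv(glkd[[nm]], file.path(od, paste0("glkd_", nm, "_vs_",
                                               config$control, ".tsv")))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("# Small-RNA signature pipeline report", "",
               sprintf("- seed: %d", config$seed),
               sprintf("- config hash: %s", manifest$config_hash), "",
               "## Stage log", log_lines), file.path(od, "report.md"))

  invisible(list(genome = genome, library_stats = stats,
                 signatures = signatures, te_rpkm = te_tabs, glkd = glkd,
                 manifest = manifest, out_dir = od))
}

#' Run the clonal-memory pipeline
#'
#' Takes a gonad observation table (or simulates one from a
#' [clone_sim_spec()]), classifies every gonad for compatibility with
#' clonal repression homogeneity, and evaluates the plastic-repression
#' null probability for the single-clone gonads.
#'
#' @param obs gonad observation data.frame (`gonad_id`, `gfp_pos_cells`,
#'   `bgal_pos_among_gfp`) or TSV path; `NULL` when `sim_spec` is given.
#' @param sim_spec optional [clone_sim_spec()]; simulated cells are
#'   tallied with [tally_gonads()].
#' @param r repression fraction for the null (default 0.6647).
#' @param k single-clone size (default 8).
#' @param out_dir optional output directory for TSV/JSON/report.
#' @return the [clone_memory_test()] bundle, plus `manifest`.
#' @export
run_clonal_pipeline <- function(obs = NULL, sim_spec = NULL, r = 0.6647,
                                k = 8L, out_dir = NULL) {
  if (is.null(obs) && is.null(sim_spec))
    stop("provide an observation table or a simulation spec")
  if (is.null(obs)) {
    obs <- tally_gonads(simulate_clones(sim_spec))
  } else if (is.character(obs)) obs <- read_tsv(obs)
  if (!nrow(obs)) stop("empty observation table")
  res <- clone_memory_test(obs, r = r, k = k)
  res$manifest <- list(r = r, k = k,
                       seed = if (!is.null(sim_spec)) sim_spec$seed else NA,
                       n_gonads = nrow(obs),
                       config_hash = config_hash(list(obs, sim_spec, r, k)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res$classification, file.path(out_dir, "classification.tsv"))
    jsonlite::write_json(
      list(compatible_fraction = res$compatible_fraction,
           single_clone_tally = as.list(res$single_clone_tally),
           plastic_null = res$plastic_null, manifest = res$manifest),
      file.path(out_dir, "clonal_summary.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    writeLines(c("# Clonal-memory pipeline report", "",
                 sprintf("- gonads: %d", nrow(obs)),
                 sprintf("- compatible fraction: %.4f",
                         res$compatible_fraction),
                 if (!is.null(res$plastic_null))
                   sprintf("- plastic-null P (r=%.4f, k=%d): %.3e", r, k,
                           res$plastic_null$probability)),
               file.path(out_dir, "report.md"))
  }
  res
}
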