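# pirnadev

Small-RNA silencing signatures and clonal memory of piRNA-mediated
repression in developing germlines.

## What this package is for

PIWI-interacting RNAs (piRNAs, ~23–29 nt) silence transposable elements
and homologous reporter transgenes in animal germ cells. Two questions
recur when this silencing is studied across development:

1. **Are bona fide piRNAs present in a tissue or genotype?** Answered from
   small-RNA sequencing libraries by a set of locus-level statistics:
   stranded, multimapping-aware coverage; read-size distributions; the 1U
   bias (fraction of 23–29 nt reads beginning with uridine); and the
   ping-pong signature — an excess of sense/antisense read pairs whose 5′
   ends overlap by exactly 10 nt, diagnostic of the Aub/Ago3 amplification
   cycle. Transposon-level antisense RPKM and knockdown-versus-control
   scatters quantify which piRNA populations depend on which gene.
2. **Is the per-cell ON/OFF repression state heritable through cell
   division (an epigenetic lock) or free to switch (plastic repression)?**
   Answered by clonal lineage tracing: classify each gonad's labelled
   clone for homogeneity of the repression reporter, and compare with the
   closed-form probability of the observed pattern if every cell chose
   its state independently.

The package implements both analysis tracks end to end for desk-scale
("toy") references, plus a synthetic-data generator that emits small-RNA
libraries and gonad clone tables with known ground truth, so the whole
pipeline is testable without any external sequencing data.

## Models and statistics

- **Read processing.** Reads are trimmed at the leftmost exact occurrence
  (≥ 8 nt) of the 3′ adapter `TGGAATTCTCGGGTGCCAAG`; inserts of 19–29 nt
  over A/C/G/T are retained and collapsed to unique sequences with counts.
- **Placement and weighting.** Every placement of a read on the profiled
  region set is reported (0 or 1 mismatch, best stratum). A read of
  occurrence count *c* with *n* placements deposits weight *c·f/n* at each
  placement, where *f* is the library normalization factor — so each
  read's total weight is conserved at *c·f*.
- **Normalization.** Effective depth = matched reads − (rRNA/snoRNA +
  tRNA). The lowest-depth library is the reference (factor 1); factors are
  ref/depth. An alternative miRNA-count factor is flagged unusable when a
  library's miRNA fraction is below 10%.
- **Ping-pong.** For sense 5′ end *s* and antisense 5′ end *a* (0-based
  genome coordinates), the overlap is *o = a − s + 1*; the histogram over
  *o* = 1..28 accumulates products of weighted 5′-end counts of 23–28 nt
  reads, and *z* = (hist[10] − mean(others)) / sd(others) summarizes the
  10 nt peak.
- **TE comparisons.** rpkm = normalized antisense count / (TE kb) /
  (effective depth in millions); knockdown scatters plot
  log2(control + 1) against log2((test + 1)/(control + 1)).
- **Clonal memory.** A gonad with *g* lineage-labelled (GFP⁺) cells and
  *b* βGAL⁺ cells among them is compatible with clonal homogeneity iff
  *b* ∈ {0, g, g/2}. Under the fully plastic null with repression fraction
  *r*, observing *g₊* all-repressed and *g₋* all-expressing clones of *k*
  cells has probability *P = (r^k)^{g₊} · ((1−r)^k)^{g₋}* (computed in log
  space). Lineage simulations (lock: state inherited; plastic: state
  re-drawn from Bernoulli(r) per division with a tunable switch rate) and
  an adult ovariole simulator give expected phenotype distributions.

## Worked example

```r
library(pirnadev)

genome <- make_toy_genome(default_genome_spec(seed = 1))
ann    <- make_annotation_sets(seed = 1)
spec   <- pirna_library_spec(n_reads = 5000, pingpong_fraction = 0.6,
                             u1_bias = 0.8, seed = 2)
lib    <- simulate_library(genome, spec, ann)

pr    <- process_reads(lib$reads)            # trim + filter + collapse
stats <- annotate_library(pr$reads, genome, ann, library_id = "demo")$stats
hits  <- match_reads(pr$reads, genome)
hist  <- pingpong_signature(hits, "cluster42", genome)

stats[, c("total_matched", "miscRNA", "tRNA", "miRNA", "effective_depth")]
#>   total_matched miscRNA tRNA miRNA effective_depth
#> 1          5000     263  111   257            4626
round(hist[9:11], 1)                         # pairs at overlap 9, 10, 11
#>     9    10    11
#> 343.0 963.0 354.5
round(pingpong_zscore(hist), 2)
#> [1] 15.4
round(u1_bias(hits, "cluster42"), 3)
#> [1] 0.802
```

The sharp excess at overlap 10 (963 pairs against a ~350-pair background,
z = 15.4) is the ping-pong signature the library was simulated to carry,
and the recovered 1U bias (0.802) matches the simulated 0.8.

The clonal-memory track on the bundled late-L3 gonad observations:

```r
res <- clone_memory_test(l3_gonad_observations())
sprintf("%.1f%%", 100 * res$compatible_fraction)
#> [1] "91.3%"
format(res$plastic_null$probability, digits = 3)
#> [1] "4.76e-22"
```

91.3% of gonads are compatible with clonal repression homogeneity, and the
chance of the observed single-clone tally under fully independent per-cell
states is ~5 × 10⁻²² — the epigenetic-lock signature.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pirnadev.R", package = "pirnadev"))')
Rscript "$CLI" simulate-reads --out-dir sim --seed 5 --n-reads 2000
Rscript "$CLI" trim  --fastq sim/reads.fastq --out collapsed.tsv
Rscript "$CLI" align --reads collapsed.tsv --ref sim/genome.fasta --out hits.sam
Rscript "$CLI" clone-test --obs gonads.tsv --out-dir clone_out
```

Run `Rscript "$CLI"` with no arguments for the full subcommand list
(simulation, annotation, profiling, ping-pong, TE RPKM, knockdown
comparison, ovariole simulation, end-to-end demo).

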