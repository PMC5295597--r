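---
title: "Methods: piRNA silencing signatures and clonal memory"
author: "pirnadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA silencing signatures and clonal memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnadev)
```

# Scope and model

`pirnadev` implements two linked analysis tracks for piRNA-mediated
silencing in developing germlines.

**Track 1 — small-RNA signatures.** Given small-RNA sequencing reads and a
compact set of reference loci (a dual-strand piRNA cluster, a subtelomeric
region, a reporter transgene, transposon consensus sequences), the package
answers: does this library contain bona fide piRNAs against these targets,
and how does a germline knockdown change them? The diagnostics are the
classical ones: a 23–29 nt size range, a 5′-uridine (1U) bias, dual-strand
coverage, a ping-pong 5′-overlap signature at exactly 10 nt, and antisense
RPKM per transposon.

**Track 2 — clonal memory.** Given per-gonad or per-ovariole staining
observations of a lineage label (GFP flip-out) crossed with a repression
reporter (βGAL), the package asks whether the per-cell ON/OFF repression
state behaves as a heritable epigenetic lock or as a plastic state, using
a homogeneity classification, a closed-form null probability, and lineage
simulations.

Both tracks are exercised end to end on synthetic data with known ground
truth; nothing in the package requires external sequencing data.

# Track 1: statistics and conventions

## Read processing

Reads are trimmed at the leftmost position where the read matches a
prefix of the 3′ adapter (default `TGGAATTCTCGGGTGCCAAG`) exactly, over at
least `min_overlap = 8` bases, either to the read end or spanning the full
adapter internally. The adapter match tolerates no mismatches; published
descriptions of such pipelines rarely state the trimmer's mismatch
policy, and exact matching is the conservative, reproducible choice.
Inserts outside 19–29 nt are discarded, as are inserts containing `N`
(the upstream base caller's ambiguity codes carry no usable signal at
these read lengths). Identical inserts are collapsed to unique sequences
with occurrence counts; all downstream weighting operates on collapsed
counts.

## Placement and multi-mapping weights

`match_reads()` reports **every** placement of each read on both strands
of every profiled region, at 0 or 1 mismatches, with a best-stratum rule:
a read with a perfect placement reports only perfect placements. This
mimics common short-read mapper behaviour while keeping the matcher
exhaustive (a compiled sliding-window scan — no seed heuristic, so no
placement can be missed; an independent pure-R scan oracle verifies this
in the test suite). Coordinates are 0-based half-open internally, with
SAM's 1-based convention applied only at import/export; 5′ ends are
`start` on the plus strand and `start + length − 1` on the minus strand.
This single convention keeps all overlap arithmetic free of off-by-one
ambiguity.

A read with collapsed count $c$, library normalization factor $f$ and $n$
placements within the profiled region set deposits weight $c \cdot f / n$
at each placement — the multi-mapping apportionment rule. The number of
placements is counted **within the profiled region set only**, not
genome-wide. Weight conservation (each read contributes exactly
$c \cdot f$ in total) is asserted for every read of a simulated library in
the acceptance suite.

## Normalization

The effective depth of a library is the number of matched reads that are
not abundant cellular RNAs (rRNA/snoRNA, collectively "miscRNA", and
tRNA). Across libraries, the lowest effective depth defines the reference
(factor exactly 1) and other libraries are scaled by
`ref_depth / depth`. A second factor based on miRNA counts is computed
analogously, but flagged unusable for libraries whose miRNA fraction is
below 10% of matched reads: a sample in which miRNAs are a few percent of
the library (as in carcass samples) cannot be normalized on them. The 10%
threshold is a package decision (configurable); the motivating
observation is only that ≈3.6% was too low while >50% was fine.

Reads are assigned to exactly one annotation category by the fixed
priority `miscRNA > tRNA > miRNA > TE > genome_other`. Whether multi-
category reads should be assigned by priority or fractionally is not
settled in the literature this pipeline descends from; priority is the
simplest auditable rule, and the category partition (categories plus
unmatched sum to the input) is enforced by test.

## Ping-pong signature

For a sense read with 5′ end at genome position $s$ and an antisense read
with 5′ end at $a$ (both 0-based), the 5′ overlap is

$$o = a - s + 1 ,$$

so a canonical ping-pong pair scores $o = 10$. For each $o \in 1..28$ the
histogram accumulates the **product** of weighted sense and antisense
5′-end counts at distance $o - 1$, over reads of 23–28 nt. Products of
counts (rather than binary co-occurrence) are the natural pair count and
match the method lineage this statistic comes from; multimapper weighting
(1/n) is applied for consistency with coverage, a choice the source
literature leaves open. The `pingpong_zscore()` summary standardizes bin
10 against the other bins; a perfectly flat histogram scores 0 and any
other zero-spread background returns `NA` (no scale to standardize
against).

One subtlety is worth recording: the overlap histogram is **not**
invariant under simply relabelling strands (that converts facing-5′ pairs
into facing-3′ pairs), but it **is** invariant under the strand involution
that reverse-complements the reference ($\text{strand swap} +
s \mapsto L - (s + \text{len})$). The property tests assert exactly that;
pure relabelling is asserted to flip coverage sign and transpose the size
histogram, which it does.

## TE-level comparisons

`te_antisense_rpkm()` counts antisense 23–29 nt weighted reads per
transposon and converts to RPKM using the library's **effective depth** as
the per-million denominator — the printed definition of the statistic
does not spell out its denominator, and effective depth is the only
denominator consistent with the library normalization. The knockdown
scatter plots, per TE, $x = \log_2(\text{control} + 1)$ and
$y = \log_2((\text{test} + 1)/(\text{control} + 1))$; the pseudocount 1
(configurable) guards zero counts, another detail the source methods do
not state.

# Track 2: clonal memory

## Homogeneity classification

A gonad with $g$ GFP⁺ (lineage-labelled) cells of which $b$ are βGAL⁺ is
*compatible* with clonal homogeneity iff $b \in \{0,\ g,\ g/2\}$ (the
$g/2$ case requiring $g$ even): one fully repressed clone, one fully
expressing clone, or two homogeneous clones of equal size (the "50:50"
pattern). Gonads not matching any pattern are scored incompatible even
when a three-clone or unequal-division explanation exists — such
explanations are alternatives to be discussed, not reclassifications.

## The plastic null

If every cell's repression state is independent with repression
probability $r$, a clone of $k$ cells is all-repressed with probability
$r^k$ and all-expressing with probability $(1-r)^k$, so observing $g_+$
all-repressed and $g_-$ all-expressing clones has probability

$$P = (r^k)^{g_+} \left[(1-r)^k\right]^{g_-} .$$

With $r = 0.6647$, $k = 8$, $g_+ = 7$, $g_- = 3$ this evaluates to
$4.758 \times 10^{-22}$ (the commonly printed $4.75 \times 10^{-22}$ is a
truncation of this value at the third significant figure). The
computation is done in log space so that magnitudes around $10^{-22}$ and
far smaller survive; boundary cases ($r \in \{0, 1\}$ with conflicting
clone counts) return probability 0 rather than erroring. $r$ is treated
purely as an input parameter — how it was estimated from gonad images is
not modelled here.

## Lineage simulation semantics

`simulate_clones()` starts each gonad with `pgc_init = 10` embryonic
PGCs, each independently repressed with probability `r = 0.6647` and
GFP-labelled with probability `flipout_prob`, then applies
`divisions = 3` mitoses (so embryonic clones are 8 cells at observation —
the biology of the assay it emulates). Under the **lock** model daughters
copy the parental state. Under the **plastic** model each daughter, with
probability `switch_rate` per division, **re-draws** its state from
Bernoulli($r$).

Re-drawing (rather than toggling) is a deliberate design choice: the
plastic null of interest is "states independent with marginal $r$", and
re-draw semantics reaches exactly that limit at `switch_rate = 1`, where
the homogeneous-clone fraction converges to $r^k + (1-r)^k \approx
0.0383$ for $k = 8$. A symmetric toggle would drive the marginal to 0.5
regardless of $r$ and could never reproduce the closed form above. The
test suite checks the simulator against an exact enumeration of all
resample histories of the 3-level division tree at intermediate switch
rates.

The truth table retains the clone id of every cell, but classification
operations never read it — they see only what immunostaining measures
(GFP⁺ counts and βGAL⁺ counts among them), via `tally_gonads()`.

## Ovariole simulation

Each simulated germarium carries two germline stem cells with probability
`p_two_gsc = 0.5` (the spectrosome-staining estimate for the emulated
experiment), otherwise three. Each GSC is independently GFP-labelled
(default 0.5, the strong late-larval heat-shock regime) and repressed
(probability $r$); each emits `cysts_per_gsc = 3` egg chambers. Under
lock, chambers copy GSC states; under plastic, each chamber's βGAL state
is re-drawn while GFP — a true lineage label — is still copied. An
ovariole is informative only when heterogeneous for **both** markers; the
distinct (GFP, βGAL) state sets then classify it as overlap
{(+,+),(−,−)}, exclusion {(+,−),(−,+)}, or mixed (3 or 4 states). With at
most three GSCs the lock model can never produce four states — the
acceptance suite asserts exactly zero `mixed4` at any simulation size.
The number of egg chambers observed per GSC lineage is not documented for
the emulated experiment; 3 per GSC is a realistic ovariole's worth. Lock-
model classifications are invariant to this count, plastic-model mixed
fractions are not — treat it as a model parameter, not a measurement.

# The synthetic-data generator

`simulate_library()` emits what the signature statistics assume:

- genomic reads drawn from the toy regions proportionally to length ×
  depletion factor, sense or antisense (`antisense_fraction = 0.5`;
  dual-strand cluster output is strand-balanced);
- a `pingpong_fraction` of genomic reads emitted as pairs whose 5′ ends
  are exactly 10 nt apart on opposite strands (pair lengths restricted to
  23–28 nt, the window the signature is computed over);
- read lengths from a unimodal 23–29 nt distribution peaking at 25–26 nt
  (`default_size_dist()`; the emulated experiments publish size
  distributions only as figures, so these weights are a package choice);
- a 1U bias imposed by forcing each insert's 5′ base to `T` with
  probability `u1_bias = 0.75` (and to a non-T base otherwise), making
  the realized bias exactly Binomial — at the cost of up to one 5′
  mismatch against the reference, inside the aligner's tolerance;
- multimapping reads drawn from an exact 60 nt internal repeat planted in
  every dual-strand cluster region (`multimap_rate = 0.1`);
- contaminants (miRNA/miscRNA/tRNA substrings of dedicated annotation
  references) so the annotation stage has something to classify;
- the full 3′ adapter appended to every read, constant `I` qualities
  (base qualities are never used downstream), and a truth table recording
  every read's origin, strand and ping-pong partner.

Germline-knockdown effects are emulated by per-region multiplicative
`depletion` factors; a TE-level knockdown world is built by letting
genome regions double as the TE reference set.

What the generator does **not** emulate — real sequence composition,
genome-scale multimapping ambiguity, ligation biases, quality decay,
partial adapters, PCR duplicates beyond simple multiplicity: a green test
establishes the statistics' arithmetic and their statistical power in the
stated world, not robustness to every artefact of a real library.

Annotation references are generated from a seed that is internally
decorrelated from the genome seed, so passing one master seed everywhere
can never make an annotation sequence duplicate genome sequence.

# Numerical and engineering choices

- Probabilities spanning $10^{-22}$ and below: log-space accumulation,
  `log1p` for $1-r$.
- Degenerate inputs: empty hit sets give zero histograms and `NA` 1U
  bias; zero effective depth, zero-length TEs, region-bound violations
  and malformed SAM records (reported with line numbers) are errors.
- Determinism: every stochastic operation takes an explicit integer seed
  and restores the caller's RNG state; pipeline outputs embed the seed
  and a configuration hash, and reruns are byte-identical (asserted).
- SAM import is delegated to Rsamtools; only single-segment unspliced
  records (CIGAR `<len>M`) are accepted, matching what the toy matcher
  emits. Multi-mapping counts are recomputed over the provided region
  set whenever `NH` tags are absent or a region restriction is applied.
- Collapsed-read output is ordered by decreasing count then sequence, so
  all tables are stable across runs.

# Known limitations

- The matcher is exhaustive and desk-scale by contract (references
  ≤ 1 Mnt total); it is not a replacement for a genome-scale aligner, and
  published genome-scale numbers (library depths, printed RPKM values)
  are out of reach without the original deposited reads and full
  references.
- Indels are not modelled anywhere (alignment is ungapped, 0–1
  substitutions).
- The ovariole model treats each GSC's cyst output as one state stream
  and does not model germarium geometry or cyst turnover.
- `r` is an input, never estimated; no Bayesian comparison between lock
  and plastic models is attempted — only simulation plus the closed-form
  null.
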