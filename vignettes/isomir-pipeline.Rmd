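---
title: "Annotating and profiling isomiRs in single cells: methods and design"
author: "isomirsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and profiling isomiRs in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirsc)
```

## The problem

Mature microRNAs are not single sequences. A miRNA gene gives rise to a
population of variants — isomiRs — that differ from the reference
(miRBase-style) mature sequence at the 5' end, at the 3' end, or
internally. Because the 5' end defines the seed region (bases 2–8) that
drives target recognition, these variants are not interchangeable: a one-base
5' shift redefines the target repertoire. `isomirsc` implements a complete
desk-scale pipeline for studying this heterogeneity in single-cell small-RNA
sequencing data: read preprocessing, tolerance-bounded annotation against
precursor hairpins, five-way categorisation, per-cell profiling, UMI-based
deduplication, and a correlation test of isomiR-category expression against
predicted canonical targets. A ground-truthed simulator generates every
input, so each stage is verifiable end-to-end without external data.

## The annotation model

Every processed read is explained as a decomposition against one mature arm
of one precursor:

* a **templated segment**: the precursor subsequence from `start − fp` to
  `end + tp`, where `(start, end)` are the canonical mature coordinates and
  the 5' offset `fp` and 3' offset `tp` each lie in `[-3, +3]`
  (positive `fp` = 5' extension into the precursor, positive `tp` = 3'
  templated extension);
* at most **one internal substitution** inside that segment, never on the
  first or last base of the read (terminal mismatches are 5'/3' variation,
  not substitution, and invalidate a placement);
* a **non-templated 3' tail** of 0–3 residual bases. Templating is maximal:
  a 3' base equal to the next precursor base is always consumed as
  templated, so no reported tail can begin with a templated base.

This is the `-sub 1 -trim 3 -add 3` tolerance regime of small-RNA isomiR
aligners; all three bounds are configurable through `alignment_params()`.

Several decompositions can explain one read. The implementation enumerates
all of them and ranks by parsimony: fewest substitutions, then shortest
tail, then smallest `|fp| + |tp|`, then smallest `|fp|`, then the
lexicographically first (precursor, mature) pair. The last key exists only
to make results deterministic; when the best score is reached on more than
one precursor the read is assigned to the first and flagged `ambiguous`
rather than fractionally split. External aligners leave this ordering
implicit; here it is a declared part of the contract so that an exhaustive
independent oracle can check the optimised implementation read-for-read
(the test suite does exactly that).

Categories follow from the winning decomposition, and one read may hold
several at once:

| category | condition |
|---|---|
| `CANONICAL` | `fp = 0`, `tp = 0`, no tail, no substitution |
| `FP_VARIANT` | `fp != 0` |
| `TP_TEMPLATED` | `tp != 0` |
| `TP_NONTEMPLATED` | tail non-empty |
| `SUBSTITUTION` | one internal substitution |

One consequence of parsimony-first scoring is worth knowing: a genuine
internal substitution at one of the last two internal read positions can be
re-explained with zero substitutions as a 3' trim plus a short
non-templated tail, and the scoring order prefers that explanation. On
simulated data with uniformly placed substitutions this reclassifies about
`2/(L-2)` (roughly 10% at 22 nt) of substitution molecules into the 3'
categories. It is a property of the scoring model — any tool with this
preference behaves the same way — and the mixture-recovery checks account
for it by testing within binomial sampling bands at the per-cell depth
rather than asserting exact class recovery.

## Read processing

The preprocessing order is fixed: UMI extraction (a 5' prefix of
configurable length, default 8 nt, moved to the read's metadata), then 3'
adapter trimming, then a minimum-length filter at 15 nt (a 14 nt read is
dropped, a 15 nt read kept). The adapter contract is the cutadapt-style
one: every alignment offset of the adapter against the read is scored
(full internal occurrence or read-suffix/adapter-prefix overlap), a
placement is valid when the overlap is at least `min_overlap` (default 1)
with at most `floor(0.1 × overlap)` mismatches, and the winner maximises
matching bases with ties to the longer then leftmost placement. Matching is
substitutions-only; indel-tolerant trimming is out of scope. Note that with
`min_overlap = 1` a read whose final base equals the adapter's first base
loses that base — the documented consequence of a 1 nt minimum overlap.

Deduplication is keyed on the precursor alignment: reads group by (cell,
precursor, alignment start), UMIs within a group are clustered, and one
representative per cluster survives (most frequent sequence, ties to the
lexicographically smallest, then smallest read id — all deterministic).
Exact-match collapse is the default; a "directional" mode merges a
lower-count UMI into a higher-count one at Hamming distance 1 when
`count_high >= 2 × count_low − 1`, the de-facto rule of common
deduplicators, applied greedily to cluster roots in descending count order
(deep chained merges are not followed; at desk scale with 8–10 nt UMIs the
difference is immaterial and the simpler rule is exactly testable). Keying
on the precursor alignment rather than a genome alignment is deliberate:
the genome stage in the original protocols exists only to position reads
for deduplication, and the precursor coordinate is an equivalent key for
miRNA-mapped reads.

## Per-cell profiles

Counting supports three feature levels — miRNA, isomiR signature (the
tuple mature/fp/tp/tail/substitution), and miRNA × category, where one read
increments every category it carries but its parent miRNA once. Cells with
fewer than 1000 miRNA-mapped reads (pre-deduplication) are excluded; the
boundary is inclusive at 1000.

Positional profiles report the proportion of reads starting at each 5'
offset and ending at each 3' templated offset in `[-3, +3]`, plus the
proportions with at least one non-templated A and at least one
non-templated U (both can hold for mixed tails). Proportions are computed
per cell first and then averaged unweighted across cells, so deep cells do
not dominate; a pooled-read mode exists behind a flag for comparison.
Per-miRNA profiles require a minimum of 50 reads for the miRNA across the
group (configurable) — an explicit stand-in for the unquantified expression
filters such figures typically apply.

Cell-cell structure uses Spearman correlation on per-cell CPM-normalised
miRNA counts and average-linkage hierarchical clustering on `1 − ρ`.
Spearman is rank-based, so the CPM choice only matters for the exported
matrices, not the clustering; average linkage is a deterministic,
standard default for correlation distances.

## Target correlation

Predicted targets are consumed as a flat table (miRNA, gene, source
algorithm, rank) and aggregated locally with the minimum-rank rule, keeping
only genes predicted by at least two distinct sources. For each of the
top-k (default 6) most highly expressed miRNAs whose non-canonical read
share is at least 10%, the per-cell expression of each isomiR category
(TOTAL, CANONICAL, FP_VARIANT, TP_TEMPLATED, NTA_A, NTA_U, SUBSTITUTION;
the NTA classes use the at-least-one-base rule) is correlated (Pearson)
against every gene, and the distribution of target correlations is compared
with the non-target distribution by a two-sided two-sample
Kolmogorov–Smirnov test at α = 0.05. A significant result is labelled
negative when the target correlations' median lies below the non-targets'
median — the shift direction the test's ECDF plot shows — and positive
otherwise; the median was chosen as the direction statistic because it is
robust and directly testable. No multiple-testing correction is applied to
the headline calls (each test stands at its own α, as is conventional for
this display), but a Benjamini–Hochberg column is emitted alongside for
users who want it.

Normalisation defaults: category expression is counts-per-million over the
cell's total miRNA-mapped reads, with a parent-miRNA-relative mode
available; mRNA expression is log1p of CPM, with a raw mode available. The
tests verify that planted signals are recovered under both mRNA modes.

## The synthetic-data generator

The simulator is the package's reference instrument, not a fixture. It
emulates:

* a skewed miRNA abundance vector (normalised gamma draws, shape 0.3) so a
  few species dominate, as in real libraries;
* per-cell molecule counts of 10³–10⁴, the depth range of miRNA-mapped
  reads per cell in published single-cell small-RNA datasets;
* an isomiR mixture over five molecule classes with defaults (canonical
  0.40, 5' variant 0.10, 3' templated 0.30, NTA 0.15, substitution 0.05)
  chosen for test power — every downstream category receives enough mass to
  be measurable at simulated depth. No published per-class ground truth
  exists (real data only yields observed proportions), so these weights are
  a verification instrument, not a biological claim;
* class-specific draws: 5' offsets over −3..−1 (5' extensions are
  permitted by the tolerance model but are vanishingly rare in real cells,
  so the generator does not produce them by default), 3' offsets over
  −3..+3 excluding 0, A/U tails of length 1–3 with a 60:40 A:U ratio
  (adenylation dominating uridylation), and uniform internal substitutions;
* tails that are genuinely non-templated: a tail's first base is re-drawn
  (flipped within {A, U}) whenever it equals the next templated base;
* PCR duplication as a shifted Poisson (`1 + Poisson(mean − 1)`), positive
  support and a single dial, with an optional canonical-biased mode that
  multiplies the Poisson rate for canonical molecules only — used to
  demonstrate that deduplication removes a PCR-induced inflation of the
  canonical share (the direction of the shift is asserted, never a
  magnitude, which is bias-dependent);
* 5'-prefix UMIs (default 8 nt), optionally drawn without replacement per
  cell to model the collision-free regime in which deduplication must be
  exact, and a 3' adapter appended to every read.

Reads are emitted in DNA space (U→T); GFF3 output is 1-based inclusive
while all internal coordinates are 0-based half-open. Every molecule draw
is recorded, so per-cell truth proportions, molecule counts and coupled
expression are recomputable exactly.

The coupled mRNA generator plants, for each chosen miRNA, a block of target
genes whose values are `mu + s(r·z + sqrt(1−r²)·ε)` with `z` the
standardised per-cell molecule count of the miRNA — a construction whose
population Pearson correlation with the miRNA is exactly `r` on the emitted
scale (`mu = 100`, `s = noise_sd`, values floored at 0, which is rare at
that scale). Non-target genes are independent noise. The target table names
2–3 pseudo-algorithm sources per planted target plus single-source decoy
rows, so the ≥2-source aggregation filter is exercised in both directions.

What the generator does **not** model: ligation bias at either adapter
junction, sequencing errors beyond the planted substitutions, UMI
sequencing errors, cross-mapping between paralogous precursor families
(random references make arms nearly orthogonal), and barcoded single-FASTQ
layouts. Passing tests therefore demonstrate the correctness of the
computational contracts, not robustness to those real-data artefacts.

## Numerical and design choices

* All randomness flows from one integer seed through named per-stage
  substreams; identical config + seed reproduces FASTQ/TSV outputs
  byte-identically, and the pipeline writes a manifest (parameter echo +
  md5 per output) sufficient to reproduce a run.
* Probability vectors must sum to 1 within 1e−9 at config validation.
* Zero-variance cells in clustering get correlation 0 with a warning;
  zero-variance genes yield NA correlations and are excluded from ECDFs;
  KS inputs shorter than 5 are flagged untestable rather than tested.
* Degenerate inputs (empty read streams, all cells filtered, no miRNA
  passing target selection) return empty results with warnings rather than
  errors; malformed references (out-of-bounds arms, unknown seqids) fail
  fast with the offending record named.
* Verification problem sizes were chosen so the full suite exercises
  realistic depth while staying interactive: oracle equivalence on ~1200
  reads against 20 precursors, mixture recovery on 50 cells × 10,000
  molecules, dedup exactness on 5 cells × 800 molecules at PCR mean 5,
  KS calibration on 500 null replicates of a 30-cell × 2000-gene matrix
  and power on 100 replicates with 200 planted targets at r = −0.5.

## A worked example

```{r demo, eval = FALSE}
library(isomirsc)
res <- run_demo(dir = "demo", n_precursors = 15, n_cells = 12,
                reads_per_cell = 2000, seed = 1)
head(res$ks$results[res$ks$results$category == "TOTAL",
                    c("mirna", "ks_statistic", "p_value", "direction")])
```

The demo simulates a reference and reads, writes per-cell FASTQ, runs every
stage, and — because the demo plants repression at r = −0.5 for the six
most abundant miRNAs — reports significant negative KS shifts for their
TOTAL categories.

## Known limitations

* The annotator is exhaustive within its tolerance bounds and therefore
  exact, but it is not a general-purpose aligner: reads from loci outside
  the supplied precursors are no-hits by design, as are reads containing N.
* Ambiguous multi-precursor hits are assigned wholly to one arm; fractional
  or expectation-maximisation assignment is out of scope.
* The substitution/3'-tail boundary ambiguity described above is inherent
  to parsimony scoring; consumers needing unbiased substitution rates near
  the 3' end should treat the last two internal positions separately.
* KS p-values for large target sets use the asymptotic distribution (via
  `stats::ks.test`), which is mildly conservative at these sizes; the null
  calibration check in the test suite measures the realised type-I rate
  directly.
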