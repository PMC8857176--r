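# isomirsc

Single-cell isomiR annotation, profiling and target correlation in R.

Mature miRNAs occur as populations of sequence variants (isomiRs) that
differ from the reference mature sequence at the 5' end, the 3' end, or
internally. Because bases 2–8 form the seed that selects targets, 5'
variants in particular can rewire a miRNA's regulatory programme.
`isomirsc` is for researchers analysing single-cell small RNA-seq who want
to quantify this heterogeneity per cell and ask whether different isomiR
classes of the same miRNA associate differently with the expression of the
miRNA's predicted targets.

## What it does

* **Preprocessing** — 5'-prefix UMI extraction, 3' adapter trimming
  (minimum overlap 1 nt, maximum error rate 0.1, substitutions only),
  minimum-length filter at 15 nt, in that fixed order.
* **Annotation** — each read is decomposed against precursor hairpins as a
  templated segment with 5'/3' offsets in ±3 nt, at most one internal
  substitution, and a non-templated 3' tail of ≤3 nt (the
  `-sub 1 -trim 3 -add 3` tolerance regime), with maximal templating and a
  declared parsimony scoring order, then assigned to the categories
  CANONICAL, FP_VARIANT (5'), TP_TEMPLATED (3' templated),
  TP_NONTEMPLATED (A/U tails), SUBSTITUTION — multi-membership allowed.
* **Profiling** — cells × {miRNA, isomiR, miRNA×category} count matrices;
  a ≥1000 miRNA-read cell filter; read-length distributions; ±3 nt
  positional profiles with ≥1-A / ≥1-U tail proportions (cell-averaged);
  per-cell category proportions; Spearman + average-linkage cell
  clustering.
* **UMI deduplication** — keyed on (cell, precursor, alignment start),
  exact or directional UMI clustering, with a pre/post category-shift
  report.
* **Target correlation** — local aggregation of predicted-target tables
  (minimum rank, ≥2 algorithms), Pearson correlation of per-category
  miRNA expression against every gene across cells, and a two-sample
  Kolmogorov–Smirnov test of target vs non-target correlation ECDFs with
  a median-based direction call at p < 0.05.
* **Simulation** — a ground-truthed generator for references (FASTA +
  GFF3), per-cell FASTQ reads with configurable isomiR mixtures, UMIs, PCR
  duplication and adapters, plus mRNA matrices with planted
  miRNA–target correlations — so the entire pipeline is verifiable
  offline.

## A worked example

```r
library(isomirsc)
res <- run_demo(dir = "demo", n_precursors = 15, n_cells = 12,
                reads_per_cell = 2000, seed = 1)

round(colMeans(res$category_proportions), 3)
#>       CANONICAL      FP_VARIANT    TP_TEMPLATED TP_NONTEMPLATED    SUBSTITUTION
#>           0.397           0.100           0.307           0.155           0.046

res$ks$results[res$ks$results$category == "TOTAL",
               c("mirna", "ks_statistic", "p_value", "direction")]
#>        mirna ks_statistic  p_value direction
#> 1 mir-001-5p        0.709 1.82e-04  negative
#> 2 mir-001-3p        0.551 9.43e-03  negative
#> 3 mir-003-3p        0.643 1.15e-03  negative
#> 4 mir-006-5p        0.666 6.29e-04  negative
#> 5 mir-013-5p        0.681 4.12e-04  negative
#> 6 mir-015-5p        0.860 5.11e-07  negative
```

The demo simulates 12 cells with the default isomiR mixture (canonical
0.40, 5' variant 0.10, 3' templated 0.30, non-templated addition 0.15,
substitution 0.05): the recovered per-cell category proportions match that
design. It also plants repression (r = −0.5) between the six most abundant
miRNAs and their predicted targets, and the KS test flags all six TOTAL
categories as significantly negatively shifted against non-targets — the
signature the procedure is built to detect. All stage outputs (drop
statistics, annotation table, count matrices pre/post deduplication,
profiles, clustering, KS and ECDF tables, a reproducibility manifest) are
written under `demo/out/`.

A thin command-line front end over the same functions ships in
`inst/scripts/isomirsc-cli.R` (`demo`, `simulate`, `run` subcommands); the
methods vignette (`vignettes/isomir-pipeline.Rmd`) documents the models,
parameter defaults and design decisions.

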