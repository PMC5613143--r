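# matdosage

Maternal transcript dosage analysis across mouse oocyte maturation.

## The problem

When transcription shuts down in the full-grown germinal-vesicle (GV)
oocyte, everything up to the metaphase-II (MII) egg is post-transcriptional.
Maturation triggers a degradation wave that removes ~20% of total maternal
RNA, selectively: transcripts end up relatively stabilized, destabilized, or
unchanged in the MII pool. The m6A reader YTHDF2 binds methylated mRNA at
the GAC(U/A) consensus — enriched just downstream of stop codons — and
commits it to decay; a maternal knockout (mCKO) therefore leaves the GV
transcriptome near normal but de-represses motif-bearing targets at MII.

`matdosage` is for transcriptomics analysts studying this kind of
post-transcriptional dosage control. It implements, as tested tidyverse-style
R functions:

* **Dosage statistics** — empirical-Bayes moderated t:
  `t = log2FC / sqrt(s2_tilde * (1/nA + 1/nB))` with
  `s2_tilde = (d0*s0^2 + d*s2) / (d0 + d)`, hyperparameters by trigamma
  moment matching on `log s2`; Benjamini–Hochberg adjustment; the
  fold-change ≥ 2 / p < 0.05 calling gate; `2^-ddCt` qPCR fold changes.
* **Maturation gates** — stabilized/destabilized/unchanged classification of
  the GV→MII control contrast and the 3×3 cross-tabulation against knockout
  calls.
* **Motif profiling** — one transcript per gene (highest |log2FC|, unique
  sequences), top/bottom/centre 1000-transcript sets, ±400 nt N-padded
  windows around start/stop codons, the 1000×800 binary occurrence matrix,
  spline/loess-smoothed positional profiles, and upper-tail hypergeometric
  set enrichment computed in log space.
* **Metagene m6A profiling** — BED peak condensation (max-score union),
  scale-regions gene-body matrices (100 body bins + 400 nt flanks in 10-nt
  bins, strand-aware), group profiles, and regional Welch t-tests at the
  stop codon.
* **Synthetic data** — a seeded generator of transcripts, expression, and
  peak intervals carrying ground-truth labels, calibrated so the expected
  GV→MII mass retention is exactly
  `sum(class_fractions * retentions) = 0.7996`.

`run_pipeline()` chains everything into one seeded, byte-reproducible run.
See the methods vignette (`vignettes/maternal-dosage-methods.Rmd`) for the
model, calibration choices, and known limitations.

## Worked example

```r
library(matdosage)

cfg <- synthetic_config(n_genes = 6000, seed = 42)
sim <- simulate_study(cfg)
study <- sim$study

# knockout dosage at MII
cmp <- moderated_t(as_tibble(study),
                   a = sample_ids(study, "MII", "CTL"),
                   b = sample_ids(study, "MII", "mCKO"))
calls <- call_deregulated(cmp)            # FC >= 2, p < 0.05
deregulation_counts(calls)
#> $n_up: 109   $n_down: 0   $n_unchanged: 5891

# maturation classes on total-equalised dosage, and the gate table
mat <- classify_maturation(
  moderated_t(normalize_total(as_tibble(study)),
              a = sample_ids(study, "GV", "CTL"),
              b = sample_ids(study, "MII", "CTL"))
)
gate_crosstab(calls, mat)
#> <gate_table> 6000 genes
#>            maturation
#> ko_call     stabilized destabilized unchanged
#>   up                 0           14        95
#>   down               0            0         0
#>   unchanged          0          688      5203
#> up row: 95/109 unchanged, 14/109 destabilized, 0/109 stabilized

# positional motif enrichment around the stop codon
ranked <- dedupe_and_rank(cmp, sim$transcripts)
sets <- select_sets(ranked, set_size = 1000)
oms <- lapply(split(sets, sets$set_label), build_occurrence_matrix)
oms$upregulated
#> <occurrence_matrix> 1000 transcripts x 800 positions, stop_codon anchor,
#>   pattern GAC[UA]: 952 match sites
enrichment_test(oms$upregulated, oms$unchanged)
#> <enrichment_result> stop_codon: k = 507 of n = 1000 vs K = 909 of
#>   N = 2000 in [-400, 399]; p = 1.473e-06

# m6A metagene: stop-region prevalence, up set vs unchanged set
mm <- metagene_matrix(sim$models, condense_samples(sim$peaks))
gs <- split(sets$gene_id, sets$set_label)
stop_region_ttest(mm, gs$upregulated, gs$unchanged)
#> <region_ttest> t = 9.984, df = 1724.2, p = 7.383e-23
#>   (means 0.09523 vs 0.03413; n = 1000 vs 1000)
```

Reading the numbers: 109 genes are called up in the knockout at MII (of
~220 planted targets — the default knockout effect sits exactly on the
2-fold threshold, so ~half clear it, with essentially no false positives);
the up-called cohort is 87% maturation-unchanged / 13% destabilized / 0%
stabilized, the qualitative gate pattern expected when a decay factor is
removed; the upregulated set is strongly enriched for GAC(U/A)-bearing
windows at the stop codon (507 vs 442.5 expected hits, hypergeometric
p = 1.5e-06) but not at the start codon; and the planted m6A peaks make
stop-region prevalence ~2.8-fold higher in the up set (Welch p = 7e-23),
while the down set shows no enrichment.

The same analysis as a single seeded run, with every artifact on disk:

```r
report <- run_pipeline(list(seed = 42), out_dir = "demo")
# demo/report.json, demo/report.md, demo/run.log, demo/fixture/*, *.tsv
```

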