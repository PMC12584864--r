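# slscreen

Synthetic-lethality analysis of pooled CRISPR knockout dropout screens
run in paired wild-type / mutant haploid cell backgrounds, plus the
downstream validation statistics (amplicon allele tracking,
cell-competition assays, drug-sensitivity panel comparisons).

A synthetic-lethal (SL) partner of a mutated gene — say a mismatch-repair
gene or a tumour suppressor — is a gene whose knockout kills the mutant
cells but not wild-type cells. Dropout screens detect this as
guide-specific depletion in the mutant pool over ~3 weeks of passaging.
This package implements the full hit-calling cascade for that design and
a set of seeded generators that emulate every assay with known ground
truth, so the whole pipeline is testable without any external data.

## The core statistic

For each gene *g* and comparison, the CRISPR score is the mean of its
guides' log2 abundance ratios,

    CS_g = mean_i  log2( (a_i(cond1) + c) / (a_i(cond2) + c) ),

with abundances averaged over replicates and a small pseudocount *c*.
Three comparisons are scored — WT (WT final vs WT baseline), MUT
(mutant final vs WT baseline) and MUT\* (mutant final vs WT final) —
by three pipelines differing in normalization and test (rpm + t-test;
median-of-ratios + rank-sum against non-targeting controls;
control-scaled + permutation), each Benjamini–Hochberg adjusted.
Candidates must be depleted in MUT\*, follow one of three
mutant-specific trends across the WT/MUT comparisons, pass in at least
two pipelines, survive an expression filter, and show quartile-level
separation of their guides' Z-scores between mutant-final and wild-type
samples. `vignettes/synthetic-lethality-screens.Rmd` walks through the
model and every convention.

## Worked example

```r
library(slscreen)

genes <- sprintf("G%02d", 1:30)
lib <- build_custom_library(genes, sgrnas_per_gene = 4,
                            n_nontargeting = 12, seed = 1)
eff <- gene_effect_table(genes, sl_genes = c("G01", "G02"),
                        essential_genes = "G03")
sim <- simulate_screen_counts(screen_sim_config(lib, eff, seed = 1))
hits <- call_hits(sim$counts, sim$samples, lib, sim$expression,
                  config = hit_call_config(n_perm = 300), seed = 1)
hits
#> Synthetic-lethality hit call
#>   genes scored: 30 | expressed: 30 | consensus: 2 | final candidates: 2
#> # A tibble: 2 × 8
#>   gene  n_pipelines pipelines trend consensus cs_MUT_star p_adj_MUT_star
#>   <chr>       <int> <chr>     <int> <lgl>           <dbl>          <dbl>
#> 1 G01             3 A,B,C         3 TRUE            -6.79         0.0280
#> 2 G02             3 A,B,C         3 TRUE            -5.78         0.0280
```

Both planted SL genes (and only they) come back: each was depleted in
the mutant-vs-wild-type comparisons (CS around −6 to −7 log2 units,
i.e. ~100-fold guide dropout), static in the WT screen, flagged by all
three pipelines, and passed the quartile filter; the planted essential
gene G03 is excluded by the trend predicate because it also drops out
in wild type. `tidy(hits)` returns the candidate table, `glance(hits)`
per-stage counts, `autoplot(hits)` a volcano plot.

The same pattern applies to the other assays:
`simulate_amplicon_timecourse()` → `allele_frequencies()` →
`normalize_trajectories()` → `group_trend_test()` for allele tracking;
`simulate_competition()` → `normalize_competition()` →
`competition_test()`; `simulate_sensitivity_panel()` →
`group_ccls_by_mmr()` → `compare_sensitivity()`.

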