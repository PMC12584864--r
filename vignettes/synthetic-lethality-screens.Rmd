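---
title: "Calling synthetic-lethality hits from paired haploid CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling synthetic-lethality hits from paired haploid CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slscreen)
library(dplyr)
```

## The problem

A synthetic-lethal (SL) partner of a tumour-suppressor gene is a gene
whose loss kills cells that have already lost the tumour suppressor,
while sparing wild-type cells. Pooled CRISPR knockout dropout screens
find such partners by transducing a guide library into matched
wild-type (WT) and mutant (MUT) haploid cell populations, passaging
them for about three weeks, and sequencing the guide cassette at
successive time points: guides against an SL partner disappear from
the mutant pool but not from the wild-type pool. Haploid cells make
the readout unusually clean — one genome copy means one edit fully
determines the genotype of a cell, for the screen as well as for the
amplicon-level validation assays this package also covers.

## The score and the three comparisons

Guide counts are normalized per sample and, for each comparison, the
CRISPR score of gene $g$ is the unweighted mean of its guides' log2
abundance ratios:

$$\mathrm{CS}_g = \frac{1}{|S_g|}\sum_{i \in S_g}
  \log_2\frac{\bar{a}_i(\text{cond. 1}) + c}{\bar{a}_i(\text{cond. 2}) + c},$$

where $\bar a_i$ is the guide's normalized abundance averaged over the
replicate samples of a condition and $c$ a pseudocount. Three
comparisons are scored: **WT** (WT final day vs WT baseline), **MUT**
(mutant final day vs WT baseline) and **MUT\*** (mutant final vs WT
final). The WT baseline anchors all three because immediately after
selection both pools still carry the unperturbed library
representation; the mutant screens may run a few days longer than the
wild type, which the comparisons accommodate by always pairing named
final days.

Significance comes from three deliberately different pipelines sharing
the CS definition, so that the later consensus rule spans parametric,
rank-based and resampling nulls:

* **A** — reads-per-million normalization; one-sample two-sided t-test
  of the gene's guide log-ratios against zero.
* **B** — median-of-ratios (DESeq-style) normalization; two-sided
  Wilcoxon rank-sum of the gene's guide log-ratios against the
  non-targeting-control log-ratios.
* **C** — control-scaled normalization (non-targeting totals define
  the per-sample scale); permutation test drawing, per gene, `n_perm`
  random guide sets of the same size from all guides, with
  $p = (1 + \#\{|CS_{null}| \ge |CS_{obs}|\})/(1 + n_\mathrm{perm})$.

p-values are Benjamini–Hochberg adjusted within each
(pipeline, comparison) stratum.

## The hit-calling cascade

`call_hits()` runs, in order: expression filter → scoring →
class assignment → trend selection → pipeline consensus →
quartile-separation filter.

Classes per (gene, comparison): **depleted** (CS < −0.5 and p < α),
**enriched** (CS > 0.5 and p < α), **static** (|CS| ≤ 0.5). A gene is
a trend hit when it is depleted in MUT\* and additionally (1) static
in MUT and enriched in WT, (2) depleted in MUT and enriched in WT, or
(3) depleted in MUT and static in WT; all three demand
mutant-specific dropout and exclude generally essential genes. Genes
flagged in at least two of the three pipelines go forward; the final
filter keeps a gene only when the third quartile of its guides'
Z-scores (computed on fraction-normalized counts across all samples)
in the mutant-final samples lies strictly below the first quartiles in
both the WT baseline and WT final samples — the bulk of the guide
distribution must separate, not just the mean.

### Why "static" does not require significance by default

One reading of the class thresholds makes "static" require |CS| ≤ 0.5
*and* p < 0.05 — a significantly unchanged gene, which is an unusual
object. Taken literally, a truly neutral gene in the WT comparison
would be "static" only in the ~5% of cases where its null p-value
dips below α, and the three-trend predicate (whose WT arm is "enriched
or static") could essentially never fire for a genuine SL partner
whose WT behaviour is neutral. We therefore treat static as "no
meaningful change" (|CS| ≤ 0.5, no p condition) by default, which is
also how the screen's selection intent reads — depleted in the mutant,
enriched or *not significantly changed* in the wild type. The literal
rule remains available via
`hit_call_config(static_requires_significance = TRUE)`.

Other deliberately fixed conventions:

* **Pseudocount** (default 0.5) is interpreted in reads-per-million
  units and rescaled to each normalized table
  (`0.5 * mean column sum / 1e6`), so it always means half a read per
  million regardless of the normalization's natural scale.
* **Replicate aggregation**: abundances are averaged across a
  condition's replicates *before* the single log-ratio per guide, not
  per-replicate ratios averaged.
* **Quartiles** use linear interpolation between order statistics
  (type 7), and the separation inequality is strict, so ties fail.
* Zero-variance t-test inputs are reported at a p floor of 1e-12 with
  a QC flag; zero-variance guide rows get Z = 0 and are flagged.
* Pipeline C draws its permutation nulls per gene from a single RNG
  stream over genes in sorted-name order, with the guide pool sorted
  by id: p-values stay independent across genes while results are
  invariant to the row/column order of the inputs.
* Median-of-ratios normalization is defined on raw counts (matching
  the DESeq size-factor estimator): rescaling one sample's reads moves
  all abundances by a common factor, which cancels in every log-ratio;
  the other normalizations are exactly invariant.

## The synthetic screen generator

`simulate_screen_counts()` draws the expected read fraction of guide
$i$ (gene $g$, background $b$, day $t$) proportional to
$a_i \exp(u_i\, s_{g,b}\, t)$, with $a_i$ log-normal initial
abundances (sd 0.5 — a typical pooled-library skew), $u_i \sim
U(0.7, 1)$ per-guide efficiencies that give within-gene variation the
significance tests and the quartile filter must tolerate, and counts
negative-binomial with size 10 around `fraction × depth`
(over-dispersed sequencing noise; the default depth of 500 reads per
guide reflects deeply sequenced pooled screens). Effect classes: neutral ($s=0$), essential
($s<0$ both backgrounds), SL ($s<0$ mutant only), WT-advantage
($s>0$ wild type). Defaults mirror the screening design: five
sampling days, day 1 baseline, 21 days for WT and up to 27 for the
mutant, two replicates.

What it does **not** emulate: PCR duplicates and sequencing errors,
guide-level off-target effects, copy-number artefacts (the cells are
haploid), batch effects, and changing library representation during
selection. Passing tests therefore demonstrate the statistical
machinery under a clean exponential-growth model, not robustness to
every artefact of real screens.

```{r screen-example}
genes <- sprintf("G%02d", 1:30)
lib <- build_custom_library(genes, sgrnas_per_gene = 4,
                            n_nontargeting = 12, seed = 1)
eff <- gene_effect_table(genes, sl_genes = c("G01", "G02"),
                         essential_genes = "G03")
sim <- simulate_screen_counts(screen_sim_config(lib, eff, seed = 1))
hits <- call_hits(sim$counts, sim$samples, lib, sim$expression,
                  config = hit_call_config(n_perm = 300), seed = 1)
tidy(hits)
```

## Amplicon allele tracking

The validation assay deep-sequences one edited locus in haploid WT and
mutant cells over time. Alleles are compact descriptor strings relative
to the Cas9 cut site (`"D:-2:3"`, `"I:0:AT"`, `"WT"`); the frame class
is pure indel arithmetic — net length change not divisible by three is
a frameshift (FS, loss of function in a haploid cell), divisible is
non-frameshift, no indel is WT. A nonsense substitution would also be
LoF but is not derivable from indel arithmetic; substitution-only
alleles are classed WT and this is a documented limitation. Locations
reference the affected position nearest the cut site (deletions
spanning it get 0; ties between sides break toward the negative,
PAM-distal side — an arbitrary documented convention), and the
clustering QC reports both read-weighted and allele-level fractions
within a ±5 bp window by default.

Trajectories keep FS alleles present at the first time point in both
groups, divide each allele's frequency path by its first-time-point
frequency within each replicate, and average replicates afterwards,
so every trajectory starts at exactly 1. The group trend test is a
two-sided Welch t-test on per-allele fold-changes at a chosen time
point (Student's and a paired-by-allele variant are options; Welch is
the default for robustness to unequal spread). Fold-change noise is
ratio-like and heavy-tailed, which makes the test mildly conservative
at α = 0.05 in our calibration.

The amplicon generator defaults describe a strongly selective regime:
200 edited alleles (138 frameshift), indel offsets geometric with
p = 0.5 around the cut, 80% editing, FS fitness 1.2/day in WT and
0.8/day in the mutant (the direction in which LoF of a true SL
partner rescues WT cells but kills mutant ones), three time points
over two weeks, 20,000 reads per sample, two replicates.

## Validation statistics

Competition assays (a labelled KO population mixed with WT cells and
followed by FACS) are normalized to each replicate's first time point
and compared arm-to-arm with a one-sided t-test per time point
(treated below control); the baseline day is excluded from the default
windows since normalization pins it to 1. Latent dynamics follow the
logistic curve $f(t) = f_0 e^{st}/(f_0 e^{st} + 1 - f_0)$. Cell-line
sensitivity panels are grouped by mismatch-repair status — deficient
requires microsatellite instability *and* a mutated MMR gene,
proficient requires stability *and* no mutation, everything else is
excluded — and compared with a two-sample two-sided Kolmogorov–Smirnov
test (exact p when both groups have ≤ 25 lines).

## Problem sizes used by the test suite

The packaged checks run a 1000-gene × 4-guide screen with 100
non-targeting controls (planted: 20 SL, 50 essential, 30 WT-advantage
genes) for recovery, 20 neutral replicates of the same design for null
calibration, 1000 neutral and 200 selective amplicon simulations for
the trend test, and 1000 random alleles against a translation oracle.
These sizes keep a full run in a few minutes while leaving Monte-Carlo
error well below the asserted margins.

## Known limitations

* The three pipelines share one CS definition; consensus diversity
  comes from normalization and test choice only.
* The expression filter is a hard threshold on a user-supplied table;
  no attempt is made to model dosage.
* Frame classification ignores substitution consequences and assumes
  descriptor coordinates are already aligned to the cut site by the
  upstream variant caller.
* The quartile filter needs at least two guide observations per sample
  group and fails (conservatively) otherwise.
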