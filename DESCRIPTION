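Package: slscreen
Title: Synthetic-Lethality Analysis of Pooled CRISPR Dropout Screens in
    Paired Haploid Backgrounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level scoring and consensus hit calling for pooled
    CRISPR knockout dropout screens run in matched wild-type and mutant
    haploid backgrounds. Computes CRISPR scores (mean per-sgRNA log2
    fold-changes), per-gene significance through three complementary
    pipelines (parametric, rank-based versus non-targeting controls, and
    permutation), and calls synthetic-lethality candidates with an
    expression filter, a three-trend class predicate, a multi-pipeline
    consensus rule and a quartile-separation filter on per-sgRNA
    Z-scores. Also provides the downstream validation toolkit: amplicon
    allele tracking in haploid cells (frameshift classification,
    cut-site clustering QC, first-timepoint-normalised trajectories and
    group trend tests), cell-competition assay statistics, and
    mismatch-repair-status grouping with Kolmogorov-Smirnov sensitivity
    comparisons. Ships seeded generators that emulate every assay with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
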