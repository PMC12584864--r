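# small fixtures built in code

tiny_library <- function(n_genes = 6L, sgrnas_per_gene = 4L,
                         n_nontargeting = 8L, seed = 42L) {
  build_custom_library(sprintf("G%02d", seq_len(n_genes)),
                       sgrnas_per_gene = sgrnas_per_gene,
                       n_nontargeting = n_nontargeting, seed = seed)
}

tiny_screen <- function(n_genes = 30L, sl = 2L, essential = 2L,
                        wt_adv = 2L, seed = 7L, ...) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  lib <- build_custom_library(genes, sgrnas_per_gene = 4L,
                              n_nontargeting = 12L, seed = seed)
  eff <- gene_effect_table(
    genes,
    sl_genes = genes[seq_len(sl)],
    essential_genes = genes[sl + seq_len(essential)],
    wt_advantage_genes = genes[sl + essential + seq_len(wt_adv)]
  )
  cfg <- screen_sim_config(lib, eff, seed = seed, ...)
  c(simulate_screen_counts(cfg), list(library = lib, config = cfg))
}

neutral_w <- function() {
  list(FS = c(WT = 1, MUT = 1), NFS = c(WT = 1, MUT = 1),
       WT = c(WT = 1, MUT = 1))
}
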