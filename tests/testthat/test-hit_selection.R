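test_that("class thresholds are applied literally", {
  cfg <- hit_call_config()
  expect_equal(classify_gene(-0.6, 0.01, cfg), "depleted")
  expect_equal(classify_gene(0.6, 0.01, cfg), "enriched")
  expect_equal(classify_gene(0.2, 0.01, cfg), "static")
  # boundary: |CS| exactly at the cut is static, not depleted/enriched
  expect_equal(classify_gene(c(-0.5, 0.5), c(0.01, 0.01), cfg),
               c("static", "static"))
  expect_equal(classify_gene(0.6, 0.2, cfg), "unclassified")
  # a small, non-significant change is static by default but
  # unclassified under the fully literal reading
  strict <- hit_call_config(static_requires_significance = TRUE)
  expect_equal(classify_gene(0.2, 0.2, cfg), "static")
  expect_equal(classify_gene(0.2, 0.2, strict), "unclassified")
  expect_error(classify_gene(0.1, 1.2, cfg), "0, 1")
})

test_that("depleted calls are monotone in alpha and cs_cut", {
  set.seed(41)
  cs <- runif(200, -3, 3)
  p <- runif(200)
  base <- classify_gene(cs, p, hit_call_config(alpha = 0.03, cs_cut = 0.8))
  relaxed <- classify_gene(cs, p, hit_call_config(alpha = 0.1, cs_cut = 0.4))
  expect_true(all(which(base == "depleted") %in% which(relaxed == "depleted")))
})

test_that("expression filter removes silent and unknown genes", {
  expr <- tibble::tibble(gene = paste0("G", 1:10),
                         expression = c(rep(10, 7), 0, 0.5, 0))
  kept <- expression_filter(paste0("G", 1:10), expr, threshold = 1)
  expect_equal(kept, paste0("G", 1:7))
  expect_equal(expression_filter(paste0("G", 1:10), expr, threshold = 0),
               paste0("G", 1:10))
  expect_warning(
    out <- expression_filter(c("G1", "NOVEL"), expr, 1),
    "unexpressed"
  )
  expect_equal(out, "G1")
})

test_that("trend predicate matches the hand-coded truth table on all 64 triples", {
  classes <- c("depleted", "enriched", "static", "unclassified")
  grid <- expand.grid(MUT_star = classes, MUT = classes, WT = classes,
                      stringsAsFactors = FALSE)
  tbl <- tibble::tibble(
    gene = rep(sprintf("g%02d", seq_len(nrow(grid))), times = 3),
    comparison = rep(c("MUT_star", "MUT", "WT"), each = nrow(grid)),
    class = c(grid$MUT_star, grid$MUT, grid$WT)
  )
  got <- select_trend_hits(tbl)
  got <- got[match(sprintf("g%02d", seq_len(nrow(grid))), got$gene), ]
  want <- mapply(trend_truth, grid$MUT_star, grid$MUT, grid$WT)
  expect_equal(got$trend, unname(want))
  expect_equal(got$hit, unname(!is.na(want)))
  expect_error(select_trend_hits(tbl[tbl$comparison != "WT", ]), "WT")
})

test_that("consensus keeps genes hit in enough pipelines", {
  ph <- tibble::tibble(
    gene = c("A", "A", "B", "C", "C", "C"),
    pipeline = c("A", "B", "A", "A", "B", "C"),
    hit = TRUE, trend = c(1L, 1L, 3L, 2L, 3L, 3L)
  )
  cons <- consensus_merge(ph, min_pipelines = 2)
  expect_equal(cons$gene[cons$consensus], c("A", "C"))
  expect_equal(cons$trend[cons$gene == "C"], 3L)
  all_union <- consensus_merge(ph, min_pipelines = 1)
  expect_equal(sort(all_union$gene[all_union$consensus]), c("A", "B", "C"))
  # adding a pipeline never shrinks the consensus at fixed min_pipelines
  extra <- dplyr::bind_rows(ph, tibble::tibble(gene = "B", pipeline = "C",
                                               hit = TRUE, trend = 3L))
  cons2 <- consensus_merge(extra, min_pipelines = 2)
  expect_true(all(cons$gene[cons$consensus] %in% cons2$gene[cons2$consensus]))
})

test_that("quartile separation uses interpolated quartiles and strict inequality", {
  z <- tibble::tibble(
    sgrna_id = paste0("G1_sg", 1:4),
    mut_f = c(-2, -1.5, -1.2, -1.0),
    wt_1 = c(0.5, 0.8, 1.0, 1.2),
    wt_f = c(0.5, 0.8, 1.0, 1.2)
  )
  samples <- tibble::tibble(
    sample_id = c("mut_f", "wt_1", "wt_f"),
    background = c("MUT", "WT", "WT"),
    day = c(27, 1, 21), replicate = 1L
  )
  lib <- tibble::tibble(sgrna_id = paste0("G1_sg", 1:4),
                        spacer = strrep("A", 20), target_gene = "G1",
                        category = "gene_targeting", label = NA)
  res <- quartile_separation_filter(z, samples, "G1", lib)
  # hand-interpolated quartiles of the two value sets
  expect_equal(res$q3_mut_final, -1.15)
  expect_equal(res$q1_wt_baseline, 0.725)
  expect_true(res$pass)
  expect_equal(res$q3_mut_final,
               quantile7_oracle(c(-2, -1.5, -1.2, -1.0), 0.75))

  # identical distributions in every group never separate
  z2 <- dplyr::mutate(z, mut_f = .data$wt_1)
  expect_false(quartile_separation_filter(z2, samples, "G1", lib)$pass)

  # complete separation always passes
  z3 <- dplyr::mutate(z, mut_f = .data$wt_1 - 10)
  expect_true(quartile_separation_filter(z3, samples, "G1", lib)$pass)

  # too few observations in a group fails with a recorded reason
  res4 <- quartile_separation_filter(z[1, ], samples, "G1", lib)
  expect_false(res4$pass)
  expect_match(res4$reason, "fewer than 2")
})

test_that("quantile type-7 matches the interpolation oracle on random data", {
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1))
    p <- runif(1)
    expect_equal(unname(quantile(x, p, type = 7)), quantile7_oracle(x, p),
                 tolerance = 1e-12)
  }
})

test_that("the cascade recovers planted SL genes and excludes essentials", {
  sim <- tiny_screen(n_genes = 40, sl = 3, essential = 3, wt_adv = 3,
                     seed = 19)
  res <- call_hits(sim$counts, sim$samples, sim$library, sim$expression,
                   config = hit_call_config(n_perm = 300), seed = 2)
  cand <- tidy(res)$gene
  sl <- sim$truth$gene[sim$truth$class_label == "sl_mutant_only"]
  ess <- sim$truth$gene[sim$truth$class_label == "essential"]
  # small-screen noise can blur one gene's WT arm; most must be recovered
  expect_gte(sum(sl %in% cand), 2)
  expect_length(intersect(cand, ess), 0)
  expect_true(all(cand %in% sl))
  g <- glance(res)
  expect_equal(g$n_candidates, length(cand))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("unexpressed planted hits are removed by the expression filter", {
  sim <- tiny_screen(n_genes = 40, sl = 3, essential = 0, wt_adv = 0,
                     seed = 23, unexpressed_genes = "G01")
  res <- call_hits(sim$counts, sim$samples, sim$library, sim$expression,
                   config = hit_call_config(n_perm = 300), seed = 2)
  expect_false("G01" %in% tidy(res)$gene)
})

test_that("candidate sets are invariant to row and column permutations", {
  sim <- tiny_screen(n_genes = 25, sl = 2, essential = 2, wt_adv = 2,
                     seed = 29)
  cfg <- hit_call_config(n_perm = 300)
  res1 <- call_hits(sim$counts, sim$samples, sim$library, sim$expression,
                    config = cfg, seed = 4)
  set.seed(99)
  shuf <- sim$counts[sample(nrow(sim$counts)),
                     c(1, 1 + sample(nrow(sim$samples)))]
  res2 <- call_hits(shuf, sim$samples[sample(nrow(sim$samples)), ],
                    sim$library, sim$expression, config = cfg, seed = 4)
  expect_setequal(tidy(res1)$gene, tidy(res2)$gene)
})
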