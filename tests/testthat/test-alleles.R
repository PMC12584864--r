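test_that("frame classification follows indel arithmetic", {
  expect_equal(classify_alleles("D:0:1"), "FS")
  expect_equal(classify_alleles("D:0:3"), "NFS")
  expect_equal(classify_alleles("I:0:AT;D:4:2"), "NFS")  # net 0
  expect_equal(classify_alleles("WT"), "WT")
  expect_equal(classify_alleles("S:2:AG"), "WT")  # substitutions keep frame
  expect_equal(classify_alleles("I:0:AT"), "FS")
  expect_equal(classify_alleles(c("D:-3:6", "I:1:ACGTA")), c("NFS", "FS"))
})

test_that("descriptor parsing round-trips and rejects malformed tokens", {
  d <- parse_descriptor("D:-2:3")
  expect_equal(d$events$kind, "deletion")
  expect_equal(d$events$start, -2L)
  expect_equal(d$events$length, 3L)
  i <- parse_descriptor("I:0:AT")
  expect_equal(i$net_length, 2L)
  expect_equal(i$class, "FS")
  wt <- parse_descriptor("WT")
  expect_equal(nrow(wt$events), 0)
  expect_equal(wt$class, "WT")
  for (s in c("D:-2:3;I:5:ACG", "WT", "S:0:A", "I:-1:T;D:2:2;S:9:GG")) {
    expect_equal(format_descriptor(parse_descriptor(s)$events), s)
  }
  expect_error(parse_descriptor("D:xx:3"), "Malformed")
  expect_error(classify_alleles("D:1:0"), "Malformed")
  expect_error(classify_alleles("WT;D:1:1"), "combined")
})

test_that("allele location takes the affected position nearest the cut", {
  expect_equal(allele_location("D:-1:3"), 0L)   # spans the cut site
  expect_equal(allele_location("D:4:3"), 4L)    # nearest end of +4..+6
  expect_equal(allele_location("D:-6:3"), -4L)  # nearest end of -6..-4
  expect_equal(allele_location("I:-3:A"), -3L)
  # multi-event: minimum over events, ties broken toward negative
  expect_equal(allele_location("D:-5:2;I:2:G"), 2L)
  expect_equal(allele_location("D:-2:1;I:2:G"), -2L)
  expect_error(allele_location("WT"), "no location")
})

test_that("classifier agrees exactly with the translation oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(77)
  cds <- random_cds()
  n <- 300
  for (i in seq_len(n)) {
    events <- random_event_list()
    desc <- events_to_descriptor(events)
    expect_identical(classify_alleles(desc), frame_class_oracle(cds, events),
                     label = desc)
  }
})

test_that("frequencies are per-sample fractions summing to one", {
  tbl <- tibble::tibble(
    allele = rep(c("WT", "D:0:1", "D:0:3"), 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    count = c(80, 15, 5, 10, 80, 10)
  )
  fr <- allele_frequencies(tbl)
  expect_equal(fr$frequency[fr$sample_id == "s1"], c(0.80, 0.15, 0.05))
  sums <- tapply(fr$frequency, fr$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  bad <- dplyr::mutate(tbl, count = ifelse(sample_id == "s2", 0, count))
  expect_error(allele_frequencies(bad), "s2")
})

test_that("frequencies are stable under uniform read downsampling", {
  sim <- simulate_amplicon_timecourse(
    amplicon_sim_config(n_alleles = 40, reads_per_sample = 50000, seed = 13)
  )
  fr_full <- allele_frequencies(sim$table)
  set.seed(14)
  thin <- dplyr::mutate(sim$table, count = rbinom(dplyr::n(), count, 0.1))
  fr_thin <- allele_frequencies(thin)
  j <- dplyr::inner_join(fr_full, fr_thin, by = c("allele", "sample_id"))
  expect_lt(max(abs(j$frequency.x - j$frequency.y)), 0.03)
})

test_that("allele table TSV parses and validates", {
  tbl <- tibble::tibble(allele = c("WT", "D:0:1"), sample_id = "s1",
                        count = c(5, 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_equal(as.data.frame(parse_allele_table(path)), as.data.frame(tbl))
  readr::write_tsv(tibble::tibble(allele = "D:bad", sample_id = "s1",
                                  count = 1), path)
  expect_error(parse_allele_table(path), "Malformed")
})

test_that("cut-site clustering handles the worked example and boundaries", {
  tbl <- tibble::tibble(
    allele = c("D:0:1", "I:1:A", "D:-1:1", "I:2:C", "D:10:1"),
    sample_id = "s1", count = 10
  )
  qc <- cutsite_clustering_qc(tbl, window = 5)
  expect_equal(qc$frac_reads, 0.8)
  expect_equal(qc$frac_alleles, 0.8)
  all0 <- dplyr::mutate(tbl, allele = paste0("I:0:", c("A", "C", "G", "T", "AA")))
  expect_equal(cutsite_clustering_qc(all0, 0)$frac_reads, 1)
  wt_only <- tibble::tibble(allele = "WT", sample_id = "s1", count = 5)
  expect_message(qc0 <- cutsite_clustering_qc(wt_only, 5), "undefined")
  expect_true(is.na(qc0$frac_reads))
})

test_that("trajectories are tp1-normalized and restricted to shared LoF alleles", {
  samples <- tidyr::expand_grid(background = c("WT", "MUT"),
                                day = c(0, 7, 14), replicate = 1L) %>%
    dplyr::mutate(sample_id = sprintf("%s_%g", background, day))
  mk <- function(allele, wt_path, mut_path) {
    tibble::tibble(
      allele = allele,
      sample_id = c(sprintf("WT_%g", c(0, 7, 14)),
                    sprintf("MUT_%g", c(0, 7, 14))),
      count = c(wt_path, mut_path)
    )
  }
  tbl <- dplyr::bind_rows(
    mk("D:0:1", c(200, 100, 50), c(100, 100, 100)),
    mk("D:1:2", c(100, 100, 100), c(50, 100, 200)),
    mk("D:0:3", c(100, 100, 100), c(100, 100, 100)),   # NFS: excluded
    mk("I:0:A", c(0, 10, 10), c(100, 100, 100)),       # absent at WT tp1
    mk("WT", c(600, 690, 740), c(650, 600, 500))
  )
  tr <- normalize_trajectories(allele_frequencies(tbl), samples)
  expect_setequal(unique(tr$allele), c("D:0:1", "D:1:2"))
  expect_true(all(tr$fold_change[tr$day == 0] == 1))
  d01_wt <- tr$fold_change[tr$allele == "D:0:1" & tr$group == "WT"]
  totals_wt <- c(1000, 1000, 1000)  # constructed equal totals
  expect_equal(d01_wt, c(200, 100, 50) / 200)
})

test_that("group trend test separates selection regimes and is symmetric under the null", {
  sim <- simulate_amplicon_timecourse(amplicon_sim_config(seed = 55))
  tr <- normalize_trajectories(allele_frequencies(sim$table), sim$samples)
  tt <- group_trend_test(tr)
  expect_gt(tt$mean_wt, 1)
  expect_lt(tt$mean_mut, 1)
  expect_lt(tt$p_value, 1e-6)
  # paired variant agrees in direction
  tp <- group_trend_test(tr, paired = TRUE)
  expect_lt(tp$p_value, 1e-6)
  # identical groups: p = 1 exactly for the paired test on equal vectors
  eq <- tibble::tibble(
    allele = rep(c("D:0:1", "D:0:2", "D:0:4"), 2),
    group = rep(c("WT", "MUT"), each = 3),
    day = 7, fold_change = rep(c(0.5, 1, 2), 2)
  )
  expect_equal(group_trend_test(eq, day = 7)$p_value, 1, tolerance = 1e-12)
})

test_that("top alleles are ranked by cumulative frequency among LoF", {
  tbl <- tibble::tibble(
    allele = rep(c("D:0:1", "D:0:2", "D:0:4", "D:0:3", "WT"), 2),
    sample_id = rep(c("s1", "s2"), each = 5),
    count = c(50, 30, 10, 5, 5, 40, 35, 15, 5, 5)
  )
  fr <- allele_frequencies(tbl)
  top <- top_alleles(fr, k = 2)
  expect_equal(top$allele, c("D:0:1", "D:0:2"))
  expect_equal(top$rank, 1:2)
  one <- top_alleles(fr, k = 1)
  expect_equal(one$allele, "D:0:1")
  expect_warning(all3 <- top_alleles(fr, k = 10), "available")
  expect_equal(nrow(all3), 3)  # the NFS D:0:3 and WT never rank
})

test_that("top alleles dominate a concentrated simulated spectrum", {
  sim <- simulate_amplicon_timecourse(amplicon_sim_config(seed = 61))
  fr <- allele_frequencies(sim$table)
  top5 <- top_alleles(fr, k = 5)
  fs_total <- sum(fr$frequency[classify_alleles(fr$allele) == "FS"])
  share <- sum(top5$cumulative_frequency) / fs_total
  expect_gt(share, 0.1)  # direction only: a handful of alleles carry real mass
})
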