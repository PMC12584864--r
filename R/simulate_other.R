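#' Configuration for the amplicon allele-dynamics simulator
#'
#' Emulates deep amplicon sequencing of a Cas9-edited locus in haploid
#' cells followed over time in two backgrounds. Indel start offsets
#' decay geometrically with distance from the cut site, frame class is
#' set by drawing indel lengths congruent to the target class, and
#' allele frequencies evolve under per-day multiplicative fitness
#' `w(class, background)` before multinomial read sampling.
#'
#' @param n_alleles Number of distinct edited indel alleles
#'   (default 200).
#' @param p_geo Geometric decay parameter of `|offset|` from the cut
#'   site (default 0.5).
#' @param frameshift_fraction Fraction of edited alleles that are
#'   frameshift (default 0.69, so the default allele count yields 138
#'   FS alleles).
#' @param insertion_prob Probability an indel is an insertion
#'   (default 0.3).
#' @param n_substitutions Extra substitution-only alleles, classed WT
#'   (default 3).
#' @param unedited_share Initial frequency of the unedited allele
#'   (default 0.2, i.e. 80 percent editing).
#' @param w Named list of per-day fitness by class, each a named
#'   vector over backgrounds; default FS alleles gain 1.2-fold/day in
#'   WT and lose to 0.8-fold/day in MUT, all else neutral.
#' @param days Sampling days, first is the baseline (default 0, 7,
#'   14).
#' @param reads_per_sample Reads per sample (default 20000).
#' @param replicates Replicates per background/day (default 2).
#' @param seed Integer seed.
#' @return An `amplicon_sim_config` list.
#' @export
amplicon_sim_config <- function(n_alleles = 200L, p_geo = 0.5,
                                frameshift_fraction = 0.69,
                                insertion_prob = 0.3,
                                n_substitutions = 3L,
                                unedited_share = 0.2,
                                w = list(FS = c(WT = 1.2, MUT = 0.8),
                                         NFS = c(WT = 1, MUT = 1),
                                         WT = c(WT = 1, MUT = 1)),
                                days = c(0, 7, 14),
                                reads_per_sample = 20000L,
                                replicates = 2L, seed = 1L) {
  if (n_alleles < 2L) abort("`n_alleles` must be >= 2.")
  stopifnot_scalar_number(p_geo, "p_geo", lower = 1e-6, upper = 1)
  stopifnot_scalar_number(frameshift_fraction, "frameshift_fraction", 0, 1)
  stopifnot_scalar_number(unedited_share, "unedited_share", 0, 1 - 1e-9)
  if (length(days) < 2L || any(diff(days) <= 0)) {
    abort("`days` must be >= 2 strictly increasing values.")
  }
  for (cls in c("FS", "NFS", "WT")) {
    if (is.null(w[[cls]]) || any(w[[cls]] <= 0) ||
        !all(c("WT", "MUT") %in% names(w[[cls]]))) {
      abort("`w` needs positive entries for WT and MUT in classes FS, NFS, WT.")
    }
  }
  structure(
    list(n_alleles = as.integer(n_alleles), p_geo = p_geo,
         frameshift_fraction = frameshift_fraction,
         insertion_prob = insertion_prob,
         n_substitutions = as.integer(n_substitutions),
         unedited_share = unedited_share, w = w, days = days,
         reads_per_sample = as.integer(reads_per_sample),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "amplicon_sim_config"
  )
}

random_dna <- function(lengths) {
  vapply(lengths, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# n unique single-indel descriptors with the requested frame classes;
# offsets decay geometrically from the cut site, lengths are
# 1 + geometric resampled into (FS) or scaled into (NFS) the frame class
random_indel_alleles <- function(n, is_fs, p_geo, insertion_prob) {
  draw <- function(k, fs) {
    offset <- rgeom(k, p_geo) * sample(c(-1L, 1L), k, replace = TRUE)
    len <- 1L + rgeom(k, 0.5)
    while (any(bad <- fs & len %% 3L == 0L)) {
      len[bad] <- 1L + rgeom(sum(bad), 0.5)
    }
    len[!fs] <- 3L * (1L + rgeom(sum(!fs), 0.6))
    ins <- runif(k) < insertion_prob
    out <- sprintf("D:%d:%d", offset, len)
    if (any(ins)) out[ins] <- sprintf("I:%d:%s", offset[ins],
                                      random_dna(len[ins]))
    out
  }
  alleles <- draw(n, is_fs)
  while (anyDuplicated(alleles)) {
    dup <- which(duplicated(alleles))
    alleles[dup] <- draw(length(dup), is_fs[dup])
  }
  alleles
}

#' Simulate an amplicon allele-tracking time course
#'
#' @param config An [amplicon_sim_config()].
#' @return A list with `table` (long tibble `allele`, `sample_id`,
#'   `count`), `samples` (sample sheet) and `truth` (tibble `allele`,
#'   `class`, `w_wt`, `w_mut`, `f0`).
#' @examples
#' sim <- simulate_amplicon_timecourse(amplicon_sim_config(n_alleles = 20))
#' head(sim$table)
#' @export
simulate_amplicon_timecourse <- function(config) {
  if (!inherits(config, "amplicon_sim_config")) {
    abort("`config` must come from amplicon_sim_config().")
  }
  with_seed(config$seed, {
    n_fs <- round(config$n_alleles * config$frameshift_fraction)
    is_fs <- c(rep(TRUE, n_fs), rep(FALSE, config$n_alleles - n_fs))
    alleles <- random_indel_alleles(config$n_alleles, is_fs, config$p_geo,
                                    config$insertion_prob)
    subs <- character(0)
    if (config$n_substitutions > 0L) {
      repeat {
        subs <- sprintf("S:%d:%s",
                        rgeom(config$n_substitutions, config$p_geo) *
                          sample(c(-1L, 1L), config$n_substitutions, TRUE),
                        sample(c("A", "C", "G", "T"), config$n_substitutions,
                               TRUE))
        if (!anyDuplicated(subs)) break
      }
    }
    all_alleles <- c(alleles, subs, "WT")
    cls <- classify_alleles(all_alleles)

    # Dirichlet initial frequencies over edited alleles; the unedited
    # allele keeps its configured share
    g <- rgamma(length(all_alleles) - 1L, 1)
    f0 <- c(g / sum(g) * (1 - config$unedited_share), config$unedited_share)

    samples <- tidyr::expand_grid(
      background = c("WT", "MUT"), day = config$days,
      replicate = seq_len(config$replicates)
    ) %>%
      dplyr::mutate(sample_id = sprintf("%s_d%g_r%d", .data$background,
                                        .data$day, .data$replicate))

    w_tbl <- vapply(config$w, function(x) x[c("WT", "MUT")],
                    numeric(2))  # 2 x class matrix
    n_a <- length(all_alleles)
    cnt <- matrix(0, n_a, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      w <- w_tbl[samples$background[j], cls]
      f <- f0 * w^samples$day[j]
      cnt[, j] <- rmultinom(1, config$reads_per_sample, f / sum(f))
    }
    counts <- tibble::tibble(
      allele = rep(all_alleles, nrow(samples)),
      sample_id = rep(samples$sample_id, each = n_a),
      count = as.vector(cnt)
    )

    list(
      table = counts,
      samples = dplyr::select(samples, "sample_id", "background", "day",
                              "replicate"),
      truth = tibble::tibble(
        allele = all_alleles, class = cls,
        w_wt = w_tbl["WT", cls], w_mut = w_tbl["MUT", cls], f0 = f0
      )
    )
  })
}

#' Simulate a two-population cell-competition assay
#'
#' A labelled knockout population with per-day log-fitness difference
#' `s` competes against wild-type cells; the latent knockout fraction
#' follows the logistic curve
#' `f(t) = f0 e^{st} / (f0 e^{st} + 1 - f0)` and the observed fraction
#' is binomial over `n_cells_observed` FACS-scored cells.
#'
#' @param f0 Initial knockout fraction in (0, 1).
#' @param s Per-day log-fitness difference (0 = neutral).
#' @param days Observation days.
#' @param n_cells_observed Cells scored per measurement
#'   (default 10000).
#' @param replicates Replicates per day (default 3).
#' @param condition Condition label (default `"control"`).
#' @param seed Integer seed.
#' @return Tibble `day`, `replicate`, `condition`, `fraction_ko`,
#'   `latent_fraction`.
#' @examples
#' simulate_competition(0.5, log(2), days = 0:3, seed = 2)
#' @export
simulate_competition <- function(f0, s, days, n_cells_observed = 10000L,
                                 replicates = 3L, condition = "control",
                                 seed = 1L) {
  stopifnot_scalar_number(f0, "f0", lower = 1e-12, upper = 1 - 1e-12)
  with_seed(seed, {
    tidyr::expand_grid(day = days, replicate = seq_len(replicates)) %>%
      dplyr::mutate(
        condition = condition,
        latent_fraction = f0 * exp(s * .data$day) /
          (f0 * exp(s * .data$day) + 1 - f0),
        fraction_ko = rbinom(dplyr::n(), n_cells_observed,
                             .data$latent_fraction) / n_cells_observed
      ) %>%
      dplyr::select("day", "replicate", "condition", "fraction_ko",
                    "latent_fraction")
  })
}

#' Simulate a cell-line drug-sensitivity panel
#'
#' Two groups of cell lines with normally distributed sensitivity
#' (log2 viability ratio, treatment vs control; more negative = more
#' sensitive). Group A records are annotated microsatellite-instable
#' with a mismatch-repair mutation (MMR-deficient under the grouping
#' rule), group B microsatellite-stable without one (MMR-proficient).
#'
#' @param n_group_a,n_group_b Group sizes (>= 2).
#' @param mean_a,mean_b Group means (defaults -2 and -0.5: deficient
#'   lines more sensitive).
#' @param sd Common standard deviation (default 1).
#' @param seed Integer seed.
#' @return Tibble `cell_line`, `msi_status`, `mmr_mutated`,
#'   `tp53_lof`, `sensitivity`.
#' @export
simulate_sensitivity_panel <- function(n_group_a = 12L, n_group_b = 18L,
                                       mean_a = -2, mean_b = -0.5, sd = 1,
                                       seed = 1L) {
  if (n_group_a < 2L || n_group_b < 2L) abort("Each group needs n >= 2.")
  stopifnot_scalar_number(sd, "sd", lower = 1e-12)
  with_seed(seed, {
    tibble::tibble(
      cell_line = c(sprintf("DEF_%02d", seq_len(n_group_a)),
                    sprintf("PRO_%02d", seq_len(n_group_b))),
      msi_status = rep(c("MSI", "MSS"), c(n_group_a, n_group_b)),
      mmr_mutated = rep(c(TRUE, FALSE), c(n_group_a, n_group_b)),
      tp53_lof = sample(c(TRUE, FALSE), n_group_a + n_group_b, replace = TRUE),
      sensitivity = c(rnorm(n_group_a, mean_a, sd),
                      rnorm(n_group_b, mean_b, sd))
    )
  })
}
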