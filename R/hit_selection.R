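#' Hit-calling configuration
#'
#' Thresholds and switches for the candidate-selection cascade.
#'
#' @param cs_cut Absolute CRISPR-score threshold separating
#'   depleted/enriched from static (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param use_adjusted_p Test `p_adj` rather than raw `p`
#'   (default `TRUE`).
#' @param min_pipelines Pipelines a gene must be a trend hit in
#'   (default 2).
#' @param expression_threshold Minimum expression for a gene to be
#'   considered (default 1, in the expression table's units).
#' @param quartile_filter Apply the quartile-separation filter
#'   (default `TRUE`).
#' @param static_requires_significance If `TRUE`, "static" additionally
#'   requires p < alpha, reading the class thresholds fully literally;
#'   the default `FALSE` treats static as "no large change"
#'   (|CS| <= cs_cut with no p condition), matching the screens'
#'   selection intent of "enriched or not significantly changed" in
#'   the wild type. See the methods vignette.
#' @param pseudocount,n_perm Passed through to scoring.
#' @return A `hit_call_config` list.
#' @export
hit_call_config <- function(cs_cut = 0.5, alpha = 0.05,
                            use_adjusted_p = TRUE, min_pipelines = 2L,
                            expression_threshold = 1,
                            quartile_filter = TRUE,
                            static_requires_significance = FALSE,
                            pseudocount = 0.5, n_perm = 1000L) {
  stopifnot_scalar_number(cs_cut, "cs_cut", lower = 1e-12)
  stopifnot_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (min_pipelines < 1L) abort("`min_pipelines` must be >= 1.")
  structure(
    list(cs_cut = cs_cut, alpha = alpha, use_adjusted_p = use_adjusted_p,
         min_pipelines = as.integer(min_pipelines),
         expression_threshold = expression_threshold,
         quartile_filter = quartile_filter,
         static_requires_significance = static_requires_significance,
         pseudocount = pseudocount, n_perm = as.integer(n_perm)),
    class = "hit_call_config"
  )
}

#' Classify genes as depleted, enriched, static or unclassified
#'
#' Applies the class thresholds: depleted = CS < -cs_cut and
#' p < alpha; enriched = CS > cs_cut and p < alpha; static =
#' |CS| <= cs_cut (plus p < alpha when
#' `static_requires_significance`); everything else is unclassified.
#'
#' @param cs,p Numeric vectors (recycled to common length).
#' @param config A [hit_call_config()]; `p` should already be the
#'   adjusted or raw value the caller wants tested.
#' @return Character vector of classes.
#' @examples
#' classify_gene(c(-0.6, 0.6, 0.2), c(0.01, 0.01, 0.01), hit_call_config())
#' @export
classify_gene <- function(cs, p, config = hit_call_config()) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  sig <- p < config$alpha
  dplyr::case_when(
    cs < -config$cs_cut & sig ~ "depleted",
    cs > config$cs_cut & sig ~ "enriched",
    abs(cs) <= config$cs_cut &
      (sig | !config$static_requires_significance) ~ "static",
    TRUE ~ "unclassified"
  )
}

#' Keep genes expressed above a threshold
#'
#' Screens can only report on genes the cell line expresses: a guide
#' against a silent gene is phenotypically inert, so unexpressed genes
#' are removed before hit calling. Genes missing from the expression
#' table are treated as unexpressed, with a warning.
#'
#' @param genes Character vector of gene symbols.
#' @param expression Tibble with columns `gene` and `expression`.
#' @param threshold Minimum expression (same units as the table).
#' @return The retained subset of `genes`.
#' @export
expression_filter <- function(genes, expression, threshold = 1) {
  missing <- setdiff(genes, expression$gene)
  if (length(missing)) {
    warn(paste0(length(missing),
                " gene(s) absent from the expression table treated as unexpressed."))
  }
  expressed <- expression$gene[expression$expression >= threshold]
  genes[genes %in% expressed]
}

#' Select genes following one of the three synthetic-lethality trends
#'
#' A gene is a candidate when it is depleted in the MUT_star
#' comparison (mutant final vs wild-type final) and shows one of:
#' trend 1, static in MUT and enriched in WT; trend 2, depleted in MUT
#' and enriched in WT; trend 3, depleted in MUT and static in WT.
#' All three demand mutant-specific dropout while excluding generally
#' essential genes (depleted in WT too).
#'
#' @param classes Tibble with columns `gene`, `comparison`, `class`
#'   covering all of WT, MUT, MUT_star for each gene.
#' @return Tibble `gene`, `trend` (1, 2, 3 or `NA`), `hit` (logical).
#' @export
select_trend_hits <- function(classes) {
  wide <- classes %>%
    dplyr::select("gene", "comparison", "class") %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "class")
  need <- c("WT", "MUT", "MUT_star")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    abort(paste0("Missing comparison(s): ", toString(miss)))
  }
  if (anyNA(wide[need])) {
    abort("Every gene needs a class in all three comparisons.")
  }
  wide %>%
    dplyr::mutate(
      trend = dplyr::case_when(
        .data$MUT_star != "depleted" ~ NA_integer_,
        .data$MUT == "static" & .data$WT == "enriched" ~ 1L,
        .data$MUT == "depleted" & .data$WT == "enriched" ~ 2L,
        .data$MUT == "depleted" & .data$WT == "static" ~ 3L,
        TRUE ~ NA_integer_
      ),
      hit = !is.na(.data$trend)
    ) %>%
    dplyr::select("gene", "trend", "hit")
}

#' Merge per-pipeline hits into a consensus set
#'
#' @param pipeline_hits Tibble with columns `gene`, `pipeline`, `hit`
#'   (and optionally `trend`).
#' @param min_pipelines Minimum number of pipelines flagging the gene.
#' @return Tibble `gene`, `n_pipelines`, `pipelines`, `trend` (modal
#'   trend over flagging pipelines, smallest on ties), `consensus`.
#' @export
consensus_merge <- function(pipeline_hits, min_pipelines = 2L) {
  if (!any(pipeline_hits$hit)) {
    return(tibble::tibble(gene = character(), n_pipelines = integer(),
                          pipelines = character(), trend = integer(),
                          consensus = logical()))
  }
  pipeline_hits %>%
    dplyr::filter(.data$hit) %>%
    dplyr::group_by(gene = .data$gene) %>%
    dplyr::summarise(
      n_pipelines = dplyr::n_distinct(.data$pipeline),
      pipelines = paste(sort(unique(.data$pipeline)), collapse = ","),
      trend = if ("trend" %in% names(pipeline_hits)) {
        # modal trend; which.max takes the smallest trend on ties
        as.integer(names(which.max(table(.data$trend))))
      } else NA_integer_,
      .groups = "drop"
    ) %>%
    dplyr::mutate(consensus = .data$n_pipelines >= min_pipelines)
}

#' Quartile-separation filter on per-guide Z-scores
#'
#' The final robustness check: a gene passes when the third quartile
#' of its guides' Z-scores in the mutant-final samples lies strictly
#' below the first quartile in both the wild-type baseline and
#' wild-type final samples, i.e. the bulk of the guide distribution
#' separates, not just the mean. Quartiles use linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param zscores Z-score tibble from [sgrna_zscores()] on
#'   fraction-normalized counts.
#' @param samples Sample sheet tibble.
#' @param genes Genes to evaluate.
#' @param library Library tibble.
#' @return Tibble `gene`, `q3_mut_final`, `q1_wt_baseline`,
#'   `q1_wt_final`, `pass`, `reason`.
#' @export
quartile_separation_filter <- function(zscores, samples, genes, library) {
  z <- counts_to_matrix(zscores)
  pick <- function(bg, d) {
    intersect(samples$sample_id[samples$background == bg & samples$day == d],
              colnames(z))
  }
  wt_days <- samples$day[samples$background == "WT"]
  mut_days <- samples$day[samples$background == "MUT"]
  grp <- list(
    mut_final = pick("MUT", max(mut_days)),
    wt_baseline = pick("WT", min(wt_days)),
    wt_final = pick("WT", max(wt_days))
  )
  purrr::map_dfr(genes, function(g) {
    ids <- intersect(library$sgrna_id[!is.na(library$target_gene) &
                                        library$target_gene == g],
                     rownames(z))
    vals <- purrr::map(grp, function(cols) as.vector(z[ids, cols]))
    if (any(lengths(vals) < 2L)) {
      return(tibble::tibble(gene = g, q3_mut_final = NA_real_,
                            q1_wt_baseline = NA_real_, q1_wt_final = NA_real_,
                            pass = FALSE, reason = "fewer than 2 observations in a group"))
    }
    q3m <- unname(quantile(vals$mut_final, 0.75, type = 7))
    q1b <- unname(quantile(vals$wt_baseline, 0.25, type = 7))
    q1f <- unname(quantile(vals$wt_final, 0.25, type = 7))
    tibble::tibble(gene = g, q3_mut_final = q3m, q1_wt_baseline = q1b,
                   q1_wt_final = q1f, pass = q3m < q1b && q3m < q1f,
                   reason = NA_character_)
  })
}

#' Full synthetic-lethality hit-calling cascade
#'
#' Runs, in order: expression filter, three-pipeline scoring
#' ([score_screen()]), class assignment, three-trend selection per
#' pipeline, multi-pipeline consensus, and the quartile-separation
#' filter on consensus survivors.
#'
#' @param counts,samples,library,expression Screen inputs (see
#'   [simulate_screen_counts()] for the shapes).
#' @param config A [hit_call_config()].
#' @param pipelines Pipelines to run.
#' @param seed Seed for the permutation pipeline.
#' @return An `sl_hits` object: a list with `scores`, `classes`,
#'   `trends`, `consensus`, `quartile`, `candidates` tibbles plus the
#'   `config`. `tidy()` returns the candidate table; `glance()` one
#'   row of stage counts.
#' @export
call_hits <- function(counts, samples, library, expression,
                      config = hit_call_config(),
                      pipelines = c("A", "B", "C"), seed = 1L) {
  expressed <- expression_filter(
    unique(stats::na.omit(library$target_gene)),
    expression, config$expression_threshold
  )
  scores <- score_screen(counts, samples, library,
                         pipelines = pipelines,
                         pseudocount = config$pseudocount,
                         n_perm = config$n_perm, seed = seed)
  classes <- scores %>%
    dplyr::filter(.data$gene %in% expressed) %>%
    dplyr::mutate(
      class = classify_gene(.data$cs,
                            if (config$use_adjusted_p) .data$p_adj else .data$p,
                            config)
    )
  trends <- classes %>%
    dplyr::group_by(pipeline = .data$pipeline) %>%
    dplyr::group_modify(~ select_trend_hits(.x)) %>%
    dplyr::ungroup()
  consensus <- consensus_merge(trends, config$min_pipelines)
  consensus_genes <- consensus$gene[consensus$consensus]

  if (config$quartile_filter && length(consensus_genes)) {
    zs <- sgrna_zscores(normalize_counts(counts, "fraction"))
    quart <- quartile_separation_filter(zs, samples, sort(consensus_genes),
                                        library)
  } else {
    quart <- tibble::tibble(gene = character(), q3_mut_final = numeric(),
                            q1_wt_baseline = numeric(), q1_wt_final = numeric(),
                            pass = logical(), reason = character())
  }

  mutstar <- classes %>%
    dplyr::filter(.data$comparison == "MUT_star") %>%
    dplyr::group_by(gene = .data$gene) %>%
    dplyr::summarise(cs_MUT_star = mean(.data$cs),
                     p_adj_MUT_star = median(.data$p_adj), .groups = "drop")

  candidates <- consensus %>%
    dplyr::filter(.data$consensus) %>%
    dplyr::left_join(mutstar, by = "gene") %>%
    dplyr::left_join(dplyr::select(quart, "gene", quartile_pass = "pass"),
                     by = "gene")
  if (config$quartile_filter) {
    candidates <- dplyr::mutate(
      candidates, quartile_pass = dplyr::coalesce(.data$quartile_pass, FALSE)
    )
    final <- dplyr::filter(candidates, .data$quartile_pass)
  } else {
    final <- candidates
  }

  structure(
    list(scores = scores, classes = classes, trends = trends,
         consensus = consensus, quartile = quart,
         pre_quartile_candidates = candidates, candidates = final,
         expressed_genes = expressed, config = config),
    class = "sl_hits"
  )
}

#' @export
tidy.sl_hits <- function(x, ...) x$candidates

#' @export
glance.sl_hits <- function(x, ...) {
  tibble::tibble(
    n_genes_scored = dplyr::n_distinct(x$scores$gene),
    n_expressed = length(x$expressed_genes),
    n_consensus = sum(x$consensus$consensus),
    n_quartile_pass = sum(x$quartile$pass),
    n_candidates = nrow(x$candidates)
  )
}

#' @export
print.sl_hits <- function(x, ...) {
  cat("Synthetic-lethality hit call\n")
  g <- glance(x)
  cat(sprintf("  genes scored: %d | expressed: %d | consensus: %d | final candidates: %d\n",
              g$n_genes_scored, g$n_expressed, g$n_consensus, g$n_candidates))
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}
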