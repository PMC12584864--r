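# ggplot2 helpers for each result type

#' Volcano plot of gene-level screen scores
#'
#' @param scores Long score tibble from [score_screen()].
#' @param comparison,pipeline Which stratum to plot.
#' @param config A [hit_call_config()] supplying the class thresholds.
#' @return A ggplot.
#' @export
plot_volcano <- function(scores, comparison = "MUT_star", pipeline = "A",
                         config = hit_call_config()) {
  dat <- scores %>%
    dplyr::filter(.data$comparison == !!comparison,
                  .data$pipeline == !!pipeline) %>%
    dplyr::mutate(class = classify_gene(
      .data$cs, if (config$use_adjusted_p) .data$p_adj else .data$p, config
    ))
  ggplot2::ggplot(dat, ggplot2::aes(.data$cs, -log10(.data$p_adj),
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-config$cs_cut, config$cs_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "CRISPR score (log2)", y = "-log10 adjusted p",
                  title = paste0(comparison, ", pipeline ", pipeline)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sl_hits <- function(object, comparison = "MUT_star",
                             pipeline = "A", ...) {
  plot_volcano(object$scores, comparison, pipeline, object$config)
}

#' Mean LoF-allele trajectories by group
#'
#' @param trajectories Output of [normalize_trajectories()].
#' @return A ggplot of group mean fold-change (with standard-error
#'   ribbons) against day.
#' @export
plot_trajectories <- function(trajectories) {
  summ <- trajectories %>%
    dplyr::group_by(group = .data$group, day = .data$day) %>%
    dplyr::summarise(mean_fc = mean(.data$fold_change),
                     sem = sd(.data$fold_change) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$day, .data$mean_fc,
                                     colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fc - .data$sem,
                                      ymax = .data$mean_fc + .data$sem,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "day", y = "fold-change vs first timepoint") +
    ggplot2::theme_minimal()
}

#' Competition-assay time courses
#'
#' @param series Output of [normalize_competition()].
#' @return A ggplot of normalized knockout fractions over time.
#' @export
plot_competition <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$day, .data$fraction_norm,
                                       colour = .data$condition,
                                       group = interaction(.data$condition,
                                                           .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "day", y = "KO fraction (fold of day 0)") +
    ggplot2::theme_minimal()
}

#' Sensitivity distributions by MMR group
#'
#' @param records Output of [group_ccls_by_mmr()].
#' @return A ggplot boxplot of sensitivity by group (excluded lines
#'   dropped).
#' @export
plot_sensitivity <- function(records) {
  dat <- dplyr::filter(records, .data$group != "excluded")
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$sensitivity,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "log2 viability ratio (treated / control)") +
    ggplot2::theme_minimal()
}
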