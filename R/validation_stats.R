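#' Normalize a competition series to its initial timepoint
#'
#' FACS-measured knockout fractions are divided, within each
#' condition/replicate, by that replicate's first-day value, so every
#' series starts at 1 and later values are fold-changes. Replicates
#' with a zero initial fraction are dropped with a warning.
#'
#' @param series Tibble `day`, `replicate`, `condition`,
#'   `fraction_ko`.
#' @return The series with a `fraction_norm` column.
#' @examples
#' s <- tibble::tibble(day = c(0, 3, 6), replicate = 1,
#'                     condition = "control",
#'                     fraction_ko = c(0.5, 0.6, 0.75))
#' normalize_competition(s)
#' @export
normalize_competition <- function(series) {
  first <- series %>%
    dplyr::group_by(condition = .data$condition,
                    replicate = .data$replicate) %>%
    dplyr::summarise(day0 = min(.data$day),
                     f0 = .data$fraction_ko[which.min(.data$day)],
                     .groups = "drop")
  zero <- dplyr::filter(first, .data$f0 == 0)
  if (nrow(zero)) {
    warn(paste0("Replicate(s) with zero initial fraction excluded: ",
                paste(zero$condition, zero$replicate, sep = "/",
                      collapse = ", ")))
  }
  series %>%
    dplyr::inner_join(dplyr::filter(first, .data$f0 > 0),
                      by = c("condition", "replicate")) %>%
    dplyr::mutate(fraction_norm = .data$fraction_ko / .data$f0) %>%
    dplyr::select(-"day0", -"f0")
}

#' Per-timepoint one-sided competition test
#'
#' One-sided two-sample t-test of treated versus control normalized
#' knockout fractions at each timepoint (alternative: treated below
#' control, i.e. the treatment suppresses the knockout population).
#' Timepoints may be grouped into day windows when replicate days
#' differ between experiments.
#'
#' @param series Output of [normalize_competition()] with conditions
#'   `"control"` and `"treated"`.
#' @param direction Alternative for the treated group (default
#'   `"less"`).
#' @param windows Optional list of `c(lo, hi)` day ranges defining
#'   timepoint windows; default: each distinct day is its own window,
#'   excluding the baseline day when testing `fraction_norm` (the
#'   normalization pins every series to 1 there, so no test exists).
#' @param value Column to test (default `"fraction_norm"`).
#' @return Tibble `window`, `day_lo`, `day_hi`, `n_control`,
#'   `n_treated`, `mean_control`, `mean_treated`, `statistic`,
#'   `p_value`.
#' @export
competition_test <- function(series, direction = c("less", "greater"),
                             windows = NULL, value = "fraction_norm") {
  direction <- match.arg(direction)
  if (!value %in% names(series)) {
    abort(paste0("Column `", value, "` not found; run normalize_competition()?"))
  }
  if (is.null(windows)) {
    days <- sort(unique(series$day))
    if (value == "fraction_norm" && length(days) > 1L) {
      days <- days[days != min(days)]
    }
    windows <- lapply(days, function(d) c(d, d))
  }
  purrr::imap_dfr(windows, function(wd, i) {
    at <- dplyr::filter(series, .data$day >= wd[1], .data$day <= wd[2])
    ctl <- at[[value]][at$condition == "control"]
    trt <- at[[value]][at$condition == "treated"]
    if (length(ctl) < 2L || length(trt) < 2L) {
      abort(sprintf("Window [%g, %g] needs >= 2 values per arm.",
                    wd[1], wd[2]))
    }
    tt <- tryCatch(
      t.test(trt, ctl, alternative = direction),
      error = function(e) abort(paste0("Degenerate competition test: ",
                                       conditionMessage(e)))
    )
    tibble::tibble(
      window = i, day_lo = wd[1], day_hi = wd[2],
      n_control = length(ctl), n_treated = length(trt),
      mean_control = mean(ctl), mean_treated = mean(trt),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

#' Group cell lines by mismatch-repair status
#'
#' MMR-deficient: microsatellite-instable (MSI) and mutated in an MMR
#' gene. MMR-proficient: microsatellite-stable (MSS) and not mutated
#' in any MMR gene. Everything else (discordant or missing
#' annotations) is excluded, so the two groups are cleanly separated.
#'
#' @param records Tibble with columns `cell_line`, `msi_status`
#'   (`"MSI"`/`"MSS"`), `mmr_mutated` (logical) and `sensitivity`.
#' @return The records with a `group` column
#'   (`"deficient"`/`"proficient"`/`"excluded"`).
#' @export
group_ccls_by_mmr <- function(records) {
  missing <- is.na(records$msi_status) | is.na(records$mmr_mutated)
  if (any(missing)) {
    warn(paste0(sum(missing), " record(s) with missing annotation excluded."))
  }
  records %>%
    dplyr::mutate(
      group = dplyr::case_when(
        is.na(.data$msi_status) | is.na(.data$mmr_mutated) ~ "excluded",
        .data$msi_status == "MSI" & .data$mmr_mutated ~ "deficient",
        .data$msi_status == "MSS" & !.data$mmr_mutated ~ "proficient",
        TRUE ~ "excluded"
      )
    )
}

#' Kolmogorov-Smirnov comparison of sensitivity distributions
#'
#' Two-sample two-sided KS test on drug-sensitivity values of two
#' cell-line groups; the statistic D is the maximum gap between the
#' empirical distribution functions. The exact small-sample p-value is
#' used when both groups have at most 25 lines, the asymptotic one
#' otherwise.
#'
#' @param group_a,group_b Numeric sensitivity vectors (>= 2 values
#'   each).
#' @return One-row tibble `statistic` (D), `p_value`, `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_sensitivity <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs >= 2 values.")
  }
  exact <- length(group_a) <= 25L && length(group_b) <= 25L
  kt <- suppressWarnings(ks.test(group_a, group_b, exact = exact))
  tibble::tibble(
    statistic = unname(kt$statistic), p_value = kt$p.value,
    median_a = median(group_a), median_b = median(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
}
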