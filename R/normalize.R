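#' Normalize a guide-by-sample count matrix
#'
#' Four per-sample normalizations used by the scoring pipelines:
#' \describe{
#'   \item{`fraction`}{count / sample total (the quantity behind the
#'     per-guide Z-scores).}
#'   \item{`rpm`}{fraction scaled to reads per million.}
#'   \item{`median_ratio`}{DESeq-style size factors: each sample is
#'     divided by the median, over guides with no zero counts, of the
#'     ratio of its count to the guide's geometric mean across
#'     samples.}
#'   \item{`control_scaled`}{count divided by the sample's total of
#'     non-targeting-control counts, so neutral controls define the
#'     scale.}
#' }
#'
#' @param counts Count tibble (`sgrna_id` + one column per sample).
#' @param method One of `"fraction"`, `"rpm"`, `"median_ratio"`,
#'   `"control_scaled"`.
#' @param library Library tibble; required for `control_scaled`.
#' @return A tibble of the same shape with real-valued abundances.
#' @examples
#' counts <- tibble::tibble(sgrna_id = c("a", "b", "c"),
#'                          s1 = c(10, 30, 60))
#' normalize_counts(counts, "fraction")
#' @export
normalize_counts <- function(counts, method = c("fraction", "rpm", "median_ratio",
                                                "control_scaled"),
                             library = NULL) {
  method <- match.arg(method)
  m <- counts_to_matrix(counts)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Empty count matrix.")
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("All-zero sample column(s): ",
                 toString(colnames(m)[tot == 0])))
  }
  scale_factors <- switch(
    method,
    fraction = tot,
    rpm = tot / 1e6,
    median_ratio = {
      pos <- rowSums(m == 0) == 0L
      if (!any(pos)) abort("median_ratio needs >= 1 guide with no zero counts.")
      ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
      apply(m[pos, , drop = FALSE] / ref, 2L, median)
    },
    control_scaled = {
      if (is.null(library)) abort("control_scaled requires `library`.")
      nt <- library$sgrna_id[library$category == "non_targeting"]
      nt <- intersect(nt, rownames(m))
      if (length(nt) == 0L) {
        abort("control_scaled requires >= 1 non_targeting guide in the matrix.")
      }
      nt_tot <- colSums(m[nt, , drop = FALSE])
      if (any(nt_tot == 0)) {
        abort(paste0("Zero non-targeting counts in sample(s): ",
                     toString(colnames(m)[nt_tot == 0])))
      }
      nt_tot
    }
  )
  matrix_to_tbl(sweep(m, 2L, scale_factors, "/"))
}

#' Per-guide Z-scores across samples
#'
#' Standardizes each guide's normalized abundance across all samples
#' (mean 0, sd 1 with the n-1 denominator). This is the per-sgRNA
#' quantity plotted when comparing guide distributions between
#' backgrounds and the input to the quartile-separation filter.
#' Zero-variance guides get Z = 0 and are listed in the
#' `"zero_variance"` attribute.
#'
#' @param normalized Normalized abundance tibble (`sgrna_id` + samples).
#' @return A tibble of the same shape with Z-scores.
#' @export
sgrna_zscores <- function(normalized) {
  m <- counts_to_matrix(normalized)
  if (ncol(m) < 2L) abort("Z-scores need >= 2 samples.")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / s
  flat <- s == 0
  z[flat, ] <- 0
  out <- matrix_to_tbl(z)
  attr(out, "zero_variance") <- rownames(m)[flat]
  out
}
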