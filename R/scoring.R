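#' Screen comparison specifications
#'
#' A comparison names a numerator ("condition 1") and denominator
#' ("condition 2") set of samples. The canonical trio for a paired
#' wild-type/mutant dropout screen is built by [auto_comparisons()]:
#' \describe{
#'   \item{WT}{wild-type final day vs wild-type baseline day.}
#'   \item{MUT}{mutant final day vs wild-type baseline day.}
#'   \item{MUT_star}{mutant final day vs wild-type final day.}
#' }
#' The wild-type baseline serves both backgrounds: right after
#' selection the mutant and wild-type pools carry the same library
#' representation, so one baseline anchors all three contrasts.
#'
#' @param name Comparison name.
#' @param numerator,denominator Character vectors of sample ids.
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(name, numerator, denominator) {
  if (length(numerator) == 0L || length(denominator) == 0L) {
    abort("Both comparison sides need >= 1 sample.")
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator),
            class = "comparison_spec")
}

#' @param samples Sample sheet tibble (`sample_id`, `background`,
#'   `day`, `replicate`).
#' @rdname comparison_spec
#' @export
auto_comparisons <- function(samples) {
  pick <- function(bg, d) {
    samples$sample_id[samples$background == bg & samples$day == d]
  }
  need <- function(bg) {
    if (!bg %in% samples$background) {
      abort(paste0("Sample sheet has no ", bg, " samples."))
    }
  }
  need("WT"); need("MUT")
  wt_days <- samples$day[samples$background == "WT"]
  mut_days <- samples$day[samples$background == "MUT"]
  wt1 <- pick("WT", min(wt_days))
  wtF <- pick("WT", max(wt_days))
  mutF <- pick("MUT", max(mut_days))
  list(
    WT = comparison_spec("WT", wtF, wt1),
    MUT = comparison_spec("MUT", mutF, wt1),
    MUT_star = comparison_spec("MUT_star", mutF, wtF)
  )
}

#' Gene-level CRISPR scores
#'
#' For each guide, abundances are averaged over the replicate samples
#' of each comparison side, a pseudocount is added to both sides, and
#' the log2 ratio (condition 1 / condition 2) is taken. The CRISPR
#' score (CS) of a gene is the unweighted mean of its guides'
#' log-ratios; negative CS means dropout in condition 1. The guide
#' level log-ratios are retained for the significance tests.
#'
#' The pseudocount is interpreted on the reads-per-million scale and
#' rescaled to the table's own scale (`pseudocount * mean column sum /
#' 1e6`), so 0.5 always means half a read per million regardless of
#' which normalization produced the abundances.
#'
#' @param normalized Normalized abundance tibble.
#' @param comparison A [comparison_spec()].
#' @param library Library tibble mapping guides to genes.
#' @param pseudocount Pseudocount in RPM units (default 0.5).
#' @return A list of class `crispr_scores` with `genes` (tibble `gene`,
#'   `cs`, `n_sgrnas`), `sgrnas` (tibble `sgrna_id`, `gene`,
#'   `category`, `logratio`) and `comparison`.
#' @export
gene_crispr_score <- function(normalized, comparison, library,
                              pseudocount = 0.5) {
  stopifnot_scalar_number(pseudocount, "pseudocount", lower = 1e-12)
  m <- counts_to_matrix(normalized)
  miss <- setdiff(c(comparison$numerator, comparison$denominator), colnames(m))
  if (length(miss)) {
    abort(paste0("Comparison samples absent from the table: ", toString(miss)))
  }
  ps <- pseudocount * mean(colSums(m)) / 1e6
  num <- rowMeans(m[, comparison$numerator, drop = FALSE])
  den <- rowMeans(m[, comparison$denominator, drop = FALSE])
  lr <- log2((num + ps) / (den + ps))

  lib <- library[match(rownames(m), library$sgrna_id), ]
  sgr <- tibble::tibble(
    sgrna_id = rownames(m),
    gene = lib$target_gene,
    category = lib$category,
    logratio = unname(lr)
  )
  lost <- setdiff(unique(stats::na.omit(library$target_gene)),
                  unique(stats::na.omit(sgr$gene)))
  if (length(lost)) {
    warn(paste0("Gene(s) with no guides in the matrix omitted: ",
                toString(utils::head(lost, 5))))
  }
  genes <- sgr %>%
    dplyr::filter(!is.na(.data$gene)) %>%
    dplyr::group_by(gene = .data$gene) %>%
    dplyr::summarise(cs = mean(.data$logratio), n_sgrnas = dplyr::n(),
                     .groups = "drop")
  structure(list(genes = genes, sgrnas = sgr, comparison = comparison$name),
            class = "crispr_scores")
}

#' @export
tidy.crispr_scores <- function(x, ...) x$genes

#' Per-gene significance of guide log-ratios
#'
#' Three complementary nulls for "this gene's guides moved":
#' \describe{
#'   \item{A}{one-sample two-sided t-test of the gene's guide
#'     log-ratios against 0 (parametric; needs >= 2 guides/gene).}
#'   \item{B}{two-sided Wilcoxon rank-sum of the gene's guide
#'     log-ratios against the non-targeting-control log-ratios
#'     (rank-based; needs non-targeting guides).}
#'   \item{C}{permutation: for each gene, `n_perm` random guide sets of
#'     the same size are drawn from all guides, the null CS is their
#'     mean log-ratio, and `p = (1 + #\{|CS_null| >= |CS_obs|\}) /
#'     (1 + n_perm)`.}
#' }
#' Permutation draws are made over genes in sorted-name order from a
#' guide pool sorted by id, so results do not depend on the row order
#' of the inputs.
#'
#' @param sgrna_logratios The `sgrnas` tibble of a [gene_crispr_score()]
#'   result.
#' @param pipeline_id `"A"`, `"B"` or `"C"`.
#' @param n_perm Permutations for pipeline C (>= 100).
#' @param seed Seed for pipeline C.
#' @param p_floor p-value reported for degenerate zero-variance t-tests
#'   (default 1e-12).
#' @return Tibble `gene`, `p`, `flag` (`NA` or a QC note).
#' @export
significance_test <- function(sgrna_logratios, pipeline_id = c("A", "B", "C"),
                              n_perm = 1000L, seed = 1L, p_floor = 1e-12) {
  pipeline_id <- match.arg(pipeline_id)
  sgr <- dplyr::arrange(sgrna_logratios, .data$sgrna_id)
  gene_tbl <- dplyr::filter(sgr, !is.na(.data$gene))
  genes <- sort(unique(gene_tbl$gene))

  if (pipeline_id == "A") {
    res <- gene_tbl %>%
      dplyr::group_by(gene = .data$gene) %>%
      dplyr::summarise(n = dplyr::n(), m = mean(.data$logratio),
                       s = sd(.data$logratio), .groups = "drop")
    if (any(res$n < 2L)) {
      abort("Pipeline A needs >= 2 guides per gene.")
    }
    tstat <- res$m / (res$s / sqrt(res$n))
    p <- 2 * pt(-abs(tstat), df = res$n - 1L)
    flag <- ifelse(res$s == 0, "zero_variance", NA_character_)
    p[res$s == 0] <- p_floor
    return(tibble::tibble(gene = res$gene, p = p, flag = flag))
  }

  if (pipeline_id == "B") {
    ctrl <- sgr$logratio[sgr$category == "non_targeting"]
    if (length(ctrl) == 0L) {
      abort("Pipeline B needs non-targeting guides.")
    }
    split_lr <- split(gene_tbl$logratio, gene_tbl$gene)
    p <- vapply(split_lr, function(x) {
      suppressWarnings(wilcox.test(x, ctrl)$p.value)
    }, numeric(1))
    return(tibble::tibble(gene = names(p), p = unname(p),
                          flag = NA_character_))
  }

  # pipeline C
  if (n_perm < 100L) abort("Pipeline C needs n_perm >= 100.")
  pool <- sgr$logratio
  obs <- gene_tbl %>%
    dplyr::group_by(gene = .data$gene) %>%
    dplyr::summarise(cs = mean(.data$logratio), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(.data$gene)
  p <- with_seed(seed, {
    out <- numeric(nrow(obs))
    for (s in sort(unique(obs$n))) {
      rows <- which(obs$n == s)
      idx <- sample_index_sets(length(pool), s, n_perm * length(rows))
      null_cs <- abs(rowMeans(matrix(pool[idx], nrow = nrow(idx))))
      null_cs <- matrix(null_cs, nrow = n_perm)
      exceed <- colSums(null_cs >= rep(abs(obs$cs[rows]), each = n_perm))
      out[rows] <- (1 + exceed) / (1 + n_perm)
    }
    out
  })
  tibble::tibble(gene = obs$gene, p = p, flag = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper
#' around [stats::p.adjust()] applied per comparison per pipeline by
#' [score_screen()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

pipeline_normalization <- c(A = "rpm", B = "median_ratio", C = "control_scaled")

#' Score a screen with the three pipelines
#'
#' Runs, for every requested pipeline and comparison: normalization
#' (pipeline A = rpm, B = median ratio, C = control scaled), CRISPR
#' scores, the pipeline's significance test, and Benjamini-Hochberg
#' adjustment within each (pipeline, comparison) stratum.
#'
#' @param counts Count tibble (`sgrna_id` + samples).
#' @param samples Sample sheet tibble.
#' @param library Library tibble.
#' @param comparisons `"auto"` (the WT / MUT / MUT_star trio derived
#'   from the sample sheet) or a named list of [comparison_spec()]s.
#' @param pipelines Subset of `c("A", "B", "C")`.
#' @param pseudocount,n_perm,seed Passed to the scoring stages.
#' @return A long tibble `gene`, `comparison`, `pipeline`, `cs`, `p`,
#'   `p_adj`, `n_sgrnas`, with the per-guide log-ratio tables in the
#'   `"sgrna_logratios"` attribute (a tibble with `pipeline` and
#'   `comparison` columns) for downstream filters.
#' @export
score_screen <- function(counts, samples, library, comparisons = "auto",
                         pipelines = c("A", "B", "C"), pseudocount = 0.5,
                         n_perm = 1000L, seed = 1L) {
  validate_sgrna_library(library)
  if (identical(comparisons, "auto")) comparisons <- auto_comparisons(samples)
  pipelines <- match.arg(pipelines, several.ok = TRUE)

  rows <- list()
  detail <- list()
  for (pl in pipelines) {
    norm <- normalize_counts(counts, pipeline_normalization[[pl]], library)
    for (cmp in comparisons) {
      cs <- gene_crispr_score(norm, cmp, library, pseudocount)
      sig <- significance_test(cs$sgrnas, pl, n_perm = n_perm, seed = seed)
      scored <- cs$genes %>%
        dplyr::left_join(sig, by = "gene") %>%
        dplyr::mutate(
          p_adj = adjust_pvalues(.data$p),
          comparison = cmp$name, pipeline = pl
        )
      rows[[paste(pl, cmp$name)]] <- scored
      detail[[paste(pl, cmp$name)]] <- dplyr::mutate(
        cs$sgrnas, pipeline = pl, comparison = cmp$name
      )
    }
  }
  out <- dplyr::bind_rows(rows) %>%
    dplyr::select("gene", "comparison", "pipeline", "cs", "p", "p_adj",
                  "n_sgrnas", "flag")
  attr(out, "sgrna_logratios") <- dplyr::bind_rows(detail)
  out
}
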