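#' Per-gene fitness effect table
#'
#' Ground-truth fitness effects used by [simulate_screen_counts()]. Each
#' gene carries a per-day log-fitness in the wild-type (`s_wt`) and in
#' the mutant (`s_mut`) background, and a class label:
#' `neutral` (s_wt = s_mut = 0), `essential` (both negative),
#' `sl_mutant_only` (synthetic-lethal: negative in the mutant only) and
#' `wt_advantage` (positive in the wild type).
#'
#' @param genes Character vector of all gene symbols in the library.
#' @param sl_genes,essential_genes,wt_advantage_genes Disjoint subsets
#'   of `genes` receiving non-neutral effects.
#' @param s_sl Per-day log-fitness of SL genes in the mutant (default
#'   -0.2/day; their wild-type fitness is 0).
#' @param s_essential Per-day log-fitness of essential genes in both
#'   backgrounds (default -0.25/day).
#' @param s_wt_advantage Per-day wild-type log-fitness of
#'   `wt_advantage_genes` (default +0.1/day; mutant fitness 0).
#' @return A tibble with columns `gene`, `class_label`, `s_wt`, `s_mut`.
#' @export
gene_effect_table <- function(genes,
                              sl_genes = character(),
                              essential_genes = character(),
                              wt_advantage_genes = character(),
                              s_sl = -0.2,
                              s_essential = -0.25,
                              s_wt_advantage = 0.1) {
  special <- c(sl_genes, essential_genes, wt_advantage_genes)
  if (anyDuplicated(special)) {
    abort("A gene may belong to at most one effect class.")
  }
  if (!all(special %in% genes)) {
    abort(paste0("Effect genes absent from `genes`: ",
                 toString(utils::head(setdiff(special, genes), 5))))
  }
  eff <- tibble::tibble(
    gene = genes, class_label = "neutral", s_wt = 0, s_mut = 0
  )
  eff$class_label[eff$gene %in% sl_genes] <- "sl_mutant_only"
  eff$s_mut[eff$gene %in% sl_genes] <- s_sl
  eff$class_label[eff$gene %in% essential_genes] <- "essential"
  eff$s_wt[eff$gene %in% essential_genes] <- s_essential
  eff$s_mut[eff$gene %in% essential_genes] <- s_essential
  eff$class_label[eff$gene %in% wt_advantage_genes] <- "wt_advantage"
  eff$s_wt[eff$gene %in% wt_advantage_genes] <- s_wt_advantage
  eff
}

#' Configuration for the pooled-screen count simulator
#'
#' Captures the screening design: a library, per-gene fitness effects,
#' which backgrounds are screened, sampling days per background
#' (baseline first; mutant screens typically run a few days longer than
#' wild type), replicates, sequencing depth, and the noise model
#' (negative-binomial dispersion, per-guide efficiency, log-normal
#' spread of initial abundances).
#'
#' @param library An sgRNA library tibble.
#' @param effects A [gene_effect_table()] covering every target gene in
#'   `library`.
#' @param backgrounds Subset of `c("WT", "MUT")`.
#' @param days Named list of strictly increasing day vectors, one per
#'   background; the first day of each is the baseline. A plain numeric
#'   vector is recycled to all backgrounds.
#' @param replicates Replicate samples per background/day (default 2).
#' @param depth Expected total reads per sample (default 500 reads per
#'   guide).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param sgrna_efficiency_range Interval in (0, 1] from which per-guide
#'   efficiencies are drawn uniformly (default (0.7, 1)).
#' @param lib_sigma Log-normal sd of initial guide abundances
#'   (default 0.5).
#' @param unexpressed_genes Genes reported as unexpressed in the
#'   emitted expression table.
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(library, effects,
                              backgrounds = c("WT", "MUT"),
                              days = list(WT = c(1, 9, 14, 18, 21),
                                          MUT = c(1, 9, 14, 18, 27)),
                              replicates = 2L,
                              depth = NULL,
                              dispersion = 10,
                              sgrna_efficiency_range = c(0.7, 1),
                              lib_sigma = 0.5,
                              unexpressed_genes = character(),
                              seed = 1L) {
  validate_sgrna_library(library)
  if (!all(backgrounds %in% c("WT", "MUT"))) {
    abort("`backgrounds` must be a subset of c(\"WT\", \"MUT\").")
  }
  if (is.numeric(days)) {
    days <- stats::setNames(rep(list(days), length(backgrounds)), backgrounds)
  }
  if (!all(backgrounds %in% names(days))) {
    abort("`days` must name every requested background.")
  }
  for (b in backgrounds) {
    if (length(days[[b]]) < 2L || any(diff(days[[b]]) <= 0)) {
      abort("Each background needs >= 2 strictly increasing days.")
    }
  }
  s_cols <- paste0("s_", tolower(backgrounds))
  miss_cols <- setdiff(c("gene", s_cols), names(effects))
  if (length(miss_cols)) {
    abort(paste0("`effects` is missing column(s): ", toString(miss_cols)))
  }
  target_genes <- unique(stats::na.omit(library$target_gene))
  missing_eff <- setdiff(target_genes, effects$gene)
  if (length(missing_eff)) {
    abort(paste0("`effects` is missing gene(s): ",
                 toString(utils::head(missing_eff, 5))))
  }
  depth <- depth %||% (500 * nrow(library))
  stopifnot_scalar_number(depth, "depth", lower = 1)
  stopifnot_scalar_number(dispersion, "dispersion", lower = 1e-8)
  stopifnot_scalar_number(lib_sigma, "lib_sigma", lower = 0)
  if (length(sgrna_efficiency_range) != 2L ||
      sgrna_efficiency_range[1] <= 0 || sgrna_efficiency_range[2] > 1 ||
      diff(sgrna_efficiency_range) < 0) {
    abort("`sgrna_efficiency_range` must be an interval within (0, 1].")
  }
  structure(
    list(
      library = library, effects = effects, backgrounds = backgrounds,
      days = days[backgrounds], replicates = as.integer(replicates),
      depth = depth, dispersion = dispersion,
      sgrna_efficiency_range = sgrna_efficiency_range,
      lib_sigma = lib_sigma, unexpressed_genes = unexpressed_genes,
      seed = as.integer(seed)
    ),
    class = "screen_sim_config"
  )
}

#' Simulate a pooled CRISPR dropout screen time course
#'
#' Draws a guide-by-sample count matrix under an exponential-growth
#' model: the expected read fraction of guide i targeting gene g in
#' background b at day t is proportional to
#' `a_i * exp(u_i * s_{g,b} * t)`, with `a_i` log-normal initial
#' abundances, `u_i` uniform per-guide efficiencies and `s_{g,b}` the
#' configured per-day log-fitness (0 for non-targeting guides). Counts
#' are negative-binomial with mean `fraction * depth` and the
#' configured dispersion, so the noise has the over-dispersion typical
#' of pooled-screen sequencing.
#'
#' @param config A [screen_sim_config()].
#' @return A list with elements `counts` (tibble: `sgrna_id` plus one
#'   column per sample), `samples` (sample sheet: `sample_id`,
#'   `background`, `day`, `replicate`), `expression` (per-gene
#'   expression table; 10 for expressed genes, 0 for the configured
#'   unexpressed subset) and `truth` (the effect table).
#' @examples
#' lib <- build_custom_library(paste0("G", 1:10), sgrnas_per_gene = 4,
#'                             n_nontargeting = 5)
#' eff <- gene_effect_table(paste0("G", 1:10), sl_genes = "G1")
#' sim <- simulate_screen_counts(screen_sim_config(lib, eff, seed = 7))
#' sim$samples
#' @export
simulate_screen_counts <- function(config) {
  if (!inherits(config, "screen_sim_config")) {
    abort("`config` must come from screen_sim_config().")
  }
  lib <- config$library
  eff <- config$effects
  s_of <- function(background) {
    col <- if (background == "WT") "s_wt" else "s_mut"
    s_map <- stats::setNames(eff[[col]], eff$gene)
    s <- rep(0, nrow(lib))
    tg <- !is.na(lib$target_gene)
    s[tg] <- s_map[lib$target_gene[tg]]
    if (anyNA(s)) abort(paste0("No effects defined for background ", background))
    s
  }

  samples <- purrr::map_dfr(config$backgrounds, function(b) {
    tibble::tibble(background = b, day = config$days[[b]])
  }) %>%
    tidyr::expand_grid(replicate = seq_len(config$replicates)) %>%
    dplyr::mutate(
      sample_id = sprintf("%s_d%d_r%d", .data$background, .data$day, .data$replicate)
    ) %>%
    dplyr::select("sample_id", "background", "day", "replicate")

  counts <- with_seed(config$seed, {
    a <- rlnorm(nrow(lib), 0, config$lib_sigma)
    u <- runif(nrow(lib), config$sgrna_efficiency_range[1],
               config$sgrna_efficiency_range[2])
    m <- matrix(0, nrow(lib), nrow(samples),
                dimnames = list(lib$sgrna_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      s <- s_of(samples$background[j])
      w <- a * exp(u * s * samples$day[j])
      mu <- config$depth * w / sum(w)
      m[, j] <- rnbinom(nrow(lib), mu = mu, size = config$dispersion)
    }
    m
  })

  genes <- unique(stats::na.omit(lib$target_gene))
  expression <- tibble::tibble(
    gene = genes,
    expression = ifelse(genes %in% config$unexpressed_genes, 0, 10)
  )

  list(
    counts = matrix_to_tbl(counts),
    samples = samples,
    expression = expression,
    truth = eff
  )
}
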