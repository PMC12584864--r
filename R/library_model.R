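#' sgRNA library tables
#'
#' An sgRNA library is a tibble with one row per guide and the columns
#' `sgrna_id` (unique), `spacer` (20-mer over A/C/G/T), `target_gene`
#' (gene symbol, `NA` for non-targeting guides), `category` (one of
#' `"gene_targeting"`, `"control_gene"`, `"non_targeting"`) and a
#' free-text `label`. `validate_sgrna_library()` checks the invariants
#' and returns the table invisibly.
#'
#' @param library A library tibble.
#' @return `library`, invisibly, after validation.
#' @export
validate_sgrna_library <- function(library) {
  req <- c("sgrna_id", "spacer", "target_gene", "category")
  missing_cols <- setdiff(req, names(library))
  if (length(missing_cols)) {
    abort(paste0("Library is missing column(s): ", toString(missing_cols)))
  }
  if (anyDuplicated(library$sgrna_id)) {
    dup <- unique(library$sgrna_id[duplicated(library$sgrna_id)])
    abort(paste0("Duplicate sgrna_id: ", toString(utils::head(dup, 5))))
  }
  bad_spacer <- !grepl("^[ACGT]{20}$", library$spacer)
  if (any(bad_spacer)) {
    abort(paste0(
      "Spacer must be a 20-mer over {A,C,G,T}; offending row(s): ",
      toString(utils::head(which(bad_spacer), 5))
    ))
  }
  ok_cat <- c("gene_targeting", "control_gene", "non_targeting")
  if (!all(library$category %in% ok_cat)) {
    abort(paste0("category must be one of ", toString(ok_cat)))
  }
  gene_empty <- is.na(library$target_gene) | library$target_gene == ""
  if (any(library$category == "non_targeting" & !gene_empty)) {
    abort("non_targeting guides must have an empty target_gene.")
  }
  if (any(library$category != "non_targeting" & gene_empty)) {
    abort("gene_targeting/control_gene guides must name a target_gene.")
  }
  invisible(library)
}

#' Build a custom focused sgRNA library
#'
#' Constructs a focused knockout library in the style used for screen
#' validation: a set of candidate ("hit") genes plus positive/negative
#' control genes, each targeted by a fixed number of guides, completed
#' by non-targeting guides. Spacer sequences are seeded random unique
#' 20-mers; downstream scoring never uses sequence content.
#'
#' @param hit_genes Character vector of candidate gene symbols.
#' @param control_genes Character vector of control gene symbols
#'   (disjoint from `hit_genes`).
#' @param sgrnas_per_gene Guides per gene (default 8).
#' @param n_nontargeting Number of non-targeting guides (default 0).
#' @param seed Integer seed for spacer generation.
#' @return A validated sgRNA library tibble with
#'   `(length(hit_genes) + length(control_genes)) * sgrnas_per_gene`
#'   gene-targeting rows plus `n_nontargeting` non-targeting rows.
#' @examples
#' lib <- build_custom_library(paste0("G", 1:3), "CTRL1",
#'                             sgrnas_per_gene = 2, n_nontargeting = 4)
#' dplyr::count(lib, category)
#' @export
build_custom_library <- function(hit_genes, control_genes = character(),
                                 sgrnas_per_gene = 8L, n_nontargeting = 0L,
                                 seed = 1L) {
  if (sgrnas_per_gene < 1L) abort("`sgrnas_per_gene` must be >= 1.")
  if (n_nontargeting < 0L) abort("`n_nontargeting` must be >= 0.")
  dup <- intersect(hit_genes, control_genes)
  if (length(dup)) {
    abort(paste0("Gene(s) in both hit and control lists: ", toString(dup)))
  }
  if (anyDuplicated(c(hit_genes, control_genes))) {
    dup2 <- unique(c(hit_genes, control_genes)[duplicated(c(hit_genes, control_genes))])
    abort(paste0("Duplicated gene symbol(s): ", toString(dup2)))
  }

  genes <- c(hit_genes, control_genes)
  categories <- rep(c("gene_targeting", "control_gene"),
                    times = c(length(hit_genes), length(control_genes)))
  gene_rows <- tibble::tibble(
    target_gene = rep(genes, each = sgrnas_per_gene),
    category = rep(categories, each = sgrnas_per_gene),
    sgrna_id = paste0(target_gene, "_sg", rep(seq_len(sgrnas_per_gene), length(genes)))
  )
  nt_rows <- tibble::tibble(
    target_gene = rep(NA_character_, n_nontargeting),
    category = rep("non_targeting", n_nontargeting),
    sgrna_id = if (n_nontargeting > 0) paste0("NT_", seq_len(n_nontargeting)) else character()
  )
  lib <- dplyr::bind_rows(gene_rows, nt_rows)
  lib$spacer <- with_seed(seed, random_spacers(nrow(lib)))
  lib$label <- NA_character_
  lib <- dplyr::select(lib, "sgrna_id", "spacer", "target_gene", "category", "label")
  validate_sgrna_library(lib)
  lib
}

#' Fold coverage of a library by a cell population
#'
#' Coverage is the mean number of cells carrying each guide,
#' `n_cells / number of guides`; pooled screens aim for a few hundred
#' to a few thousand fold so that stochastic dropout does not mimic
#' selection.
#'
#' @param n_cells Number of cells (or reads).
#' @param library An sgRNA library tibble.
#' @return A single number, the fold coverage.
#' @examples
#' lib <- build_custom_library(paste0("G", 1:5), sgrnas_per_gene = 4)
#' coverage(70000, lib)
#' @export
coverage <- function(n_cells, library) {
  stopifnot_scalar_number(n_cells, "n_cells", lower = 1)
  if (nrow(library) == 0L) abort("Cannot compute coverage of an empty library.")
  n_cells / nrow(library)
}

#' Read and write sgRNA library TSV files
#'
#' The on-disk dialect is a UTF-8 TSV with header
#' `sgrna_id  spacer  target_gene  category  label`; `target_gene` is
#' empty for non-targeting guides. `write_library()` followed by
#' `read_library()` is the identity on records.
#'
#' @param path File path.
#' @return `read_library()` returns a validated library tibble.
#' @export
read_library <- function(path) {
  lib <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      sgrna_id = readr::col_character(),
      spacer = readr::col_character(),
      target_gene = readr::col_character(),
      category = readr::col_character(),
      label = readr::col_character()
    ),
    progress = FALSE
  ))
  if (nrow(lib) == 0L) {
    warn(paste0("Library file is empty: ", path))
    lib <- tibble::tibble(
      sgrna_id = character(), spacer = character(),
      target_gene = character(), category = character(), label = character()
    )
    return(lib)
  }
  tryCatch(
    validate_sgrna_library(lib),
    error = function(e) {
      abort(paste0("Invalid library file ", path, ": ", conditionMessage(e)))
    }
  )
  lib
}

#' @param library A library tibble (validated before writing).
#' @rdname read_library
#' @export
write_library <- function(library, path) {
  validate_sgrna_library(library)
  readr::write_tsv(library, path, na = "")
  invisible(path)
}
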