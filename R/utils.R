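# internal helpers shared across modules

# counts tables are tibbles with an sgrna_id column followed by sample
# columns; most numerics happen on the matrix form
counts_to_matrix <- function(counts) {
  if (!"sgrna_id" %in% names(counts)) {
    abort("`counts` must have an `sgrna_id` first column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "sgrna_id")])
  rownames(m) <- counts$sgrna_id
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sgrna_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# seeded evaluation that never clobbers the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# n random sgRNA index sets of size s from 1..pool_n, distinct within a set;
# drawn with replacement then repaired, which is fast for s << pool_n
sample_index_sets <- function(pool_n, s, n) {
  has_dup <- function(m) {
    bad <- rep(FALSE, nrow(m))
    for (i in seq_len(ncol(m) - 1L)) {
      for (j in seq.int(i + 1L, ncol(m))) {
        bad <- bad | (m[, i] == m[, j])
      }
    }
    bad
  }
  idx <- matrix(sample.int(pool_n, n * s, replace = TRUE), nrow = n, ncol = s)
  if (s > 1L) {
    repeat {
      bad <- which(has_dup(idx))
      if (length(bad) == 0L) break
      idx[bad, ] <- matrix(sample.int(pool_n, length(bad) * s, replace = TRUE),
                           nrow = length(bad))
    }
  }
  idx
}

random_spacers <- function(n, width = 20L) {
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1))
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}
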