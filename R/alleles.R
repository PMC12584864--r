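# Allele descriptors are compact strings relative to the Cas9 cut site
# (position 0; negative = PAM-distal side): "WT", or ";"-joined events
#   D:<start>:<length>   deletion of <length> bp starting at <start>
#   I:<start>:<seq>      insertion of <seq> at <start>
#   S:<start>:<seq>      substitution of <seq> starting at <start>
# Substitutions change sequence but not length, so they never shift the
# reading frame; an allele with only substitutions is classed WT.

parse_events <- function(descriptor) {
  if (descriptor == "WT") {
    return(tibble::tibble(kind = character(), start = integer(),
                          length = integer(), seq = character()))
  }
  tokens <- strsplit(descriptor, ";", fixed = TRUE)[[1]]
  rows <- lapply(tokens, function(tok) {
    if (grepl("^D:-?[0-9]+:[0-9]+$", tok)) {
      f <- strsplit(tok, ":", fixed = TRUE)[[1]]
      len <- as.integer(f[3])
      if (len < 1L) abort(paste0("Deletion length must be >= 1: ", tok))
      tibble::tibble(kind = "deletion", start = as.integer(f[2]),
                     length = len, seq = NA_character_)
    } else if (grepl("^I:-?[0-9]+:[ACGT]+$", tok)) {
      f <- strsplit(tok, ":", fixed = TRUE)[[1]]
      tibble::tibble(kind = "insertion", start = as.integer(f[2]),
                     length = nchar(f[3]), seq = f[3])
    } else if (grepl("^S:-?[0-9]+:[ACGT]+$", tok)) {
      f <- strsplit(tok, ":", fixed = TRUE)[[1]]
      tibble::tibble(kind = "substitution", start = as.integer(f[2]),
                     length = nchar(f[3]), seq = f[3])
    } else {
      abort(paste0("Malformed allele token: \"", tok, "\""))
    }
  })
  dplyr::bind_rows(rows)
}

#' Parse and format allele descriptors
#'
#' `parse_descriptor()` turns a descriptor string into its event table,
#' net length change and frame class; `format_descriptor()` inverts it.
#'
#' @param descriptor A descriptor string (see Details in
#'   [classify_alleles()]).
#' @return `parse_descriptor()`: a list with `events` (tibble `kind`,
#'   `start`, `length`, `seq`), `net_length`, `class`.
#' @examples
#' parse_descriptor("D:-2:3")
#' parse_descriptor("I:0:AT")$class
#' @export
parse_descriptor <- function(descriptor) {
  ev <- parse_events(descriptor)
  net <- net_length_of(ev)
  list(events = ev, net_length = net, class = class_of(ev))
}

#' @param events An event tibble as returned in
#'   `parse_descriptor()$events`.
#' @rdname parse_descriptor
#' @export
format_descriptor <- function(events) {
  if (nrow(events) == 0L) return("WT")
  tok <- ifelse(
    events$kind == "deletion",
    sprintf("D:%d:%d", events$start, events$length),
    sprintf("%s:%d:%s", ifelse(events$kind == "insertion", "I", "S"),
            events$start, events$seq)
  )
  paste(tok, collapse = ";")
}

net_length_of <- function(events) {
  sum(ifelse(events$kind == "insertion", events$length,
             ifelse(events$kind == "deletion", -events$length, 0L)))
}

class_of <- function(events) {
  indel <- events$kind %in% c("insertion", "deletion")
  if (!any(indel)) return("WT")
  if (net_length_of(events) %% 3L != 0L) "FS" else "NFS"
}

location_of <- function(events) {
  if (nrow(events) == 0L) abort("An unedited allele has no location.")
  pos <- unlist(lapply(seq_len(nrow(events)), function(i) {
    if (events$kind[i] == "insertion") events$start[i]
    else seq.int(events$start[i], events$start[i] + events$length[i] - 1L)
  }))
  # nearest affected position to the cut site; ties go to the negative side
  pos[order(abs(pos), pos)][1]
}

#' Classify alleles as frameshift, in-frame or wild type
#'
#' The frame class is pure indel arithmetic: no indel events means WT;
#' a net length change (insertions minus deletions) not divisible by 3
#' means frameshift (FS), loss of function in a haploid cell; a net
#' change divisible by 3 (including 0) with at least one indel is
#' non-frameshift (NFS). Nonsense substitutions would also be LoF but
#' cannot be derived from indel arithmetic and are classed WT; see the
#' methods vignette.
#'
#' @param alleles Character vector of descriptor strings.
#' @return Character vector of `"FS"`, `"NFS"`, `"WT"`.
#' @examples
#' classify_alleles(c("D:0:1", "D:0:3", "I:0:AT;D:4:2", "WT"))
#' @export
classify_alleles <- function(alleles) {
  u <- unique(alleles)
  toks <- strsplit(u, ";", fixed = TRUE)
  tok <- unlist(toks)
  idx <- rep(seq_along(u), lengths(toks))
  ok <- tok == "WT" |
    grepl("^D:-?[0-9]+:[1-9][0-9]*$", tok) |
    grepl("^[IS]:-?[0-9]+:[ACGT]+$", tok)
  if (any(!ok)) {
    abort(paste0("Malformed allele token: \"", tok[!ok][1], "\""))
  }
  kind <- substr(tok, 1L, 1L)
  if (any(kind == "W" & lengths(toks)[idx] > 1L)) {
    abort("\"WT\" cannot be combined with other events.")
  }
  field3 <- sub("^[DIS]:-?[0-9]+:", "", tok)
  signed <- ifelse(kind == "D", -as.integer(ifelse(kind == "D", field3, "0")),
                   ifelse(kind == "I", nchar(field3), 0L))
  net <- as.vector(rowsum(signed, idx))
  n_indel <- as.vector(rowsum(as.integer(kind %in% c("D", "I")), idx))
  cls <- ifelse(n_indel == 0L, "WT", ifelse(net %% 3L != 0L, "FS", "NFS"))
  cls[match(alleles, u)]
}

#' Allele location relative to the cut site
#'
#' Positions are referenced to the PAM, with 0 the Cas9 cut site. A
#' deletion affects `start ... start+length-1`; an insertion the single
#' position `start`. The allele's location is the affected position of
#' minimal absolute value (nearest the cut site), ties broken toward
#' the negative side; multi-event alleles take the nearest position
#' over all events.
#'
#' @param alleles Character vector of descriptor strings (no `"WT"`).
#' @return Integer vector of locations.
#' @examples
#' allele_location(c("D:-1:3", "D:4:3", "I:-3:A"))
#' @export
allele_location <- function(alleles) {
  u <- unique(alleles)
  if (any(u == "WT")) abort("An unedited allele has no location.")
  toks <- strsplit(u, ";", fixed = TRUE)
  tok <- unlist(toks)
  idx <- rep(seq_along(u), lengths(toks))
  ok <- grepl("^D:-?[0-9]+:[1-9][0-9]*$", tok) |
    grepl("^[IS]:-?[0-9]+:[ACGT]+$", tok)
  if (any(!ok)) {
    abort(paste0("Malformed allele token: \"", tok[!ok][1], "\""))
  }
  kind <- substr(tok, 1L, 1L)
  start <- as.integer(sub("^[DIS]:(-?[0-9]+):.*$", "\\1", tok))
  field3 <- sub("^[DIS]:-?[0-9]+:", "", tok)
  span <- ifelse(kind == "I", 1L,
                 ifelse(kind == "D", as.integer(ifelse(kind == "D", field3, "1")),
                        nchar(field3)))
  end <- start + span - 1L
  # a contiguous affected range is either one side of the cut or spans it
  ev_loc <- ifelse(start <= 0L & end >= 0L, 0L, ifelse(start > 0L, start, end))
  loc <- vapply(split(ev_loc, idx), function(p) p[order(abs(p), p)][1],
                numeric(1))
  as.integer(loc)[match(alleles, u)]
}

#' Read an allele count table
#'
#' TSV with columns `allele` (descriptor string), `sample_id`, `count`.
#' Every descriptor is parsed on read, so malformed rows fail loudly.
#'
#' @param path File path.
#' @return Long tibble `allele`, `sample_id`, `count`.
#' @export
parse_allele_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    allele = readr::col_character(),
    sample_id = readr::col_character(),
    count = readr::col_double()
  ), progress = FALSE)
  if (any(tbl$count < 0)) abort("Allele counts must be >= 0.")
  if (anyDuplicated(tbl[c("allele", "sample_id")])) {
    abort("Duplicate (allele, sample_id) rows.")
  }
  invisible(lapply(unique(tbl$allele), parse_events))
  tbl
}

#' Per-sample relative allele frequencies
#'
#' @param table Long allele count tibble (`allele`, `sample_id`,
#'   `count`).
#' @return The table with a `frequency` column (count over the
#'   sample's total); frequencies sum to one within each sample.
#' @export
allele_frequencies <- function(table) {
  tot <- rowsum(table$count, table$sample_id)
  if (any(tot[, 1] == 0)) {
    abort(paste0("Zero-total sample(s): ",
                 toString(rownames(tot)[tot[, 1] == 0])))
  }
  dplyr::mutate(table,
                frequency = .data$count /
                  unname(tot[match(.data$sample_id, rownames(tot)), 1]))
}

#' Cut-site clustering quality control
#'
#' Fraction of mutation observations lying within `window` bp of the
#' cut site: genuine Cas9 editing concentrates at the cut, so a low
#' fraction flags alignment or amplification artefacts. Both the
#' read-weighted fraction and the unweighted allele-level fraction are
#' reported.
#'
#' @param table Long allele count tibble.
#' @param window Half-width in bp (default 5).
#' @return One-row tibble `window`, `frac_reads`, `frac_alleles`,
#'   `n_mutant_alleles`, `n_mutant_reads`.
#' @export
cutsite_clustering_qc <- function(table, window = 5L) {
  if (window < 0L) abort("`window` must be >= 0.")
  per_allele <- table %>%
    dplyr::group_by(allele = .data$allele) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::filter(.data$allele != "WT")
  per_allele <- per_allele[vapply(per_allele$allele, function(a) {
    nrow(parse_events(a)) > 0L
  }, logical(1)), ]
  if (nrow(per_allele) == 0L) {
    inform("No mutant alleles; cut-site clustering undefined.")
    return(tibble::tibble(window = window, frac_reads = NA_real_,
                          frac_alleles = NA_real_, n_mutant_alleles = 0L,
                          n_mutant_reads = 0))
  }
  loc <- allele_location(per_allele$allele)
  near <- abs(loc) <= window
  tibble::tibble(
    window = window,
    frac_reads = sum(per_allele$count[near]) / sum(per_allele$count),
    frac_alleles = mean(near),
    n_mutant_alleles = nrow(per_allele),
    n_mutant_reads = sum(per_allele$count)
  )
}

#' First-timepoint-normalized trajectories of LoF alleles
#'
#' Restricts to frameshift (LoF) alleles present at the first
#' timepoint in both groups, divides each allele's frequency path by
#' its first-timepoint frequency within each replicate, then averages
#' replicates; the first entry of every trajectory is exactly 1 and
#' later entries are fold-changes relative to it. Replicates with a
#' zero first-timepoint frequency are excluded and logged in the
#' `"excluded"` attribute.
#'
#' @param frequencies Output of [allele_frequencies()].
#' @param samples Sample sheet tibble (`sample_id`, `background`,
#'   `day`, `replicate`).
#' @return Tibble `allele`, `group`, `day`, `fold_change`.
#' @export
normalize_trajectories <- function(frequencies, samples) {
  if (dplyr::n_distinct(samples$day) < 2L) abort("Need >= 2 timepoints.")
  sm <- match(frequencies$sample_id, samples$sample_id)
  if (anyNA(sm)) abort("Frequencies reference samples missing from the sheet.")
  bg <- samples$background[sm]
  day <- samples$day[sm]
  rep_ <- samples$replicate[sm]
  keep <- classify_alleles(frequencies$allele) == "FS"

  allele <- frequencies$allele[keep]
  freq <- frequencies$frequency[keep]
  bg <- bg[keep]; day <- day[keep]; rep_ <- rep_[keep]
  tp1 <- min(samples$day)
  groups <- unique(samples$background)

  # alleles with nonzero first-timepoint frequency in every group
  at1 <- day == tp1
  g1 <- rowsum(freq[at1], paste(allele[at1], bg[at1], sep = "\r"))
  key1 <- do.call(rbind, strsplit(rownames(g1), "\r", fixed = TRUE))
  pos_groups <- rowsum(as.integer(g1[, 1] > 0), key1[, 1])
  shared <- rownames(pos_groups)[pos_groups[, 1] == length(groups)]
  in_shared <- allele %in% shared

  allele <- allele[in_shared]; freq <- freq[in_shared]
  bg <- bg[in_shared]; day <- day[in_shared]; rep_ <- rep_[in_shared]
  at1 <- day == tp1

  # per-replicate baseline; replicates with zero baseline are excluded
  repkey <- paste(allele, bg, rep_, sep = "\r")
  f1 <- stats::setNames(freq[at1], repkey[at1])[repkey]
  excluded <- tibble::tibble(
    allele = allele[at1][freq[at1] == 0],
    background = bg[at1][freq[at1] == 0],
    replicate = rep_[at1][freq[at1] == 0]
  )
  use <- !is.na(f1) & f1 > 0
  fc <- freq[use] / f1[use]

  # average replicates after normalization
  outkey <- paste(allele[use], bg[use], day[use], sep = "\r")
  mfc <- rowsum(fc, outkey) / as.vector(table(outkey))  # both sort keys identically
  ks <- do.call(rbind, strsplit(rownames(mfc), "\r", fixed = TRUE))
  traj <- tibble::tibble(
    allele = ks[, 1], group = ks[, 2], day = as.numeric(ks[, 3]),
    fold_change = unname(mfc[, 1])
  ) %>%
    dplyr::arrange(.data$allele, .data$group, .data$day)
  attr(traj, "excluded") <- excluded
  traj
}

#' Most frequent LoF alleles by cumulative frequency
#'
#' @param frequencies Output of [allele_frequencies()].
#' @param k Number of alleles to keep.
#' @return Tibble `allele`, `cumulative_frequency`, `rank`, restricted
#'   to frameshift alleles, ranked by the sum of frequencies over all
#'   samples (ties broken by descriptor string order).
#' @export
top_alleles <- function(frequencies, k = 5L) {
  if (k < 1L) abort("`k` must be >= 1.")
  ranked <- frequencies %>%
    dplyr::mutate(class = classify_alleles(.data$allele)) %>%
    dplyr::filter(.data$class == "FS") %>%
    dplyr::group_by(allele = .data$allele) %>%
    dplyr::summarise(cumulative_frequency = sum(.data$frequency),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$cumulative_frequency), .data$allele) %>%
    dplyr::mutate(rank = dplyr::row_number())
  if (k > nrow(ranked)) {
    warn(sprintf("Only %d LoF allele(s) available (k = %d).", nrow(ranked), k))
    k <- nrow(ranked)
  }
  dplyr::slice_head(ranked, n = k)
}

#' Group trend test on allele fold-changes
#'
#' Two-sided two-sample t-test (Welch by default) comparing per-allele
#' fold-changes at one timepoint between the two groups; under
#' selection against LoF alleles in one background the group means
#' separate on opposite sides of 1. A paired-by-allele variant is
#' available since every allele appears in both groups.
#'
#' @param trajectories Output of [normalize_trajectories()].
#' @param day Timepoint to test (default: the last).
#' @param var_equal Use the pooled-variance (Student) test instead of
#'   Welch.
#' @param paired Pair fold-changes by allele.
#' @return One-row tibble `day`, `mean_wt`, `mean_mut`, `statistic`,
#'   `df`, `p_value`, `method`, `n_wt`, `n_mut`.
#' @export
group_trend_test <- function(trajectories, day = NULL, var_equal = FALSE,
                             paired = FALSE) {
  groups <- sort(unique(trajectories$group))
  if (length(groups) != 2L) abort("Need exactly two groups.")
  wt_name <- if ("WT" %in% groups) "WT" else groups[1]
  mut_name <- setdiff(groups, wt_name)
  day <- day %||% max(trajectories$day)
  at <- dplyr::filter(trajectories, .data$day == !!day)
  if (paired) at <- dplyr::arrange(at, .data$allele)
  x <- at$fold_change[at$group == wt_name]
  y <- at$fold_change[at$group == mut_name]
  if (length(x) < 2L || length(y) < 2L) {
    abort("Need >= 2 alleles per group at the tested timepoint.")
  }
  tt <- tryCatch(
    t.test(x, y, var.equal = var_equal, paired = paired),
    error = function(e) abort(paste0("Degenerate trend test: ",
                                     conditionMessage(e)))
  )
  tibble::tibble(
    day = day, mean_wt = mean(x), mean_mut = mean(y),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = tt$method,
    n_wt = length(x), n_mut = length(y)
  )
}
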