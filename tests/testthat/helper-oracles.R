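# Independent brute-force oracles. These deliberately share no code with
# the package implementation.

# Benjamini-Hochberg step-up by direct minimisation over ranks
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# median-of-ratios size factors by explicit loops
median_ratio_oracle <- function(m) {
  keep <- apply(m, 1L, function(r) all(r > 0))
  ref <- numeric(nrow(m))
  for (i in which(keep)) ref[i] <- prod(m[i, ])^(1 / ncol(m))
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    sf[j] <- median(m[keep, j] / ref[keep])
  }
  norm <- m
  for (j in seq_len(ncol(m))) norm[, j] <- m[, j] / sf[j]
  norm
}

# type-7 quantile by hand: linear interpolation of order statistics
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# two-sample KS statistic as the max ECDF gap over all pooled points
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gaps <- vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1))
  max(gaps)
}

# ---- frame-class oracle via sequence surgery + translation ------------
# Events are lists with kind/start/length/seq, positions relative to a
# cut site placed mid-CDS; the oracle applies the edits to the actual
# sequence, translates, and compares the downstream peptide tail in
# frame with the unedited translation.

random_cds <- function(n = 300L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_events_to_cds <- function(cds, events, cut = 150L) {
  ord <- order(vapply(events, `[[`, numeric(1), "start"), decreasing = TRUE)
  s <- cds
  for (ev in events[ord]) {
    i <- cut + ev$start  # 1-based index of the first affected base
    if (ev$kind == "deletion") {
      s <- paste0(substr(s, 1, i - 1), substr(s, i + ev$length, nchar(s)))
    } else if (ev$kind == "insertion") {
      s <- paste0(substr(s, 1, i - 1), ev$seq, substr(s, i, nchar(s)))
    } else {
      s <- paste0(substr(s, 1, i - 1), ev$seq,
                  substr(s, i + ev$length, nchar(s)))
    }
  }
  s
}

translate_str <- function(s) {
  s <- substr(s, 1, 3 * (nchar(s) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

frame_class_oracle <- function(cds, events, cut = 150L) {
  if (!length(events)) return("WT")
  kinds <- vapply(events, `[[`, character(1), "kind")
  if (!any(kinds %in% c("insertion", "deletion"))) return("WT")
  edited <- apply_events_to_cds(cds, events, cut)
  tail_aa <- function(pep, k = 8L) substr(pep, nchar(pep) - k + 1L, nchar(pep))
  if (tail_aa(translate_str(cds)) == tail_aa(translate_str(edited))) {
    "NFS"
  } else {
    "FS"
  }
}

# random multi-event alleles on non-overlapping slots around the cut
random_event_list <- function() {
  n_ev <- sample(1:3, 1)
  slots <- sample(seq(-30L, 20L, by = 10L), n_ev)
  lapply(slots, function(sl) {
    kind <- sample(c("deletion", "insertion", "substitution"), 1,
                   prob = c(0.45, 0.45, 0.1))
    len <- sample(1:8, 1)
    list(kind = kind, start = sl + sample(0:1, 1), length = len,
         seq = if (kind == "deletion") NULL else
           paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
  })
}

events_to_descriptor <- function(events) {
  if (!length(events)) return("WT")
  paste(vapply(events, function(ev) {
    switch(ev$kind,
           deletion = sprintf("D:%d:%d", ev$start, ev$length),
           insertion = sprintf("I:%d:%s", ev$start, ev$seq),
           substitution = sprintf("S:%d:%s", ev$start, ev$seq))
  }, character(1)), collapse = ";")
}

# ---- hand-coded truth table for the three-trend predicate -------------
# (MUT_star, MUT, WT) triples that constitute a hit, written out in full
trend_truth <- function(mut_star, mut, wt) {
  hit_triples <- list(
    c("depleted", "static", "enriched"),    # trend 1
    c("depleted", "depleted", "enriched"),  # trend 2
    c("depleted", "depleted", "static")     # trend 3
  )
  for (i in seq_along(hit_triples)) {
    tr <- hit_triples[[i]]
    if (mut_star == tr[1] && mut == tr[2] && wt == tr[3]) return(i)
  }
  NA_integer_
}
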