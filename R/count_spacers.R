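#' Count library spacers in screen amplicon reads
#'
#' Exact-match counting of each 20-nt spacer (and its reverse
#' complement) inside FASTQ reads. Reads matching spacers of more than
#' one guide are discarded and tallied as ambiguous; reads matching
#' none are tallied as unmatched.
#'
#' @param fastq Path(s) to FASTQ file(s); counts are summed across
#'   files.
#' @param library Library tibble.
#' @return A list with `counts` (tibble `sgrna_id`, `count`, in
#'   library order) and `qc` (one-row tibble `n_reads`, `n_matched`,
#'   `n_ambiguous`, `n_unmatched`).
#' @export
count_spacers <- function(fastq, library) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("count_spacers() requires the Biostrings package.")
  }
  validate_sgrna_library(library)
  spacers <- Biostrings::DNAStringSet(library$spacer)
  fwd <- Biostrings::PDict(spacers)
  rev <- Biostrings::PDict(Biostrings::reverseComplement(spacers))

  counts <- stats::setNames(numeric(nrow(library)), library$sgrna_id)
  n_reads <- n_amb <- n_unmatched <- 0L
  for (f in fastq) {
    reads <- tryCatch(
      Biostrings::readDNAStringSet(f, format = "fastq"),
      error = function(e) abort(paste0("Cannot read FASTQ ", f, ": ",
                                       conditionMessage(e)))
    )
    n_reads <- n_reads + length(reads)
    hit_f <- Biostrings::vwhichPDict(fwd, reads)
    hit_r <- Biostrings::vwhichPDict(rev, reads)
    hits <- mapply(function(a, b) unique(c(a, b)), hit_f, hit_r,
                   SIMPLIFY = FALSE)
    n_hits <- lengths(hits)
    n_amb <- n_amb + sum(n_hits > 1L)
    n_unmatched <- n_unmatched + sum(n_hits == 0L)
    uniq <- unlist(hits[n_hits == 1L])
    if (length(uniq)) {
      tab <- table(uniq)
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
        as.numeric(tab)
    }
  }
  list(
    counts = tibble::tibble(sgrna_id = library$sgrna_id,
                            count = unname(counts)),
    qc = tibble::tibble(n_reads = n_reads,
                        n_matched = n_reads - n_amb - n_unmatched,
                        n_ambiguous = n_amb, n_unmatched = n_unmatched)
  )
}
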