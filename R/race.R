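#' Demultiplex 5' RACE read pairs by ligated index
#'
#' Assigns each read pair to a sample by the exact 5-nt index anchored at
#' the very start of read 1 (decapped/treated vs mock/untreated libraries).
#' Matching is exact and anchored, equivalent to anchored-adapter trimming
#' with `--trimmed-only`: pairs whose R1 starts with neither index are
#' discarded. The index is trimmed from the assigned R1.
#'
#' @param read_pairs Tibble with `read_id`, `r1_seq` and optionally
#'   `r2_seq`.
#' @param index_map Named character vector mapping index sequence to sample
#'   label; default `c(GATTA = "treated", ATCAG = "untreated")`.
#' @return The assigned subset of `read_pairs` with columns `sample` and
#'   `r1_seq` (index trimmed).
#' @export
demux_by_index <- function(read_pairs,
                           index_map = c(GATTA = "treated", ATCAG = "untreated")) {
  stopifnot(length(index_map) >= 1, !is.null(names(index_map)))
  idx <- names(index_map)
  hits <- vapply(idx, function(i) startsWith(read_pairs$r1_seq, i),
                 logical(nrow(read_pairs)))
  hits <- matrix(hits, nrow = nrow(read_pairs))
  n_hit <- rowSums(hits)
  if (any(n_hit > 1)) {
    abort("demux_by_index: a read matches more than one index; indexes must be unambiguous")
  }
  assigned <- n_hit == 1
  which_idx <- apply(hits[assigned, , drop = FALSE], 1, which.max)
  out <- read_pairs[assigned, ]
  out$sample <- unname(index_map[which_idx])
  out$r1_seq <- substr(out$r1_seq, nchar(idx[which_idx]) + 1L,
                       nchar(out$r1_seq))
  out
}

#' Validate candidate TSS with demultiplexed RACE alignments
#'
#' For each candidate TSS, counts treated and untreated R1 5' ends mapping
#' within `window` nt of the candidate position (inclusive, two-sided; R2
#' positions are not used) and computes the validation ratio
#' `treated / (treated + untreated)`. A candidate is validated iff the
#' ratio strictly exceeds 0.5 and at least one treated read supports it.
#'
#' @param candidates Tibble `candidate_id`, `chrom`, `strand`, `tss_pos`.
#' @param labeled_alignments Tibble of R1 alignments: `chrom`, `strand`,
#'   `pos` (R1 5' end) and `sample` (`"treated"`/`"untreated"`).
#' @param window Window half-width in nt.
#' @param stranded Count same-strand reads only (default); set `FALSE` to
#'   ignore strand.
#' @return `candidates` with `treated_count`, `untreated_count`, `ratio`
#'   (NA when no reads fall in the window) and `validated` appended.
#' @export
validate_tss <- function(candidates, labeled_alignments, window = 100,
                         stranded = TRUE) {
  counts <- pmap(
    list(candidates$chrom, candidates$strand, candidates$tss_pos),
    function(chrom, strand, tss_pos) {
      sel <- labeled_alignments$chrom == chrom &
        abs(labeled_alignments$pos - tss_pos) <= window
      if (stranded) sel <- sel & labeled_alignments$strand == strand
      tibble(
        treated_count = sum(sel & labeled_alignments$sample == "treated"),
        untreated_count = sum(sel & labeled_alignments$sample == "untreated")
      )
    }
  )
  out <- bind_rows(counts)
  candidates |>
    mutate(
      treated_count = out$treated_count,
      untreated_count = out$untreated_count,
      ratio = if_else(.data$treated_count + .data$untreated_count > 0,
                      .data$treated_count /
                        (.data$treated_count + .data$untreated_count),
                      NA_real_),
      validated = !is.na(.data$ratio) & .data$ratio > 0.5 &
        .data$treated_count >= 1
    )
}
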