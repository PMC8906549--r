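#' Signed distance from read 5' ends to the closest annotated TSS
#'
#' For each aligned read, finds the nearest same-strand annotated TSS on the
#' read's chromosome and reports the signed distance in the annotated
#' strand's frame: negative = the read 5' end lies upstream (5') of the TSS,
#' positive = downstream (3'). Equidistant ties resolve to the first TSS in
#' sorted position order. Reads on chromosomes (or strands) absent from the
#' annotation get `NA` distance and are flagged.
#'
#' @param alignments Primary alignment tibble with `five_prime_pos`.
#' @param annotation Transcript table from [load_gtf_annotation()].
#' @return A tibble `read_id`, `signed_distance`, `closest_tss`
#'   (transcript id), `flagged` (no same-strand TSS available).
#' @export
closest_tss_distance <- function(alignments, annotation) {
  ann <- annotation |>
    arrange(.data$chrom, .data$strand, .data$tss, .data$transcript_id)
  out <- alignments |>
    select("read_id", "chrom", "strand", pos = "five_prime_pos") |>
    mutate(.row = row_number()) |>
    group_by(.data$chrom, .data$strand)
  res <- dplyr::group_map(out, function(g, key) {
    a <- ann[ann$chrom == key$chrom & ann$strand == key$strand, ]
    if (nrow(a) == 0L || all(is.na(g$pos))) {
      return(tibble(
        .row = g$.row, signed_distance = NA_integer_,
        closest_tss = NA_character_, flagged = TRUE
      ))
    }
    tss <- a$tss
    idx <- findInterval(g$pos, tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tss))
    dl <- abs(g$pos - tss[left])
    dr <- abs(g$pos - tss[right])
    # prefer the left (sorted-first) TSS on exact distance ties
    use_left <- idx >= 1L & (idx >= length(tss) | dl <= dr)
    pick <- if_else(use_left, left, right)
    t_pos <- tss[pick]
    signed <- if (key$strand == "+") g$pos - t_pos else t_pos - g$pos
    tibble(
      .row = g$.row,
      signed_distance = as.integer(if_else(is.na(g$pos), NA_integer_, as.integer(signed))),
      closest_tss = if_else(is.na(g$pos), NA_character_, a$transcript_id[pick]),
      flagged = is.na(g$pos)
    )
  })
  bind_rows(res) |>
    arrange(.data$.row) |>
    mutate(read_id = alignments$read_id[.data$.row]) |>
    select("read_id", "signed_distance", "closest_tss", "flagged")
}

#' Fraction of 5' ends within a distance window of annotated TSS
#'
#' Computes the fraction of reads whose absolute TSS distance is at most
#' `window`, together with the full cumulative distance table (counts
#' normalized as a fraction of total reads in the set).
#'
#' @param distances Integer vector of signed TSS distances (`NA` dropped).
#' @param window Window half-width in nt.
#' @return A list: `fraction` (scalar), `cdf` (tibble `distance`,
#'   `cum_count`, `cum_frac` over sorted distances).
#' @export
distance_cdf <- function(distances, window = 300) {
  d <- distances[!is.na(distances)]
  stopifnot(length(d) > 0)
  sorted <- sort(d)
  cdf <- tibble(distance = unique(sorted)) |>
    mutate(
      cum_count = findInterval(.data$distance, sorted),
      cum_frac = .data$cum_count / length(sorted)
    )
  list(fraction = mean(abs(d) <= window), cdf = cdf)
}

#' @keywords internal
#' Single-linkage 1D clustering of positions already sorted ascending:
#' a new cluster starts where the gap to the previous position exceeds
#' `link_dist`.
link_positions <- function(pos, link_dist) {
  if (length(pos) == 0L) return(integer(0))
  stopifnot(!is.unsorted(pos))
  cumsum(c(1L, as.integer(diff(pos) > link_dist)))
}

#' Discover novel TSS clusters among read 5' ends
#'
#' Retains reads whose 5' end lies at least `min_dist` nt from any
#' same-strand annotated TSS (reads with no same-strand TSS on their
#' chromosome count as infinitely far), single-linkage clusters the
#' retained 5' positions per chromosome and strand with a maximum gap of
#' `link_dist`, and reports clusters supported by at least `min_reads`
#' reads. The cluster representative is the 5'-most member position
#' (smallest genomic coordinate on plus, largest on minus strand).
#'
#' @param alignments Primary alignment tibble.
#' @param annotation Transcript table from [load_gtf_annotation()].
#' @param min_dist Minimum absolute distance from annotated TSS (inclusive:
#'   a read exactly `min_dist` away is retained).
#' @param link_dist Maximum gap between neighbouring member 5' ends.
#' @param min_reads Minimum cluster size.
#' @return A tibble: `cluster_id`, `chrom`, `strand`, `representative_pos`,
#'   `size`, `read_ids` (list-column).
#' @export
find_novel_tss <- function(alignments, annotation, min_dist = 300,
                           link_dist = 50, min_reads = 2) {
  dist <- closest_tss_distance(alignments, annotation)
  far <- is.na(dist$signed_distance) | abs(dist$signed_distance) >= min_dist
  cand <- alignments[far & !is.na(alignments$five_prime_pos), ]
  if (nrow(cand) == 0L) {
    return(tibble(
      cluster_id = character(), chrom = character(), strand = character(),
      representative_pos = integer(), size = integer(), read_ids = list()
    ))
  }
  cand |>
    select("read_id", "chrom", "strand", pos = "five_prime_pos") |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(cluster = link_positions(.data$pos, link_dist)) |>
    group_by(.data$chrom, .data$strand, .data$cluster) |>
    summarise(
      representative_pos = if (first(.data$strand) == "+") min(.data$pos) else max(.data$pos),
      size = n(),
      read_ids = list(.data$read_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$size >= min_reads) |>
    arrange(.data$chrom, .data$strand, .data$representative_pos) |>
    mutate(cluster_id = sprintf("novel_tss_%04d", row_number())) |>
    select("cluster_id", "chrom", "strand", "representative_pos", "size", "read_ids")
}

#' Merge 5' end positions into unique ends
#'
#' Single-linkage merge of per-strand 5' positions with a maximum gap of
#' `window` nt; each merged group is represented by its 5'-most member.
#' Used to deduplicate read 5' ends before comparing against orthogonal TSS
#' markers.
#'
#' @param ends Tibble with `chrom`, `strand`, `pos`.
#' @param window Maximum gap between neighbouring merged positions.
#' @return Tibble `chrom`, `strand`, `pos` (representatives), `n_members`.
#' @export
merge_five_prime_ends <- function(ends, window = 25) {
  if (nrow(ends) == 0L) {
    return(tibble(chrom = character(), strand = character(),
                  pos = integer(), n_members = integer()))
  }
  ends |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(cluster = link_positions(.data$pos, window)) |>
    group_by(.data$chrom, .data$strand, .data$cluster) |>
    summarise(
      rep_pos = if (first(.data$strand) == "+") min(.data$pos) else max(.data$pos),
      n_members = n(),
      .groups = "drop"
    ) |>
    rename(pos = "rep_pos") |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    select("chrom", "strand", "pos", "n_members")
}

#' Overlap of unique 5' ends with orthogonal TSS marker intervals
#'
#' Tests each unique 5' end for overlap with marker intervals (CAGE peaks,
#' DNase hypersensitive sites, ChIP-seq peaks, ...) within `slop` nt, and
#' reports the overlapped fraction per marker and for the union of markers.
#'
#' @param unique_ends Tibble `chrom`, `strand`, `pos` (e.g. from
#'   [merge_five_prime_ends()]).
#' @param markers Interval tibble from [load_bed_sites()], optionally with a
#'   `marker` column naming the assay; a single unnamed set is labelled
#'   `"marker"`.
#' @param slop Extra nt allowed on each side of a marker interval.
#' @return A list: `ends` (input with one logical column per marker plus
#'   `any_marker`), `summary` (tibble `marker`, `fraction`; the union row is
#'   labelled `"union"`).
#' @export
marker_overlap <- function(unique_ends, markers, slop = 0) {
  marker_names <- if ("marker" %in% names(markers) && nrow(markers) > 0) {
    unique(markers$marker)
  } else if (nrow(markers) > 0) {
    markers$marker <- "marker"
    "marker"
  } else {
    character(0)
  }
  ends <- unique_ends
  for (m in marker_names) {
    mm <- markers[markers$marker == m, ]
    ends[[m]] <- end_in_intervals(unique_ends, mm, slop)
  }
  flags <- as.matrix(ends[, marker_names, drop = FALSE])
  ends$any_marker <- if (length(marker_names) > 0) rowSums(flags) > 0 else rep(FALSE, nrow(ends))
  summary <- tibble(
    marker = c(marker_names, "union"),
    fraction = unname(c(
      vapply(marker_names, function(m) mean(ends[[m]]), double(1)),
      mean(ends$any_marker)
    ))
  )
  if (nrow(unique_ends) == 0L) summary$fraction <- 0
  list(ends = ends, summary = summary)
}

#' @keywords internal
end_in_intervals <- function(ends, intervals, slop = 0) {
  if (nrow(ends) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(ends)))
  q <- GenomicRanges::GRanges(
    ends$chrom, IRanges::IRanges(ends$pos + 1L, ends$pos + 1L),
    strand = ends$strand
  )
  s <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(pmax(intervals$start + 1L - slop, 1L), intervals$end + slop),
    strand = intervals$strand
  )
  GenomicRanges::countOverlaps(q, s, ignore.strand = FALSE) > 0
}

#' Signal matrix around reference points
#'
#' Builds a deepTools-style reference-point matrix: rows are (merged,
#' optionally down-sampled) 5'-end reference points, columns are offsets
#' from `-flank` to `+flank` in the strand-oriented frame (negative =
#' upstream of the point), and each cell is the interval signal covering
#' that genomic position (0 where no interval applies). Signal intervals
#' are assumed non-overlapping per chromosome, as in a bedGraph track.
#'
#' @param reference_points Tibble `chrom`, `strand`, `pos`.
#' @param signal Tibble `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @param flank Half-width of the window in nt.
#' @param downsample_n Optional maximum number of rows, sampled
#'   deterministically under `seed`; larger than the available rows keeps
#'   everything.
#' @param merge_window Merge reference points within this many nt first
#'   (`0` disables merging).
#' @param seed Seed for the down-sampling draw.
#' @return A numeric matrix with one row per reference point; column names
#'   are signed offsets, row names `chrom:pos:strand`.
#' @export
marker_matrix <- function(reference_points, signal, flank = 1000,
                          downsample_n = NULL, merge_window = 50, seed = 1L) {
  pts <- reference_points
  if (merge_window > 0) pts <- merge_five_prime_ends(pts, window = merge_window)
  if (!is.null(downsample_n) && nrow(pts) > downsample_n) {
    keep <- local_sample(seq_len(nrow(pts)), downsample_n, seed)
    pts <- pts[sort(keep), ]
  }
  offsets <- seq(-flank, flank)
  mat <- matrix(0, nrow = nrow(pts), ncol = length(offsets),
                dimnames = list(
                  sprintf("%s:%d:%s", pts$chrom, pts$pos, pts$strand),
                  offsets
                ))
  if (nrow(pts) == 0L) return(mat)
  sig_by_chrom <- split(signal[order(signal$start), ], signal$chrom[order(signal$start)])
  for (i in seq_len(nrow(pts))) {
    genomic <- if (pts$strand[i] == "+") pts$pos[i] + offsets else pts$pos[i] - offsets
    sig <- sig_by_chrom[[pts$chrom[i]]]
    if (is.null(sig) || nrow(sig) == 0L) next
    idx <- findInterval(genomic, sig$start)
    hit <- idx >= 1L & genomic < sig$end[pmax(idx, 1L)]
    mat[i, hit] <- sig$score[idx[hit]]
  }
  mat
}

#' @keywords internal
#' Seeded sample that leaves the caller's RNG state untouched.
local_sample <- function(x, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample(x, n)
}

#' Write a reference-point matrix as TSV
#'
#' @param mat Matrix from [marker_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- as.data.frame(mat)
  df <- cbind(reference_point = rownames(mat), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
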