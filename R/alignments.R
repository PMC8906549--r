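#' Read spliced alignments into a table
#'
#' Loads SAM or BAM records via `Rsamtools` (SAM text is converted on the
#' fly) into a tibble with the package-wide 0-based half-open coordinates
#' and the strand-aware derived fields used by the filters: the genomic
#' position of the read's 5' and 3' ends and the number of clipped bases at
#' the 5' end.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A tibble with `read_id`, `flag`, `chrom`, `strand`, `ref_start`,
#'   `ref_end` (0-based half-open), `cigar`, `mapq`, `five_prime_clip`,
#'   `five_prime_pos`, `three_prime_pos`. Unmapped records keep `NA`
#'   coordinates.
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tbl <- tibble(
    read_id = as.character(x$qname),
    flag = as.integer(x$flag),
    chrom = as.character(x$rname),
    strand = as.character(x$strand),
    ref_start = as.integer(x$pos) - 1L,
    cigar = as.character(x$cigar),
    mapq = as.integer(x$mapq)
  )
  mapped <- !is.na(tbl$ref_start) & !is.na(tbl$cigar)
  ref_width <- rep(NA_integer_, nrow(tbl))
  ref_width[mapped] <- cigar_reference_width(tbl$cigar[mapped])
  tbl |>
    mutate(ref_end = .data$ref_start + ref_width) |>
    derive_read_ends() |>
    select("read_id", "flag", "chrom", "strand", "ref_start", "ref_end",
           "cigar", "mapq", "five_prime_clip", "five_prime_pos",
           "three_prime_pos")
}

#' @keywords internal
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  lapply(m, function(x) {
    if (nrow(x) == 0L) abort("malformed CIGAR")
    list(len = as.integer(x[, 2]), op = x[, 3])
  })
}

#' @keywords internal
cigar_reference_width <- function(cigar) {
  ops <- parse_cigar(cigar)
  vapply(ops, function(o) sum(o$len[o$op %in% c("M", "D", "N", "=", "X")]),
         integer(1))
}

#' Number of clipped bases at the 5' end of a read
#'
#' Sums soft (S) and hard (H) clip lengths at the strand-appropriate
#' alignment end: leading operations for a plus-strand alignment, trailing
#' for minus strand (where the read's 5' end is the reference-rightmost
#' position).
#'
#' @param cigar Character vector of CIGAR strings.
#' @param strand Character vector, `"+"` or `"-"`, recycled if length 1.
#' @return Integer vector of clipped base counts.
#' @examples
#' five_prime_clip(c("20S80M", "80M20S"), c("+", "-"))
#' @export
five_prime_clip <- function(cigar, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  if (length(strand) == 1L) strand <- rep(strand, length(cigar))
  stopifnot(length(strand) == length(cigar))
  ops <- parse_cigar(cigar)
  ends <- ifelse(strand == "+", "head", "tail")
  vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (any(!o$op %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X"))) {
      abort("malformed CIGAR")
    }
    if (ends[i] == "head") {
      run <- 0L
      for (k in seq_along(o$op)) {
        if (o$op[k] %in% c("S", "H")) run <- run + o$len[k] else break
      }
      run
    } else {
      run <- 0L
      for (k in rev(seq_along(o$op))) {
        if (o$op[k] %in% c("S", "H")) run <- run + o$len[k] else break
      }
      run
    }
  }, integer(1))
}

#' @keywords internal
derive_read_ends <- function(tbl) {
  mapped <- !is.na(tbl$ref_start) & !is.na(tbl$cigar) & tbl$strand %in% c("+", "-")
  fpc <- rep(NA_integer_, nrow(tbl))
  fpp <- rep(NA_integer_, nrow(tbl))
  tpp <- rep(NA_integer_, nrow(tbl))
  if (any(mapped)) {
    fpc[mapped] <- five_prime_clip(tbl$cigar[mapped], tbl$strand[mapped])
    plus <- mapped & tbl$strand == "+"
    minus <- mapped & tbl$strand == "-"
    fpp[plus] <- tbl$ref_start[plus]
    tpp[plus] <- tbl$ref_end[plus] - 1L
    fpp[minus] <- tbl$ref_end[minus] - 1L
    tpp[minus] <- tbl$ref_start[minus]
  }
  mutate(tbl, five_prime_clip = fpc, five_prime_pos = fpp, three_prime_pos = tpp)
}

#' Keep only primary alignments
#'
#' Drops unmapped (flag 0x4), secondary (0x100) and supplementary (0x800)
#' records and keeps at most one record per read id (first occurrence, with
#' a warning if duplicates survive the flag filter).
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @return Filtered alignment tibble, at most one row per read.
#' @export
select_primary <- function(alignments) {
  out <- dplyr::filter(
    alignments,
    bitwAnd(.data$flag, 4L) == 0L,
    bitwAnd(.data$flag, 256L) == 0L,
    bitwAnd(.data$flag, 2048L) == 0L
  )
  n_dup <- sum(duplicated(out$read_id))
  if (n_dup > 0L) {
    warn(sprintf("select_primary: %d duplicate primary record(s), keeping first", n_dup))
  }
  distinct(out, .data$read_id, .keep_all = TRUE)
}

#' Filter alignments on 5' clipped bases
#'
#' Removes alignments whose 5' soft+hard clip reaches `remove_at` bases
#' (default 15, i.e. reads with 14 or fewer 5'-clipped bases are kept).
#'
#' @param alignments Primary alignment tibble.
#' @param remove_at Clip count at or above which an alignment is removed.
#' @return The kept subset.
#' @export
clip_filter <- function(alignments, remove_at = 15L) {
  dplyr::filter(alignments, .data$five_prime_clip < remove_at)
}

#' Cross-check adapter calls against untrimmed and trimmed alignments
#'
#' A detected cap-adapter call is confirmed as a true positive iff the
#' adapter sequence did not itself align to the genome: the *untrimmed*
#' alignment must carry at least `remove_at` clipped bases at the 5' end
#' (the adapter was soft-clipped), and the *trimmed* alignment must pass the
#' 5'-clip filter. Calls whose untrimmed alignment absorbs the adapter into
#' the reference (clip below `remove_at`) are genomic decoys and are
#' removed; detected reads missing from either alignment set are removed
#' and counted.
#'
#' @param adapter_calls Calls tibble from [detect_adapter()].
#' @param untrimmed_alignments,trimmed_alignments Primary alignment tibbles
#'   of the same reads aligned without and with adapter trimming.
#' @param remove_at Clip threshold shared with [clip_filter()].
#' @return A list: `confirmed_ids` (character vector of confirmed
#'   cap-adapted read ids), `n_decoy` (calls rejected because the adapter
#'   matched the genome), `n_missing` (detected reads absent from an
#'   alignment set).
#' @export
true_positive_filter <- function(adapter_calls, untrimmed_alignments,
                                 trimmed_alignments, remove_at = 15L) {
  detected <- dplyr::filter(adapter_calls, .data$detected)
  u <- select(untrimmed_alignments, "read_id", u_clip = "five_prime_clip")
  t <- select(trimmed_alignments, "read_id", t_clip = "five_prime_clip")
  joined <- detected |>
    left_join(u, by = "read_id") |>
    left_join(t, by = "read_id")
  missing <- is.na(joined$u_clip) | is.na(joined$t_clip)
  decoy <- !missing & joined$u_clip < remove_at
  confirmed <- !missing & !decoy & joined$t_clip < remove_at
  list(
    confirmed_ids = joined$read_id[confirmed],
    n_decoy = sum(decoy),
    n_missing = sum(missing)
  )
}
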