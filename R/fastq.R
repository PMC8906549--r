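#' Read a FASTQ file into a read table
#'
#' Parses four-line FASTQ records into a tibble with one row per read.
#' Qualities are decoded as Phred+33 and kept both as the raw quality string
#' (so a write round-trips byte-identically) and as a derived mean read
#' quality. Sequences are taken verbatim: direct-RNA basecalls in the U
#' alphabet are not silently converted (see [u_to_t()]).
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `qualities`
#'   (Phred+33 string) and `mean_q` (error-probability-averaged read quality,
#'   see [mean_read_quality()]).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(
      read_id = character(), sequence = character(),
      qualities = character(), mean_q = double()
    ))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "malformed FASTQ: %d lines is not a multiple of 4 (truncated record near line %d)",
      length(lines), length(lines)
    ))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTQ: expected '@' header at line %d", idx[bad[1L]]))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTQ: expected '+' separator at line %d", idx[bad[1L]] + 2L))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed FASTQ: sequence/quality length mismatch at line %d",
      idx[bad[1L]] + 3L
    ))
  }
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    sequence = seqs,
    qualities = quals,
    mean_q = mean_read_quality(quals)
  )
}

#' Write a read table to FASTQ
#'
#' Inverse of [read_fastq()]: emits four-line records in table order, so
#' `write_fastq(read_fastq(f), g)` reproduces `f` byte-identically for
#' well-formed input.
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "qualities") %in% names(reads)))
  stopifnot(all(nchar(reads$sequence) == nchar(reads$qualities)))
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qualities
  writeLines(out, path)
  invisible(path)
}

#' Convert U to T in basecalled sequences
#'
#' Direct-RNA basecallers emit the U alphabet; genomic references and the
#' cap-adapter barcode are DNA. Replaces U/u with T/t, leaves every other
#' character (including N and case) untouched. Idempotent and
#' length-preserving.
#'
#' @param sequence Character vector of sequences.
#' @return Character vector of the same length, U replaced by T.
#' @examples
#' u_to_t(c("ACGU", "uuAA"))
#' @export
u_to_t <- function(sequence) {
  chartr("Uu", "Tt", sequence)
}

#' Mean read quality from Phred strings or integer vectors
#'
#' Computes the per-read average quality as
#' \eqn{-10 \log_{10}(\overline{p})}, the mean of per-base error
#' probabilities converted back to the Phred scale. This is the ONT/NanoFilt
#' convention under which a read passes a Q >= 7 gate; it weights low-quality
#' bases more heavily than the arithmetic mean of Phred scores, which is
#' available via `method = "arithmetic"`.
#'
#' @param qualities Either a character vector of Phred+33 strings (one per
#'   read) or a list of integer Phred vectors.
#' @param method `"error_prob"` (default) or `"arithmetic"`.
#' @return Numeric vector of mean read qualities.
#' @examples
#' mean_read_quality("IIII") # all Phred 40
#' mean_read_quality(list(c(10L, 20L)))
#' @export
mean_read_quality <- function(qualities, method = c("error_prob", "arithmetic")) {
  method <- match.arg(method)
  if (is.character(qualities)) {
    phred <- lapply(qualities, function(q) utf8ToInt(q) - 33L)
  } else if (is.list(qualities)) {
    phred <- qualities
  } else {
    phred <- list(as.integer(qualities))
  }
  if (any(lengths(phred) == 0L)) {
    abort("mean_read_quality: empty quality vector")
  }
  if (method == "error_prob") {
    vapply(phred, function(q) -10 * log10(mean(10^(-q / 10))), double(1))
  } else {
    vapply(phred, function(q) mean(q), double(1))
  }
}

#' Filter reads by mean quality
#'
#' Pass/fail classification of reads at a mean-quality threshold (default
#' Q >= 7, the standard direct-RNA pass gate).
#'
#' @param reads Read tibble from [read_fastq()].
#' @param min_q Minimum mean read quality to pass.
#' @return The passing subset of `reads`.
#' @export
quality_filter <- function(reads, min_q = 7) {
  dplyr::filter(reads, .data$mean_q >= min_q)
}
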