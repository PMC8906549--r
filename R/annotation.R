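#' Load a GENCODE-style GTF into a transcript annotation table
#'
#' Imports transcript records with `rtracklayer` and derives strand-aware
#' transcription start (TSS) and end (TES) sites: on the plus strand the TSS
#' is the 5'-most genomic coordinate, on the minus strand the 3'-most. All
#' coordinates are converted to the package-wide 0-based convention on read,
#' so a plus-strand transcript with GTF `start=100,end=500` has `tss = 99`,
#' `tes = 499`.
#'
#' @param path Path to a GTF file with `transcript` feature lines carrying
#'   `gene_id` and (optionally) `gene_name` and `gene_type`/`gene_biotype`
#'   attributes.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_name`, `gene_type`, `chrom`, `strand`, `tss`, `tes` (0-based).
#'   Strandless transcripts are skipped; the number skipped is attached as
#'   attribute `n_skipped` (with a warning when nonzero).
#' @export
load_gtf_annotation <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "transcript"]
  md <- S4Vectors::mcols(gr)
  gene_type <- if ("gene_type" %in% names(md)) {
    md$gene_type
  } else if ("gene_biotype" %in% names(md)) {
    md$gene_biotype
  } else {
    rep(NA_character_, length(gr))
  }
  tbl <- tibble(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    gene_name = if ("gene_name" %in% names(md)) as.character(md$gene_name) else NA_character_,
    gene_type = as.character(gene_type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start0 = GenomicRanges::start(gr) - 1L, # GTF 1-based -> internal 0-based
    end0 = GenomicRanges::end(gr) - 1L
  )
  n_skipped <- sum(!tbl$strand %in% c("+", "-"))
  if (n_skipped > 0L) {
    warn(sprintf("load_gtf_annotation: skipped %d strandless transcript(s)", n_skipped))
  }
  out <- tbl |>
    dplyr::filter(.data$strand %in% c("+", "-")) |>
    mutate(
      tss = if_else(.data$strand == "+", .data$start0, .data$end0),
      tes = if_else(.data$strand == "+", .data$end0, .data$start0)
    ) |>
    select("transcript_id", "gene_id", "gene_name", "gene_type",
           "chrom", "strand", "tss", "tes") |>
    arrange(.data$chrom, .data$strand, .data$tss)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Load a BED file of single-base sites or intervals
#'
#' Reads BED3/BED6 with `rtracklayer` into a 0-based half-open interval
#' table. Unstranded records (BED3, or `.` strand) are mirrored onto both
#' strands rather than dropped, because orthogonal marker files such as
#' DNase peaks are unstranded. With `as_sites = TRUE` each interval is
#' collapsed to its representative single-base coordinate (the interval
#' start), the convention used for poly(A) cleavage-site atlases.
#'
#' @param path Path to a BED3+ file.
#' @param as_sites Collapse intervals to single-base site coordinates?
#' @return A tibble with `chrom`, `strand`, `start`, `end` (0-based
#'   half-open) and, when `as_sites = TRUE`, a `pos` column.
#' @export
load_bed_sites <- function(path, as_sites = FALSE) {
  stopifnot(file.exists(path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    out <- tibble(
      chrom = character(), strand = character(),
      start = integer(), end = integer(), score = double()
    )
    if (as_sites) out$pos <- integer()
    return(out)
  }
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to BED 0-based half-open
    end = GenomicRanges::end(gr),
    score = if ("score" %in% names(md)) as.numeric(md$score) else NA_real_
  )
  stranded <- dplyr::filter(tbl, .data$strand %in% c("+", "-"))
  unstranded <- dplyr::filter(tbl, !.data$strand %in% c("+", "-"))
  if (nrow(unstranded) > 0L) {
    unstranded <- bind_rows(
      mutate(unstranded, strand = "+"),
      mutate(unstranded, strand = "-")
    )
  }
  out <- bind_rows(stranded, unstranded) |>
    arrange(.data$chrom, .data$strand, .data$start)
  if (as_sites) out <- mutate(out, pos = .data$start)
  out
}

#' Load a per-read poly(A) tail table
#'
#' Reads a nanopolish-polya-style TSV keyed by read name. A read passes the
#' downstream tail filter iff its `qc_tag` equals the pass label; reads
#' absent from the table carry no tail evidence and fail (closed-world
#' rule).
#'
#' @param path Path to a TSV whose header contains `readname`,
#'   `polya_length` and `qc_tag` columns (extra columns are ignored).
#' @return A tibble `read_id`, `tail_length`, `qc_tag`, first occurrence
#'   kept for duplicated read names (number of duplicates attached as
#'   attribute `n_duplicated`, with a warning when nonzero).
#' @export
load_polya_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("readname", "polya_length", "qc_tag")
  missing_col <- setdiff(required, names(tbl))
  if (length(missing_col) > 0L) {
    abort(sprintf("poly(A) table is missing required column '%s'", missing_col[1]))
  }
  n_dup <- sum(duplicated(tbl$readname))
  if (n_dup > 0L) {
    warn(sprintf("load_polya_table: %d duplicated read name(s), keeping first", n_dup))
  }
  out <- tbl |>
    distinct(.data$readname, .keep_all = TRUE) |>
    transmute(
      read_id = as.character(.data$readname),
      tail_length = as.numeric(.data$polya_length),
      qc_tag = as.character(.data$qc_tag)
    )
  attr(out, "n_duplicated") <- n_dup
  out
}

#' Apply the poly(A) tail evidence filter
#'
#' @param read_ids Character vector of read ids to test.
#' @param polya_table Table from [load_polya_table()].
#' @param pass_tag QC tag counted as positive tail evidence.
#' @return Logical vector: `TRUE` where the read has a table entry whose
#'   `qc_tag` equals `pass_tag`; absent reads are `FALSE`.
#' @export
polya_tail_pass <- function(read_ids, polya_table, pass_tag = "PASS") {
  pass_ids <- polya_table$read_id[polya_table$qc_tag == pass_tag]
  read_ids %in% pass_ids
}
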