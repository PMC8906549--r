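#' Signed distance from read 3' ends to the closest poly(A) site
#'
#' For each read, finds the nearest same-strand annotated poly(A) cleavage
#' site on its chromosome and reports the signed distance in the gene's
#' frame: negative = the 3' end is upstream of the site (internal to the
#' gene), positive = downstream. Ties resolve to the first site in sorted
#' order; reads with no same-strand site on their chromosome get `NA` (they
#' fail the site filter).
#'
#' @param alignments Primary alignment tibble with `three_prime_pos`.
#' @param polya_sites Site tibble with `chrom`, `strand`, `pos` (e.g.
#'   [load_bed_sites()] with `as_sites = TRUE`).
#' @return Tibble `read_id`, `polya_site_distance`, `flagged`.
#' @export
polya_site_distance <- function(alignments, polya_sites) {
  sites <- arrange(polya_sites, .data$chrom, .data$strand, .data$pos)
  grouped <- alignments |>
    select("read_id", "chrom", "strand", pos = "three_prime_pos") |>
    mutate(.row = row_number()) |>
    group_by(.data$chrom, .data$strand)
  res <- dplyr::group_map(grouped, function(g, key) {
    s <- sites[sites$chrom == key$chrom & sites$strand == key$strand, ]
    if (nrow(s) == 0L) {
      return(tibble(.row = g$.row, polya_site_distance = NA_integer_, flagged = TRUE))
    }
    sp <- s$pos
    idx <- findInterval(g$pos, sp)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(sp))
    dl <- abs(g$pos - sp[left])
    dr <- abs(g$pos - sp[right])
    use_left <- idx >= 1L & (idx >= length(sp) | dl <= dr)
    pick <- if_else(use_left, left, right)
    d <- if (key$strand == "+") g$pos - sp[pick] else sp[pick] - g$pos
    tibble(
      .row = g$.row,
      polya_site_distance = as.integer(d),
      flagged = is.na(g$pos)
    )
  })
  bind_rows(res) |>
    arrange(.data$.row) |>
    mutate(read_id = alignments$read_id[.data$.row]) |>
    select("read_id", "polya_site_distance", "flagged")
}

#' Poly(A)-site window filter
#'
#' A read's 3' end supports a mature poly(A) end iff its signed distance to
#' the nearest annotated site falls inside the window, default -60 to +10 nt
#' inclusive at both bounds. Undefined distances fail.
#'
#' @param distance Integer vector of signed distances.
#' @param window Length-2 numeric `c(lower, upper)`.
#' @return Logical vector.
#' @examples
#' polya_site_filter(c(-60, -61, 0, 10, 11))
#' @export
polya_site_filter <- function(distance, window = c(-60, 10)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  !is.na(distance) & distance >= window[1] & distance <= window[2]
}

#' Full-length call for untreated reads
#'
#' Without cap-adapter evidence, a read is called full-length iff some
#' same-strand annotated transcript has its TSS within `w5` nt of the read
#' 5' end and its TES within `w3` nt of the read 3' end (both windows
#' inclusive).
#'
#' @param alignments Primary alignment tibble.
#' @param annotation Transcript table from [load_gtf_annotation()].
#' @param w5,w3 Maximum absolute 5' / 3' end offsets in nt.
#' @return Logical vector, one element per alignment row.
#' @export
full_length_untreated <- function(alignments, annotation, w5 = 25, w3 = 50) {
  ann <- split(annotation, paste(annotation$chrom, annotation$strand))
  vapply(seq_len(nrow(alignments)), function(i) {
    a <- ann[[paste(alignments$chrom[i], alignments$strand[i])]]
    if (is.null(a) || is.na(alignments$five_prime_pos[i])) return(FALSE)
    any(abs(alignments$five_prime_pos[i] - a$tss) <= w5 &
          abs(alignments$three_prime_pos[i] - a$tes) <= w3)
  }, logical(1))
}

#' Gene-type composition of aligned reads
#'
#' Assigns each read to the transcript with the closest same-strand TSS
#' (the same semantics as [closest_tss_distance()]) and reports the
#' fraction of assigned reads per `gene_type`, normalized to 1.
#'
#' @param alignments Primary alignment tibble.
#' @param annotation Transcript table from [load_gtf_annotation()].
#' @return Tibble `gene_type`, `n`, `fraction` (empty for empty input).
#' @export
classify_gene_type <- function(alignments, annotation) {
  if (nrow(alignments) == 0L) {
    return(tibble(gene_type = character(), n = integer(), fraction = double()))
  }
  dist <- closest_tss_distance(alignments, annotation)
  assigned <- dist[!is.na(dist$closest_tss), ]
  joined <- left_join(
    assigned,
    select(annotation, "transcript_id", "gene_type"),
    by = c(closest_tss = "transcript_id")
  )
  joined |>
    count(.data$gene_type, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$fraction))
}

#' Assign reads to genes for expression counting
#'
#' Uses the closest same-strand TSS transcript, additionally requiring the
#' read's aligned span to overlap or abut the assigned transcript's genomic
#' span; reads failing that are unassigned and excluded from counting.
#'
#' @param alignments Primary alignment tibble.
#' @param annotation Transcript table.
#' @return Tibble `read_id`, `gene_id`, `gene_type` (assigned reads only).
#' @export
assign_genes <- function(alignments, annotation) {
  dist <- closest_tss_distance(alignments, annotation)
  joined <- alignments |>
    select("read_id", "ref_start", "ref_end") |>
    left_join(select(dist, "read_id", "closest_tss"), by = "read_id") |>
    left_join(
      select(annotation, "transcript_id", "gene_id", "gene_type", "tss", "tes"),
      by = c(closest_tss = "transcript_id")
    )
  span_lo <- pmin(joined$tss, joined$tes)
  span_hi <- pmax(joined$tss, joined$tes) + 1L
  overlaps <- !is.na(joined$gene_id) &
    joined$ref_start <= span_hi & joined$ref_end >= span_lo
  joined[overlaps, c("read_id", "gene_id", "gene_type")]
}

#' Per-gene counts-per-million table
#'
#' @param assignments Tibble with a `gene_id` column, one row per read.
#' @return Tibble `gene_id`, `count`, `cpm` (`count * 1e6 / total`).
#' @export
gene_counts_cpm <- function(assignments) {
  assignments |>
    count(.data$gene_id, name = "count") |>
    mutate(cpm = .data$count * 1e6 / sum(.data$count)) |>
    arrange(.data$gene_id)
}

#' Rank correlation between two per-gene expression tables
#'
#' Spearman correlation of CPM over the union of genes present in either
#' table; a gene absent from one table counts as 0 there.
#'
#' @param table_a,table_b Tibbles from [gene_counts_cpm()].
#' @return Spearman rho (scalar).
#' @export
correlate_cpm <- function(table_a, table_b) {
  merged <- dplyr::full_join(
    select(table_a, "gene_id", cpm_a = "cpm"),
    select(table_b, "gene_id", cpm_b = "cpm"),
    by = "gene_id"
  ) |>
    replace_na(list(cpm_a = 0, cpm_b = 0))
  cor(merged$cpm_a, merged$cpm_b, method = "spearman")
}

#' Mapping-quality summary of a scaffold set
#'
#' @param mapq Integer vector of MAPQ values (0-60).
#' @return A list: `histogram` (tibble `mapq`, `n` over 0-60), `n`,
#'   `frac_q0`, `frac_q60`.
#' @export
mapq_summary <- function(mapq) {
  mapq <- mapq[!is.na(mapq)]
  hist <- tibble(mapq = 0:60) |>
    left_join(count(tibble(mapq = mapq), .data$mapq), by = "mapq") |>
    replace_na(list(n = 0L))
  list(
    histogram = hist,
    n = length(mapq),
    frac_q0 = if (length(mapq)) mean(mapq == 0) else NA_real_,
    frac_q60 = if (length(mapq)) mean(mapq == 60) else NA_real_
  )
}

#' Call full-length poly(A) RNA scaffolds
#'
#' Applies the scaffold cascade in fixed order — quality gate, cap-adapter
#' detection, adapter true-positive confirmation, 5'-clip filter, poly(A)
#' tail evidence, poly(A)-site window — and returns the per-read verdict
#' table together with the stage funnel. A read is a full-length scaffold
#' iff every stage passes. Reads are additionally annotated with their
#' assigned gene, MAPQ and poly(A)-site distance, and flagged as novel-TSS
#' scaffolds when they belong to a reported novel TSS cluster.
#'
#' @param reads Read tibble ([read_fastq()]).
#' @param adapter_calls Calls tibble from [detect_adapter()].
#' @param confirmed_ids Character vector from [true_positive_filter()].
#' @param alignments Primary *trimmed* alignment tibble used for all
#'   coordinate-based stages.
#' @param polya_table Tail table ([load_polya_table()]).
#' @param polya_sites Site tibble (`chrom`, `strand`, `pos`).
#' @param annotation Transcript table ([load_gtf_annotation()]).
#' @param min_q Quality gate threshold.
#' @param clip_remove_at 5'-clip removal threshold.
#' @param polya_window Site window `c(lower, upper)`.
#' @param novel_clusters Optional cluster table from [find_novel_tss()]
#'   used to flag novel-TSS scaffolds.
#' @return An object of class `scaffold_calls`: a list with `calls` (per-
#'   read tibble of stage booleans, `is_full_length`, `gene_id`,
#'   `gene_type`, `is_novel_tss`, `mapq`, `polya_site_distance`) and
#'   `funnel` (tibble `stage`, `n`, `pct_of_input`, `pct_of_previous`).
#' @export
call_scaffolds <- function(reads, adapter_calls, confirmed_ids, alignments,
                           polya_table, polya_sites, annotation,
                           min_q = 7, clip_remove_at = 15L,
                           polya_window = c(-60, 10),
                           novel_clusters = NULL) {
  calls <- tibble(read_id = reads$read_id) |>
    mutate(quality_pass = reads$mean_q >= min_q) |>
    left_join(select(adapter_calls, "read_id", cap_adapted = "detected"),
              by = "read_id") |>
    replace_na(list(cap_adapted = FALSE)) |>
    mutate(true_positive_confirmed = .data$read_id %in% confirmed_ids)

  aln <- select(alignments, "read_id", "five_prime_clip", "mapq", "chrom",
                "strand", "three_prime_pos")
  calls <- calls |>
    left_join(aln, by = "read_id") |>
    mutate(clip_pass = !is.na(.data$five_prime_clip) &
             .data$five_prime_clip < clip_remove_at)

  calls$polya_tail_pass <- polya_tail_pass(calls$read_id, polya_table)

  site_d <- polya_site_distance(alignments, polya_sites)
  calls <- calls |>
    left_join(select(site_d, "read_id", "polya_site_distance"), by = "read_id") |>
    mutate(polya_site_pass = polya_site_filter(.data$polya_site_distance,
                                               polya_window))

  stage_cols <- c("quality_pass", "cap_adapted", "true_positive_confirmed",
                  "clip_pass", "polya_tail_pass", "polya_site_pass")
  # cascade: a stage only counts if every earlier stage passed
  cascade <- Reduce(`&`, lapply(stage_cols, function(s) calls[[s]]),
                    accumulate = TRUE)
  names(cascade) <- stage_cols
  for (s in stage_cols) calls[[paste0(s, "_cascade")]] <- cascade[[s]]
  calls$is_full_length <- cascade[[length(cascade)]]

  genes <- assign_genes(alignments, annotation)
  calls <- left_join(calls, genes, by = "read_id")

  novel_ids <- if (!is.null(novel_clusters) && nrow(novel_clusters) > 0) {
    unlist(novel_clusters$read_ids)
  } else {
    character(0)
  }
  calls$is_novel_tss <- calls$is_full_length & calls$read_id %in% novel_ids

  n_input <- nrow(calls)
  funnel_n <- c(input = n_input, vapply(cascade, sum, integer(1)))
  funnel <- tibble(
    stage = names(funnel_n),
    n = as.integer(funnel_n),
    pct_of_input = unname(100 * funnel_n / n_input),
    pct_of_previous = unname(
      100 * funnel_n / dplyr::lag(funnel_n, default = n_input)
    )
  )

  structure(
    list(
      calls = select(calls, "read_id", dplyr::all_of(stage_cols),
                     "is_full_length", "gene_id", "gene_type", "is_novel_tss",
                     "mapq", "polya_site_distance"),
      funnel = funnel
    ),
    class = "scaffold_calls"
  )
}

#' @export
print.scaffold_calls <- function(x, ...) {
  cat("Full-length RNA scaffold calls:", nrow(x$calls), "reads\n")
  cat("Funnel:\n")
  print(as.data.frame(x$funnel), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.scaffold_calls
#' @export
glance.scaffold_calls <- function(x, ...) {
  tibble(
    n_reads = nrow(x$calls),
    n_full_length = sum(x$calls$is_full_length),
    n_novel_tss = sum(x$calls$is_novel_tss),
    frac_full_length = mean(x$calls$is_full_length)
  )
}

#' Tidy the scaffold stage funnel
#'
#' `tidy()` returns the per-stage funnel; `glance()` returns one-row
#' headline counts.
#'
#' @param x A `scaffold_calls` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scaffold_calls <- function(x, ...) {
  x$funnel
}
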