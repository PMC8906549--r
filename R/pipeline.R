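#' Run the full cap-adapted scaffold pipeline
#'
#' Orchestrates every stage over input files: FASTQ reads, truth-based or
#' aligner-produced SAM/BAM for the untrimmed and adapter-trimmed reads,
#' GTF annotation, poly(A)-site BED and per-read tail TSV. Stages run in
#' fixed order — quality gate, adapter detection, primary selection,
#' true-positive cross-check, clip filter, tail filter, site filter — then
#' novel-TSS discovery on the confirmed cap-adapted alignments and the
#' summary statistics (TSS distance CDF, gene-type composition, MAPQ
#' summary, per-gene CPM).
#'
#' @param fastq,untrimmed_sam,trimmed_sam,gtf,polya_bed,polya_tsv Input
#'   paths.
#' @param min_q Quality gate (mean read quality).
#' @param adapter An [adapter_config()].
#' @param clip_remove_at Remove alignments with this many or more 5'-clipped
#'   bases.
#' @param polya_window Poly(A)-site window `c(lower, upper)` nt.
#' @param novel_min_dist,novel_link_dist,novel_min_reads Novel-TSS
#'   parameters (distance gate, linkage gap, minimum cluster support).
#' @param tss_window Window for the headline TSS-proximity fraction.
#' @return An object of class `nrceq_result`; see Details. Its `scaffolds`
#'   element is the [call_scaffolds()] result, `novel_clusters` the
#'   [find_novel_tss()] table, `disposition` a per-read terminal category
#'   (the stage at which the read dropped, or `"full_length"`).
#' @export
run_nrceq <- function(fastq, untrimmed_sam, trimmed_sam, gtf, polya_bed,
                      polya_tsv,
                      min_q = 7, adapter = adapter_config(),
                      clip_remove_at = 15L, polya_window = c(-60, 10),
                      novel_min_dist = 300, novel_link_dist = 50,
                      novel_min_reads = 2, tss_window = 300) {
  for (f in c(fastq, untrimmed_sam, trimmed_sam, gtf, polya_bed, polya_tsv)) {
    if (!file.exists(f)) abort(sprintf("input file does not exist: %s", f))
  }
  reads <- read_fastq(fastq)
  annotation <- load_gtf_annotation(gtf)
  polya_sites <- load_bed_sites(polya_bed, as_sites = TRUE)
  polya_table <- load_polya_table(polya_tsv)

  detect <- detect_adapter(reads, adapter)
  untrimmed <- select_primary(read_alignments(untrimmed_sam))
  trimmed <- select_primary(read_alignments(trimmed_sam))
  tp <- true_positive_filter(detect$calls, untrimmed, trimmed,
                             remove_at = clip_remove_at)

  scaffolds <- call_scaffolds(
    reads, detect$calls, tp$confirmed_ids, trimmed,
    polya_table, polya_sites, annotation,
    min_q = min_q, clip_remove_at = clip_remove_at,
    polya_window = polya_window
  )

  # novel TSS from the confirmed cap-adapted, clip-passing alignments
  confirmed_aln <- clip_filter(
    trimmed[trimmed$read_id %in% tp$confirmed_ids, ],
    remove_at = clip_remove_at
  )
  novel_clusters <- find_novel_tss(confirmed_aln, annotation,
                                   min_dist = novel_min_dist,
                                   link_dist = novel_link_dist,
                                   min_reads = novel_min_reads)
  novel_ids <- unlist(novel_clusters$read_ids)
  scaffolds$calls$is_novel_tss <- scaffolds$calls$is_full_length &
    scaffolds$calls$read_id %in% novel_ids

  tss_dist <- closest_tss_distance(confirmed_aln, annotation)
  tss_stats <- if (sum(!is.na(tss_dist$signed_distance)) > 0) {
    distance_cdf(tss_dist$signed_distance, window = tss_window)
  } else {
    list(fraction = NA_real_, cdf = tibble())
  }

  full <- scaffolds$calls[scaffolds$calls$is_full_length, ]
  gene_types <- classify_gene_type(confirmed_aln, annotation)
  cpm <- gene_counts_cpm(assign_genes(trimmed, annotation))

  stage_cols <- c("quality_pass", "cap_adapted", "true_positive_confirmed",
                  "clip_pass", "polya_tail_pass", "polya_site_pass")
  cascade <- Reduce(`&`, lapply(stage_cols, function(s) scaffolds$calls[[s]]),
                    accumulate = TRUE)
  drop_stage <- rep("full_length", nrow(scaffolds$calls))
  for (k in rev(seq_along(stage_cols))) {
    drop_stage[!cascade[[k]]] <- paste0("dropped_at_", stage_cols[k])
  }
  disposition <- tibble(read_id = scaffolds$calls$read_id,
                        disposition = drop_stage)

  structure(
    list(
      reads = reads,
      adapter_calls = detect$calls,
      trimmed_alignments = trimmed,
      untrimmed_alignments = untrimmed,
      confirmed_ids = tp$confirmed_ids,
      n_decoy_removed = tp$n_decoy,
      scaffolds = scaffolds,
      novel_clusters = novel_clusters,
      tss_distances = tss_dist,
      tss_fraction_within_window = tss_stats$fraction,
      tss_cdf = tss_stats$cdf,
      gene_type_composition = gene_types,
      cpm = cpm,
      mapq = mapq_summary(full$mapq),
      disposition = disposition,
      params = list(
        min_q = min_q, identity_threshold = adapter$identity_threshold,
        clip_remove_at = clip_remove_at, polya_window = polya_window,
        novel_min_dist = novel_min_dist, novel_link_dist = novel_link_dist,
        novel_min_reads = novel_min_reads, tss_window = tss_window
      )
    ),
    class = "nrceq_result"
  )
}

#' Simulate a data set and run the pipeline over its files
#'
#' Convenience wrapper: generates the reference and read set for `config`
#' in a temporary directory (or `dir`), then runs [run_nrceq()] on the
#' written files, so the whole round trip exercises the on-disk formats.
#'
#' @param config A [sim_config()].
#' @param dir Working directory (default a fresh temp dir).
#' @param ... Passed to [run_nrceq()].
#' @return A list: `result` (the `nrceq_result`), `truth`, `reference`,
#'   `sim`.
#' @export
run_nrceq_sim <- function(config, dir = tempfile("nrceq_sim_"), ...) {
  reference <- make_reference(config, dir = dir)
  sim <- simulate_reads(config, reference, dir = dir)
  result <- run_nrceq(
    fastq = sim$files[["reads"]],
    untrimmed_sam = sim$files[["untrimmed"]],
    trimmed_sam = sim$files[["trimmed"]],
    gtf = reference$files[["annotation"]],
    polya_bed = reference$files[["polya_sites"]],
    polya_tsv = sim$files[["polya"]],
    ...
  )
  list(result = result, truth = sim$truth, reference = reference, sim = sim)
}

#' @export
print.nrceq_result <- function(x, ...) {
  cat("Cap-adapted scaffold pipeline result\n")
  cat(sprintf("  reads in:            %d\n", nrow(x$reads)))
  print(as.data.frame(x$scaffolds$funnel), row.names = FALSE)
  cat(sprintf("  novel TSS clusters:  %d\n", nrow(x$novel_clusters)))
  if (!is.na(x$tss_fraction_within_window)) {
    cat(sprintf("  cap-adapted 5' ends within %d nt of annotated TSS: %.1f%%\n",
                x$params$tss_window, 100 * x$tss_fraction_within_window))
  }
  invisible(x)
}

#' Tidy the pipeline stage funnel
#'
#' `tidy()` on a pipeline result returns the stage funnel (counts and both
#' percentage bases); `glance()` returns one-row headline statistics.
#'
#' @param x An `nrceq_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nrceq_result <- function(x, ...) {
  x$scaffolds$funnel
}

#' @rdname tidy.nrceq_result
#' @export
glance.nrceq_result <- function(x, ...) {
  calls <- x$scaffolds$calls
  tibble(
    n_reads = nrow(calls),
    n_cap_adapted = sum(calls$quality_pass & calls$cap_adapted),
    n_full_length = sum(calls$is_full_length),
    n_novel_tss_scaffolds = sum(calls$is_novel_tss),
    n_novel_clusters = nrow(x$novel_clusters),
    frac_tss_within_window = x$tss_fraction_within_window,
    frac_q60 = x$mapq$frac_q60,
    frac_q0 = x$mapq$frac_q0
  )
}

#' Write the pipeline report files
#'
#' Persists the per-read verdicts (TSV), stage funnel (JSON, counts plus
#' both percentage bases), novel-TSS clusters (BED), full-length scaffolds
#' (BED12 with exon blocks), per-gene CPM (TSV) and the per-read terminal
#' disposition (TSV).
#'
#' @param result An `nrceq_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    calls = file.path(dir, "scaffold_calls.tsv"),
    funnel = file.path(dir, "funnel.json"),
    clusters = file.path(dir, "novel_tss.bed"),
    scaffolds = file.path(dir, "scaffolds.bed12"),
    cpm = file.path(dir, "gene_cpm.tsv"),
    disposition = file.path(dir, "read_disposition.tsv")
  )
  readr::write_tsv(result$scaffolds$calls, files[["calls"]])
  jsonlite::write_json(
    list(
      funnel = result$scaffolds$funnel,
      n_decoy_removed = result$n_decoy_removed,
      params = result$params
    ),
    files[["funnel"]], auto_unbox = TRUE, digits = NA
  )
  cl <- result$novel_clusters
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", cl$chrom, cl$representative_pos,
            cl$representative_pos + 1L, cl$cluster_id, cl$size, cl$strand),
    files[["clusters"]]
  )
  writeLines(scaffold_bed12(result), files[["scaffolds"]])
  readr::write_tsv(result$cpm, files[["cpm"]])
  readr::write_tsv(result$disposition, files[["disposition"]])
  invisible(files)
}

#' @keywords internal
#' BED12 lines (aligned exon segments as blocks) for full-length scaffolds.
scaffold_bed12 <- function(result) {
  full_ids <- result$scaffolds$calls$read_id[result$scaffolds$calls$is_full_length]
  aln <- result$trimmed_alignments
  aln <- aln[aln$read_id %in% full_ids & !is.na(aln$ref_start), ]
  if (nrow(aln) == 0L) return(character(0))
  vapply(seq_len(nrow(aln)), function(i) {
    ops <- parse_cigar(aln$cigar[i])[[1]]
    ref_consuming <- ops$op %in% c("M", "D", "N", "=", "X")
    pos <- aln$ref_start[i]
    block_start <- integer(0)
    block_len <- integer(0)
    open <- FALSE
    for (k in seq_along(ops$op)) {
      if (!ref_consuming[k]) next
      if (ops$op[k] == "N") {
        open <- FALSE
      } else {
        if (!open) {
          block_start <- c(block_start, pos)
          block_len <- c(block_len, 0L)
          open <- TRUE
        }
        block_len[length(block_len)] <- block_len[length(block_len)] + ops$len[k]
      }
      pos <- pos + ops$len[k]
    }
    sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
      aln$chrom[i], aln$ref_start[i], aln$ref_end[i], aln$read_id[i],
      aln$mapq[i], aln$strand[i], aln$ref_start[i], aln$ref_end[i],
      length(block_len),
      paste0(paste(block_len, collapse = ","), ","),
      paste0(paste(block_start - aln$ref_start[i], collapse = ","), ",")
    )
  }, character(1))
}
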