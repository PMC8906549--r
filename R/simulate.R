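#' Simulation configuration
#'
#' Parameters of the deterministic toy-data generator. Defaults emulate the
#' study conditions of a cap-adaptation experiment on poly(A)-selected RNA:
#' 14% of reads carry the 45-nt cap-adapter at their 5' end, the majority
#' are 5'-truncated strand-break products without an adapter, a small
#' fraction are genomic decoys whose transcript genuinely begins with the
#' adapter sequence, and a small fraction are degradation products that
#' acquired a poly(A) tail at an internal position. The substitution error
#' rate defaults to 0.13 (87% median basecall identity of direct-RNA
#' nanopore reads); mapping qualities are drawn with 72.3% Q60 and 6.8% Q0
#' mass.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_genes Number of genes (one transcript each), spread over
#'   `n_chroms` chromosomes on both strands.
#' @param n_chroms Number of chromosomes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length,intergenic_gap Length ranges in nt.
#' @param n_reads Number of reads (novel-TSS reads are added on top).
#' @param frac_capped,frac_truncated,frac_decoy,frac_degradation Class
#'   fractions of `n_reads`; the remainder are uncapped full-span reads.
#'   Fractions must sum to at most 1.
#' @param substitution_rate Per-base substitution probability.
#' @param polya_length Tail length range in nt.
#' @param adapter_seq DNA form of the 45-nt cap-adapter.
#' @param quality_range Per-base Phred range of simulated reads.
#' @param n_novel_clusters,novel_cluster_size Planted novel-TSS clusters:
#'   each cluster places `size` (range) cap-adapted reads with 5' ends at
#'   least `novel_offset` nt upstream of a distinct gene's annotated TSS,
#'   consecutive member ends within `novel_step_max` nt.
#' @param n_novel_singletons Isolated single novel-TSS reads (must never be
#'   reported as clusters).
#' @param novel_offset,novel_step_max See above.
#' @param n_decoy_genes Genes whose first exon starts with the adapter
#'   sequence planted in the genome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12L,
                       n_chroms = 2L,
                       exons_per_gene = c(2L, 4L),
                       exon_length = c(100L, 400L),
                       intron_length = c(60L, 300L),
                       intergenic_gap = c(2000L, 4000L),
                       n_reads = 1000L,
                       frac_capped = 0.14,
                       frac_truncated = 0.60,
                       frac_decoy = 0.02,
                       frac_degradation = 0.04,
                       substitution_rate = 0.13,
                       polya_length = c(20L, 80L),
                       adapter_seq = u_to_t("CUCUUCCGAUCUACACUCUUUCCCUACACGACGCUCUUCCGAUCU"),
                       quality_range = c(15L, 35L),
                       n_novel_clusters = 0L,
                       novel_cluster_size = c(2L, 10L),
                       n_novel_singletons = 0L,
                       novel_offset = 400L,
                       novel_step_max = 25L,
                       n_decoy_genes = 2L) {
  fr <- frac_capped + frac_truncated + frac_decoy + frac_degradation
  stopifnot(
    fr <= 1, frac_capped >= 0, frac_truncated >= 0, frac_decoy >= 0,
    frac_degradation >= 0, substitution_rate >= 0, substitution_rate < 1,
    n_genes >= n_novel_clusters + n_novel_singletons + n_decoy_genes + 1L
  )
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_chroms = as.integer(n_chroms),
      exons_per_gene = as.integer(exons_per_gene),
      exon_length = as.integer(exon_length),
      intron_length = as.integer(intron_length),
      intergenic_gap = as.integer(intergenic_gap),
      n_reads = as.integer(n_reads),
      frac_capped = frac_capped, frac_truncated = frac_truncated,
      frac_decoy = frac_decoy, frac_degradation = frac_degradation,
      substitution_rate = substitution_rate,
      polya_length = as.integer(polya_length),
      adapter_seq = toupper(adapter_seq),
      quality_range = as.integer(quality_range),
      n_novel_clusters = as.integer(n_novel_clusters),
      novel_cluster_size = as.integer(novel_cluster_size),
      n_novel_singletons = as.integer(n_novel_singletons),
      novel_offset = as.integer(novel_offset),
      novel_step_max = as.integer(novel_step_max),
      n_decoy_genes = as.integer(n_decoy_genes)
    ),
    class = "sim_config"
  )
}

#' @keywords internal
#' Run code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  force(code)
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' Best barcode identity over all sliding windows of a sequence
#' (overlapping 300-nt chunks cover every possible 150-nt read window).
max_barcode_identity <- function(seq, barcode, chunk = 300L, stride = 150L) {
  n <- nchar(seq)
  starts <- unique(c(seq(1L, max(n - chunk + 1L, 1L), by = stride),
                     max(n - chunk + 1L, 1L)))
  chunks <- substr(rep(seq, length(starts)), starts,
                   pmin(starts + chunk - 1L, n))
  res <- .semiglobal_align(chunks, barcode, 3L, -6L, -5L, -2L, chunk)
  max(res$identity_pct)
}

#' @keywords internal
rint <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a toy reference: genome, annotation and poly(A) atlas
#'
#' Lays out `n_genes` multi-exon genes on both strands of `n_chroms`
#' random-sequence chromosomes with wide intergenic gaps, places one
#' poly(A) site at every transcript TES, and plants the adapter sequence
#' into the genome at the TSS of `n_decoy_genes` plus-strand genes (so
#' reads from those genes begin with a genomic adapter look-alike). Fully
#' deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf` and `polya_sites.bed`.
#' @return A list: `genome` (named character vector), `annotation`
#'   (transcript tibble with an `exons` list-column of 0-based half-open
#'   exon tables, plus `is_decoy` and `novel_role`), `polya_sites`,
#'   `config`, and `files` when `dir` was given.
#' @export
make_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- with_seed(config$seed, {
    n_per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
    extra <- config$n_genes %% config$n_chroms
    if (extra > 0) n_per_chrom[seq_len(extra)] <- n_per_chrom[seq_len(extra)] + 1L

    # roles: decoy genes first (forced to + strand), then novel-TSS hosts
    roles <- rep(NA_character_, config$n_genes)
    k <- 0L
    if (config$n_decoy_genes > 0) {
      roles[k + seq_len(config$n_decoy_genes)] <- "decoy"
      k <- k + config$n_decoy_genes
    }
    if (config$n_novel_clusters > 0) {
      roles[k + seq_len(config$n_novel_clusters)] <- "novel_cluster"
      k <- k + config$n_novel_clusters
    }
    if (config$n_novel_singletons > 0) {
      roles[k + seq_len(config$n_novel_singletons)] <- "novel_singleton"
    }
    roles <- sample(roles) # shuffle roles over gene slots

    gene_types <- sample(c("protein_coding", "lncRNA", "snoRNA"),
                         config$n_genes, replace = TRUE,
                         prob = c(0.8, 0.15, 0.05))

    genes <- list()
    gi <- 0L
    for (ci in seq_len(config$n_chroms)) {
      cursor <- rint(1L, config$intergenic_gap)
      for (g in seq_len(n_per_chrom[ci])) {
        gi <- gi + 1L
        role <- roles[gi]
        n_ex <- rint(1L, config$exons_per_gene)
        ex_len <- rint(n_ex, config$exon_length)
        # decoy genes need room for the planted adapter in exon 1;
        # all transcripts need >= 200 nt for truncation/degradation models
        if (identical(role, "decoy")) {
          ex_len[1L] <- max(ex_len[1L], 150L)
        }
        while (sum(ex_len) < 220L) ex_len[1L] <- ex_len[1L] + 100L
        in_len <- if (n_ex > 1) rint(n_ex - 1L, config$intron_length) else integer(0)
        starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
        ends <- starts + ex_len
        strand <- if (identical(role, "decoy")) "+" else sample(c("+", "-"), 1L)
        genes[[gi]] <- tibble(
          gene_id = sprintf("GENE%03d", gi),
          chrom = sprintf("chr%d", ci),
          strand = strand,
          start0 = starts[1], end0 = ends[n_ex],
          gene_type = gene_types[gi],
          role = role,
          exons = list(tibble(start = starts, end = ends))
        )
        cursor <- ends[n_ex] + rint(1L, config$intergenic_gap)
      }
    }
    genes <- bind_rows(genes)

    chrom_len <- genes |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$end0) + max(config$intergenic_gap), .groups = "drop")
    genome <- setNames(
      vapply(chrom_len$len, random_dna, character(1)),
      chrom_len$chrom
    )

    # Screen the background: re-randomize any gene whose spliced transcript
    # contains a spurious barcode look-alike, so adapter-like sequence
    # occurs only where planted. Screening at identity >= 70 keeps both
    # published operating points (70 and 74) clear of chance hits.
    bc <- adapter_config()$barcode_seq
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      for (iter in 1:25) {
        tx <- spliced_seq(genome[[genes$chrom[i]]], ex, genes$strand[i])
        if (max_barcode_identity(tx, bc) < 70) break
        span_start <- genes$start0[i]
        span_end <- genes$end0[i]
        s <- genome[[genes$chrom[i]]]
        substr(s, span_start + 1L, span_end) <-
          random_dna(span_end - span_start)
        genome[[genes$chrom[i]]] <- s
      }
    }

    # plant the adapter into the genome at decoy TSS (plus strand only)
    for (i in which(genes$role %in% "decoy")) {
      tss <- genes$start0[i]
      s <- genome[[genes$chrom[i]]]
      substr(s, tss + 1L, tss + nchar(config$adapter_seq)) <- config$adapter_seq
      genome[[genes$chrom[i]]] <- s
    }

    annotation <- genes |>
      mutate(
        transcript_id = paste0(.data$gene_id, ".T1"),
        gene_name = .data$gene_id,
        tss = if_else(.data$strand == "+", .data$start0, .data$end0 - 1L),
        tes = if_else(.data$strand == "+", .data$end0 - 1L, .data$start0),
        is_decoy = .data$role %in% "decoy",
        novel_role = if_else(.data$role %in% c("novel_cluster", "novel_singleton"),
                             .data$role, NA_character_)
      ) |>
      select("transcript_id", "gene_id", "gene_name", "gene_type", "chrom",
             "strand", "tss", "tes", "exons", "is_decoy", "novel_role")

    polya_sites <- annotation |>
      transmute(chrom = .data$chrom, strand = .data$strand, pos = .data$tes) |>
      arrange(.data$chrom, .data$strand, .data$pos)

    list(genome = genome, annotation = annotation,
         polya_sites = polya_sites, config = config)
  })
  if (!is.null(dir)) {
    ref$files <- write_reference(ref, dir)
  }
  ref
}

#' @keywords internal
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), fa)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(format_gtf(ref$annotation), gtf)
  bed <- file.path(dir, "polya_sites.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ref$polya_sites$chrom, ref$polya_sites$pos,
                     ref$polya_sites$pos + 1L,
                     sprintf("pas_%04d", seq_len(nrow(ref$polya_sites))),
                     ref$polya_sites$strand), bed)
  c(genome = fa, annotation = gtf, polya_sites = bed)
}

#' @keywords internal
format_gtf <- function(annotation) {
  unlist(lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    ex <- a$exons[[1]]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_type "%s";',
      a$gene_id, a$transcript_id, a$gene_name, a$gene_type
    )
    span <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                    a$chrom, c("gene", "transcript"),
                    min(ex$start) + 1L, max(ex$end), a$strand, attrs)
    exl <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                   a$chrom, ex$start + 1L, ex$end, a$strand, attrs)
    c(span, exl)
  }))
}

#' @keywords internal
#' Genomic sub-segments of a transcript after trimming `trim5`/`trim3`
#' bases in transcript (5'->3') coordinates. Exons must be sorted by
#' genomic start; returns segments in genomic order.
transcript_segments <- function(exons, strand, trim5 = 0L, trim3 = 0L) {
  lens <- exons$end - exons$start
  total <- sum(lens)
  stopifnot(trim5 + trim3 < total)
  # trims in genomic frame: on '+' trim5 cuts from the left, on '-' from the right
  left <- if (strand == "+") trim5 else trim3
  right <- if (strand == "+") trim3 else trim5
  starts <- exons$start
  ends <- exons$end
  i <- 1L
  while (left > 0L) {
    take <- min(left, ends[i] - starts[i])
    starts[i] <- starts[i] + take
    left <- left - take
    if (starts[i] == ends[i]) i <- i + 1L
  }
  j <- length(ends)
  while (right > 0L) {
    take <- min(right, ends[j] - starts[j])
    ends[j] <- ends[j] - take
    right <- right - take
    if (starts[j] == ends[j]) j <- j - 1L
  }
  keep <- starts < ends
  tibble(start = starts[keep], end = ends[keep])
}

#' @keywords internal
spliced_seq <- function(genome_seq, segments, strand) {
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    substr(genome_seq, segments$start[i] + 1L, segments$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' @keywords internal
segments_cigar <- function(segments, clip_left = 0L, clip_right = 0L) {
  lens <- segments$end - segments$start
  gaps <- if (nrow(segments) > 1) segments$start[-1] - segments$end[-nrow(segments)] else integer(0)
  body <- paste0(lens[1], "M")
  if (length(gaps) > 0) {
    for (k in seq_along(gaps)) {
      body <- paste0(body, gaps[k], "N", lens[k + 1L], "M")
    }
  }
  paste0(
    if (clip_left > 0) paste0(clip_left, "S") else "",
    body,
    if (clip_right > 0) paste0(clip_right, "S") else ""
  )
}

#' Simulate a cap-adaptation read set with planted truth
#'
#' Draws reads of five classes from the reference — cap-adapted (adapter +
#' full spliced transcript + tail), 5'-truncated (no adapter, internal 5'
#' breakpoint), uncapped full-span, genomic decoys (transcript begins with
#' the adapter sequence planted in the genome) and degradation-tailed
#' (adapter + transcript cut >= 100 nt before the TES + tail) — plus
#' novel-TSS reads whose first exon extends upstream of the annotated TSS
#' per the reference's planted cluster/singleton roles. Substitution errors
#' are applied at `config$substitution_rate`. Emits the reads (U alphabet,
#' as basecalled), a per-read truth table, truth-based spliced SAM
#' alignments for both the untrimmed and adapter-trimmed reads (so no
#' external aligner is needed), and a poly(A) tail table marking every
#' planted tail as `PASS`.
#'
#' @param config A [sim_config()].
#' @param reference Output of [make_reference()] for the same config.
#' @param dir Optional output directory; writes `reads.fastq`,
#'   `untrimmed.sam`, `trimmed.sam`, `polya.tsv`, `truth.tsv`.
#' @return A list: `reads` (tibble as [read_fastq()]), `truth`,
#'   `sam_untrimmed`, `sam_trimmed` (character vectors of SAM lines),
#'   `polya_table`, and `files` when `dir` was given.
#' @export
simulate_reads <- function(config, reference, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ann <- reference$annotation
  out <- with_seed(config$seed + 1L, {
    n <- config$n_reads
    n_capped <- round(n * config$frac_capped)
    n_trunc <- round(n * config$frac_truncated)
    n_decoy <- round(n * config$frac_decoy)
    n_degr <- round(n * config$frac_degradation)
    n_uncap <- n - n_capped - n_trunc - n_decoy - n_degr
    stopifnot(n_uncap >= 0)

    normal_genes <- which(is.na(ann$novel_role) & !ann$is_decoy)
    decoy_genes <- which(ann$is_decoy)
    if (n_decoy > 0 && length(decoy_genes) == 0) {
      abort("config requests decoy reads but the reference has no decoy genes")
    }

    classes <- c(
      rep("capped", n_capped), rep("truncated", n_trunc),
      rep("uncapped", n_uncap), rep("decoy", n_decoy),
      rep("degradation_tailed", n_degr)
    )
    gene_idx <- integer(length(classes))
    is_dec <- classes == "decoy"
    gene_idx[!is_dec] <- sample(rep(normal_genes, 2L), sum(!is_dec),
                                replace = TRUE)
    if (any(is_dec)) {
      gene_idx[is_dec] <- sample(rep(decoy_genes, 2L), sum(is_dec), replace = TRUE)
    }

    # planted novel-TSS reads (all cap-adapted, upstream-extended exon 1)
    novel <- list()
    for (i in which(ann$novel_role %in% "novel_cluster")) {
      k <- rint(1L, config$novel_cluster_size)
      steps <- cumsum(c(0L, rint(k - 1L, c(1L, config$novel_step_max))))
      novel[[length(novel) + 1L]] <- tibble(
        gene_idx = i, class = "novel",
        upstream = config$novel_offset + steps
      )
    }
    for (i in which(ann$novel_role %in% "novel_singleton")) {
      novel[[length(novel) + 1L]] <- tibble(
        gene_idx = i, class = "novel", upstream = config$novel_offset
      )
    }
    novel <- if (length(novel)) bind_rows(novel) else tibble(
      gene_idx = integer(), class = character(), upstream = integer()
    )

    all_gene_idx <- c(gene_idx, novel$gene_idx)
    all_classes <- c(classes, novel$class)
    all_upstream <- c(rep(0L, length(classes)), novel$upstream)
    nr <- length(all_classes)
    read_id <- sprintf("read_%05d", seq_len(nr))

    tails <- rint(nr, config$polya_length)
    # study-condition MAPQ mixture: 72.3% Q60, 6.8% Q0, remainder 1-59
    u <- runif(nr)
    mapq <- ifelse(u < 0.723, 60L,
                   ifelse(u < 0.791, 0L, sample(1:59, nr, replace = TRUE)))

    recs <- vector("list", nr)
    for (r in seq_len(nr)) {
      a <- ann[all_gene_idx[r], ]
      exons <- a$exons[[1]]
      cls <- all_classes[r]
      total_len <- sum(exons$end - exons$start)
      trim5 <- 0L
      trim3 <- 0L
      if (cls == "truncated") {
        trim5 <- sample(10:(total_len - 110L), 1L)
      } else if (cls == "degradation_tailed") {
        trim3 <- sample(100:min(200L, total_len - 100L), 1L)
      }
      ex <- exons
      if (all_upstream[r] > 0L) {
        # extend the 5'-most exon upstream in the genomic frame
        if (a$strand == "+") {
          ex$start[1] <- ex$start[1] - all_upstream[r]
        } else {
          ex$end[nrow(ex)] <- ex$end[nrow(ex)] + all_upstream[r]
        }
      }
      segs <- transcript_segments(ex, a$strand, trim5, trim3)
      body <- spliced_seq(reference$genome[[a$chrom]], segs, a$strand)
      adapter <- cls %in% c("capped", "degradation_tailed", "novel")
      seq5 <- if (adapter) config$adapter_seq else ""
      read_dna <- paste0(seq5, body, strrep("A", tails[r]))
      # substitution-only error model
      if (config$substitution_rate > 0) {
        bases <- strsplit(read_dna, "")[[1]]
        hit <- which(runif(length(bases)) < config$substitution_rate)
        if (length(hit)) {
          bases[hit] <- vapply(bases[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
          read_dna <- paste(bases, collapse = "")
        }
      }
      fp <- if (a$strand == "+") segs$start[1] else segs$end[nrow(segs)] - 1L
      tp <- if (a$strand == "+") segs$end[nrow(segs)] - 1L else segs$start[1]
      recs[[r]] <- list(
        read_id = read_id[r], class = cls, transcript_id = a$transcript_id,
        chrom = a$chrom, strand = a$strand,
        segs = segs, read_dna = read_dna,
        adapter_len = nchar(seq5), tail_len = tails[r],
        true_5p = fp, true_3p = tp, mapq = mapq[r]
      )
    }

    quals <- vapply(recs, function(rc) {
      intToUtf8(rint(nchar(rc$read_dna), config$quality_range) + 33L)
    }, character(1))

    reads <- tibble(
      read_id = read_id,
      sequence = chartr("Tt", "Uu", vapply(recs, `[[`, character(1), "read_dna")),
      qualities = quals
    )
    reads$mean_q <- mean_read_quality(reads$qualities)

    truth <- tibble(
      read_id = read_id,
      class = all_classes,
      transcript_id = vapply(recs, `[[`, character(1), "transcript_id"),
      chrom = vapply(recs, `[[`, character(1), "chrom"),
      strand = vapply(recs, `[[`, character(1), "strand"),
      true_5p = vapply(recs, `[[`, integer(1), "true_5p"),
      true_3p = vapply(recs, `[[`, integer(1), "true_3p"),
      adapter_present = vapply(recs, function(rc) rc$adapter_len > 0, logical(1)),
      tail_length = vapply(recs, `[[`, integer(1), "tail_len"),
      mapq = vapply(recs, `[[`, integer(1), "mapq")
    )

    header <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", names(reference$genome),
              nchar(reference$genome))
    )
    sam_line <- function(rc, trim_adapter) {
      adapter_clip <- if (trim_adapter) 0L else rc$adapter_len
      segs <- rc$segs
      read_dna <- rc$read_dna
      qual <- quals[match(rc$read_id, read_id)]
      if (trim_adapter && rc$adapter_len > 0L) {
        read_dna <- substr(read_dna, rc$adapter_len + 1L, nchar(read_dna))
        qual <- substr(qual, rc$adapter_len + 1L, nchar(qual))
      }
      if (trim_adapter && rc$class == "decoy") {
        # trimming a genomic decoy removes real transcript bases
        nad <- nchar(reference$config$adapter_seq)
        segs <- transcript_segments(segs, rc$strand, trim5 = nad)
        read_dna <- substr(read_dna, nad + 1L, nchar(read_dna))
        qual <- substr(qual, nad + 1L, nchar(qual))
      }
      if (rc$strand == "+") {
        cigar <- segments_cigar(segs, adapter_clip, rc$tail_len)
        flag <- 0L
        seq_out <- read_dna
        qual_out <- qual
      } else {
        cigar <- segments_cigar(segs, rc$tail_len, adapter_clip)
        flag <- 16L
        seq_out <- revcomp(read_dna)
        qual_out <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
      }
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
              rc$read_id, flag, rc$chrom, segs$start[1] + 1L, rc$mapq,
              cigar, seq_out, qual_out)
    }
    sam_untrimmed <- c(header, vapply(recs, sam_line, character(1),
                                      trim_adapter = FALSE))
    sam_trimmed <- c(header, vapply(recs, sam_line, character(1),
                                    trim_adapter = TRUE))

    polya_table <- tibble(
      read_id = read_id,
      tail_length = as.numeric(truth$tail_length),
      qc_tag = "PASS"
    )

    list(reads = reads, truth = truth, sam_untrimmed = sam_untrimmed,
         sam_trimmed = sam_trimmed, polya_table = polya_table)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      reads = file.path(dir, "reads.fastq"),
      untrimmed = file.path(dir, "untrimmed.sam"),
      trimmed = file.path(dir, "trimmed.sam"),
      polya = file.path(dir, "polya.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_fastq(out$reads, files[["reads"]])
    writeLines(out$sam_untrimmed, files[["untrimmed"]])
    writeLines(out$sam_trimmed, files[["trimmed"]])
    readr::write_tsv(
      out$polya_table |>
        rename(readname = "read_id", polya_length = "tail_length"),
      files[["polya"]]
    )
    readr::write_tsv(out$truth, files[["truth"]])
    out$files <- files
  }
  out
}
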