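# Reconstruct the error-free read for a capped read from the reference:
# adapter + spliced transcript + tail. Used to measure simulated identity.
reconstruct_capped <- function(truth_row, reference, config) {
  a <- reference$annotation[
    reference$annotation$transcript_id == truth_row$transcript_id, ]
  ex <- a$exons[[1]]
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    substr(reference$genome[[a$chrom]], ex$start[i] + 1L, ex$end[i])
  }, character(1))
  tx <- paste(parts, collapse = "")
  if (a$strand == "-") {
    tx <- paste(rev(strsplit(chartr("ACGT", "TGCA", tx), "")[[1]]), collapse = "")
  }
  paste0(config$adapter_seq, tx, strrep("A", truth_row$tail_length))
}

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_reads = 60, n_genes = 8,
                    substitution_rate = 0.1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- make_reference(cfg, dir = d1)
  s1 <- simulate_reads(cfg, r1, dir = d1)
  r2 <- make_reference(cfg, dir = d2)
  s2 <- simulate_reads(cfg, r2, dir = d2)
  for (f in c("genome.fa", "annotation.gtf", "polya_sites.bed",
              "reads.fastq", "untrimmed.sam", "trimmed.sam", "polya.tsv",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("every transcript TES carries a poly(A) site at distance zero", {
  cfg <- sim_config(seed = 6, n_genes = 10)
  ref <- make_reference(cfg)
  joined <- dplyr::inner_join(
    dplyr::select(ref$annotation, "chrom", "strand", "tes"),
    ref$polya_sites, by = c("chrom", "strand", tes = "pos")
  )
  expect_equal(nrow(joined), nrow(ref$annotation))
})

test_that("written GTF round-trips through the loader with matching TSS/TES", {
  cfg <- sim_config(seed = 8, n_genes = 9)
  dir <- withr::local_tempdir()
  ref <- make_reference(cfg, dir = dir)
  loaded <- load_gtf_annotation(file.path(dir, "annotation.gtf"))
  merged <- dplyr::inner_join(
    dplyr::select(ref$annotation, "transcript_id", "strand",
                  tss_sim = "tss", tes_sim = "tes"),
    dplyr::select(loaded, "transcript_id", "tss", "tes"),
    by = "transcript_id"
  )
  expect_equal(nrow(merged), cfg$n_genes)
  expect_equal(merged$tss, merged$tss_sim)
  expect_equal(merged$tes, merged$tes_sim)
  # a minus-strand gene has its TSS at the GTF end coordinate
  minus <- merged[merged$strand == "-", ]
  expect_true(all(minus$tss > minus$tes))
})

test_that("truth-based SAM agrees with the planted truth when read back", {
  cfg <- sim_config(seed = 9, n_reads = 80, n_genes = 8,
                    substitution_rate = 0)
  dir <- withr::local_tempdir()
  ref <- make_reference(cfg, dir = dir)
  sim <- simulate_reads(cfg, ref, dir = dir)
  aln <- select_primary(read_alignments(file.path(dir, "trimmed.sam")))
  merged <- dplyr::inner_join(sim$truth, aln, by = "read_id")
  expect_equal(nrow(merged), nrow(sim$truth))
  expect_equal(merged$strand.x, merged$strand.y)
  # trimming a genomic decoy removes 45 real transcript bases, shifting its
  # aligned 5' end; all other classes align exactly at the planted 5' end
  decoy <- merged$class == "decoy"
  expect_equal(merged$five_prime_pos[!decoy], merged$true_5p[!decoy])
  expect_equal(merged$five_prime_pos[decoy], merged$true_5p[decoy] + 45L)
  expect_equal(merged$three_prime_pos, merged$true_3p)
  # untrimmed alignments of adapter-bearing reads soft-clip the adapter
  unt <- select_primary(read_alignments(file.path(dir, "untrimmed.sam")))
  m2 <- dplyr::inner_join(sim$truth, unt, by = "read_id")
  adapter_true <- m2$adapter_present & m2$class != "decoy"
  expect_true(all(m2$five_prime_clip[adapter_true] == 45L))
  expect_true(all(m2$five_prime_clip[m2$class == "decoy"] == 0L))
})

test_that("pure class mixes drive the upstream pipeline to its limits", {
  base <- function(fc, ft, fd = 0, fg = 0) {
    sim_config(seed = 12, n_reads = 60, n_genes = 8, substitution_rate = 0,
               frac_capped = fc, frac_truncated = ft, frac_decoy = fd,
               frac_degradation = fg, n_decoy_genes = if (fd > 0) 2L else 0L)
  }
  cfg <- base(1, 0)
  ref <- make_reference(cfg)
  sim <- simulate_reads(cfg, ref)
  det <- detect_adapter(sim$reads)
  expect_true(all(det$calls$detected)) # all capped -> all detected
  cfg2 <- base(0, 1)
  sim2 <- simulate_reads(cfg2, make_reference(cfg2))
  det2 <- detect_adapter(sim2$reads)
  expect_false(any(det2$calls$detected)) # all truncated -> none detected
})

test_that("degradation-tailed reads end >= 100 nt inside the transcript", {
  cfg <- sim_config(seed = 13, n_reads = 200, n_genes = 10,
                    substitution_rate = 0, frac_degradation = 0.5,
                    frac_truncated = 0.2, frac_capped = 0.2)
  ref <- make_reference(cfg)
  sim <- simulate_reads(cfg, ref)
  degr <- sim$truth[sim$truth$class == "degradation_tailed", ]
  expect_gt(nrow(degr), 50)
  d <- polya_site_distance(
    toy_alignment(degr$read_id, degr$chrom, degr$strand, degr$true_5p) |>
      dplyr::mutate(three_prime_pos = degr$true_3p,
                    chrom = degr$chrom, strand = degr$strand),
    ref$polya_sites
  )
  expect_true(all(d$polya_site_distance <= -100L))
  expect_equal(mean(polya_site_filter(d$polya_site_distance)), 0)
})

test_that("simulated read identity tracks one minus the substitution rate", {
  cfg <- sim_config(seed = 14, n_reads = 120, n_genes = 8,
                    substitution_rate = 0.13, frac_capped = 1,
                    frac_truncated = 0, frac_decoy = 0, frac_degradation = 0)
  ref <- make_reference(cfg)
  sim <- simulate_reads(cfg, ref)
  mism <- vapply(seq_len(nrow(sim$truth)), function(i) {
    expected <- reconstruct_capped(sim$truth[i, ], ref, cfg)
    got <- u_to_t(sim$reads$sequence[i])
    stopifnot(nchar(expected) == nchar(got))
    a <- strsplit(expected, "")[[1]]
    b <- strsplit(got, "")[[1]]
    c(sum(a != b), length(a))
  }, numeric(2))
  identity <- 1 - sum(mism[1, ]) / sum(mism[2, ])
  expect_equal(identity, 1 - cfg$substitution_rate, tolerance = 0.01 / 0.87)
})
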