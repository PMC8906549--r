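test_that("poly(A)-site distance uses the gene-frame sign convention", {
  sites <- tibble::tibble(chrom = "chr1", strand = c("+", "-"),
                          pos = c(1000L, 5000L))
  d <- function(strand, tp) {
    aln <- toy_alignment("r", "chr1", strand, 1L)
    aln$three_prime_pos <- as.integer(tp)
    polya_site_distance(aln, sites)$polya_site_distance
  }
  expect_equal(d("+", 1000L), 0L) # exactly at a site
  expect_equal(d("+", 940L), -60L) # upstream = internal = negative
  expect_equal(d("-", 5010L), -10L) # genomically right of a minus site = internal
  expect_equal(d("-", 4990L), 10L) # genomically left = downstream
  # no same-strand site on the chromosome -> NA
  aln <- toy_alignment("r", "chr9", "+", 1L)
  res <- polya_site_distance(aln, sites)
  expect_true(is.na(res$polya_site_distance))
})

test_that("poly(A)-site window is inclusive at -60 and +10", {
  expect_equal(polya_site_filter(c(-60L, -61L, 0L, 10L, 11L, NA)),
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("full-length call for untreated reads uses inclusive 25/50 windows", {
  ann <- toy_annotation("chr1", "+", 1000L, tes = 2000L)
  fl <- function(p5, p3) {
    aln <- toy_alignment("r", "chr1", "+", as.integer(p5))
    aln$three_prime_pos <- as.integer(p3)
    full_length_untreated(aln, ann)
  }
  expect_true(fl(1000, 2000)) # exact match
  expect_false(fl(1026, 2000)) # 5' offset 26 fails
  expect_true(fl(1025, 2050)) # 25/50 boundaries inclusive
  expect_false(fl(1000, 2051))
})

test_that("gene-type composition is normalized to 1 over assigned reads", {
  ann <- toy_annotation(
    rep("chr1", 2), rep("+", 2), c(1000L, 9000L),
    gene_type = c("protein_coding", "Mt_rRNA")
  )
  aln <- toy_alignment(sprintf("r%d", 1:4), "chr1", "+",
                       c(1000L, 1010L, 990L, 9000L))
  comp <- classify_gene_type(aln, ann)
  expect_equal(comp$fraction[comp$gene_type == "protein_coding"], 0.75)
  expect_equal(comp$fraction[comp$gene_type == "Mt_rRNA"], 0.25)
  expect_equal(sum(comp$fraction), 1)
  empty <- classify_gene_type(aln[0, ], ann)
  expect_equal(nrow(empty), 0L)
})

test_that("CPM normalizes to a million and rank correlation hits the closed forms", {
  one <- gene_counts_cpm(tibble::tibble(gene_id = rep("G1", 5)))
  expect_equal(one$cpm, 1e6)
  a <- tibble::tibble(gene_id = c("G1", "G2", "G3"), count = c(1L, 5L, 20L),
                      cpm = c(1, 5, 20) * 1e6 / 26)
  expect_equal(correlate_cpm(a, a), 1)
  b <- a
  b$cpm <- rev(a$cpm)
  expect_equal(correlate_cpm(a, b), -1) # anti-ordered
  # gene absent from one table counts as zero there
  c_tbl <- gene_counts_cpm(tibble::tibble(gene_id = c("G1", "G4")))
  expect_lt(correlate_cpm(a, c_tbl), 1)
})

test_that("MAPQ summary reports Q0/Q60 fractions and a full histogram", {
  s <- mapq_summary(c(60L, 60L, 0L, 30L))
  expect_equal(s$frac_q60, 0.5)
  expect_equal(s$frac_q0, 0.25)
  expect_equal(sum(s$histogram$n), 4L)
  expect_equal(s$histogram$n[s$histogram$mapq == 30], 1L)
  all60 <- mapq_summary(rep(60L, 7))
  expect_equal(all60$frac_q60, 1)
})

make_cascade_fixture <- function() {
  # five reads spanning the cascade outcomes on a one-gene annotation
  ann <- toy_annotation("chr1", "+", 1000L, tes = 3000L)
  sites <- tibble::tibble(chrom = "chr1", strand = "+", pos = 3000L)
  ids <- c("full", "degraded", "no_tail", "clipped", "lowq")
  reads <- tibble::tibble(
    read_id = ids, sequence = strrep("A", 50),
    qualities = strrep("I", 50), mean_q = c(12, 12, 12, 12, 3)
  )
  calls <- tibble::tibble(
    read_id = ids, detected = TRUE, identity_pct = 100,
    match_start = 0L, match_end = 45L, trimmed_length = 400L
  )
  aln <- toy_alignment(ids, "chr1", "+", 1000L,
                       five_prime_clip = c(0L, 0L, 0L, 20L, 0L))
  aln$three_prime_pos <- c(3000L, 2800L, 3000L, 3000L, 3000L)
  polya <- tibble::tibble(
    read_id = c("full", "degraded", "clipped", "lowq"),
    tail_length = 50, qc_tag = "PASS"
  )
  list(ann = ann, sites = sites, reads = reads, calls = calls, aln = aln,
       polya = polya, ids = ids)
}

test_that("the cascade applies stages in order and derives full-length correctly", {
  fx <- make_cascade_fixture()
  sc <- call_scaffolds(fx$reads, fx$calls, confirmed_ids = fx$ids, fx$aln,
                       fx$polya, fx$sites, fx$ann)
  calls <- sc$calls
  expect_equal(calls$is_full_length,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # degradation-tailed read passes the tail filter but fails the site window
  degr <- calls[calls$read_id == "degraded", ]
  expect_true(degr$polya_tail_pass)
  expect_false(degr$polya_site_pass)
  expect_equal(degr$polya_site_distance, -200L)
  # read without a tail-table entry fails the tail filter (closed world)
  expect_false(calls$polya_tail_pass[calls$read_id == "no_tail"])
  # funnel is monotone and its percentages recompute from counts
  funnel <- tidy(sc)
  expect_true(all(diff(funnel$n) <= 0))
  expect_equal(funnel$pct_of_input, 100 * funnel$n / funnel$n[1])
  expect_equal(funnel$pct_of_previous[-1],
               100 * funnel$n[-1] / head(funnel$n, -1))
  g <- glance(sc)
  expect_equal(g$n_full_length, 1L)
})

test_that("with permissive filters the scaffold set equals the quality-pass set", {
  fx <- make_cascade_fixture()
  permissive_polya <- tibble::tibble(read_id = fx$ids, tail_length = 50,
                                     qc_tag = "PASS")
  aln <- fx$aln
  aln$five_prime_clip <- 0L
  sc <- call_scaffolds(fx$reads, fx$calls, confirmed_ids = fx$ids, aln,
                       permissive_polya, fx$sites, fx$ann,
                       clip_remove_at = 1000L,
                       polya_window = c(-1e6, 1e6))
  expect_equal(sc$calls$is_full_length, fx$reads$mean_q >= 7)
})

test_that("novel-TSS scaffolds are the intersection with full-length calls", {
  fx <- make_cascade_fixture()
  clusters <- tibble::tibble(
    cluster_id = "c1", chrom = "chr1", strand = "+",
    representative_pos = 1000L, size = 2L,
    read_ids = list(c("full", "no_tail"))
  )
  sc <- call_scaffolds(fx$reads, fx$calls, confirmed_ids = fx$ids, fx$aln,
                       fx$polya, fx$sites, fx$ann, novel_clusters = clusters)
  expect_equal(sc$calls$read_id[sc$calls$is_novel_tss], "full")
  # is_novel_tss implies is_full_length
  expect_true(all(!sc$calls$is_novel_tss | sc$calls$is_full_length))
})
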