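test_that("closest TSS distance follows the upstream/downstream sign convention", {
  ann <- toy_annotation(c("chr1", "chr1"), c("+", "-"), c(1000L, 5000L))
  # read 5' end exactly at an annotated TSS
  expect_equal(
    closest_tss_distance(toy_alignment("a", "chr1", "+", 1000L), ann)$signed_distance,
    0L
  )
  # plus strand, 40 nt left of the TSS = upstream
  expect_equal(
    closest_tss_distance(toy_alignment("b", "chr1", "+", 960L), ann)$signed_distance,
    -40L
  )
  # minus strand, 40 nt genomically left of a minus TSS = downstream
  expect_equal(
    closest_tss_distance(toy_alignment("c", "chr1", "-", 4960L), ann)$signed_distance,
    40L
  )
  # chromosome absent from the annotation -> flagged
  res <- closest_tss_distance(toy_alignment("d", "chrX", "+", 10L), ann)
  expect_true(res$flagged)
  expect_true(is.na(res$signed_distance))
})

test_that("closest TSS distance equals a brute-force scan on fuzzed annotations", {
  set.seed(41)
  for (rep_i in 1:5) {
    n_tx <- sample(5:100, 1)
    ann <- toy_annotation(
      sample(c("chr1", "chr2"), n_tx, replace = TRUE),
      sample(c("+", "-"), n_tx, replace = TRUE),
      sample.int(50000L, n_tx)
    )
    n_reads <- 40
    aln <- toy_alignment(
      sprintf("r%d", seq_len(n_reads)),
      sample(c("chr1", "chr2"), n_reads, replace = TRUE),
      sample(c("+", "-"), n_reads, replace = TRUE),
      sample.int(50000L, n_reads)
    )
    got <- closest_tss_distance(aln, ann)
    for (i in seq_len(n_reads)) {
      cand <- ann[ann$chrom == aln$chrom[i] & ann$strand == aln$strand[i], ]
      if (nrow(cand) == 0) {
        expect_true(is.na(got$signed_distance[i]))
        next
      }
      d <- if (aln$strand[i] == "+") aln$five_prime_pos[i] - cand$tss
           else cand$tss - aln$five_prime_pos[i]
      expect_equal(abs(got$signed_distance[i]), min(abs(d)))
      expect_true(got$signed_distance[i] %in% d[abs(d) == min(abs(d))])
    }
  }
})

test_that("distance CDF counts |d| within the window as a fraction of reads", {
  res <- distance_cdf(c(0L, 10L, -500L), window = 300)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(distance_cdf(rep(0L, 5))$fraction, 1)
  cdf <- res$cdf
  expect_equal(cdf$cum_frac[cdf$distance == 10], 1) # all reads at or below 10
  expect_equal(cdf$cum_frac[cdf$distance == -500], 1 / 3)
})

test_that("novel TSS clustering honours distance, linkage and support rules", {
  ann <- toy_annotation("chr1", "+", 10000L)
  mk <- function(ids, pos) toy_alignment(ids, "chr1", "+", as.integer(pos))
  # two reads 400 nt upstream, 50 nt apart -> one cluster of two
  cl <- find_novel_tss(mk(c("a", "b"), c(9600, 9650) - 50), ann)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 2L)
  expect_equal(cl$representative_pos, 9550L) # 5'-most member
  # one isolated read far away -> no cluster
  expect_equal(nrow(find_novel_tss(mk("a", 9600), ann)), 0L)
  # two reads 51 nt apart -> no cluster
  expect_equal(nrow(find_novel_tss(mk(c("a", "b"), c(9500, 9551)), ann)), 0L)
  # reads at the distance gate: 300 retained (>=300), 299 excluded
  expect_equal(nrow(find_novel_tss(mk(c("a", "b"), c(9700, 9700)), ann)), 1L)
  expect_equal(nrow(find_novel_tss(mk(c("a", "b"), c(9701, 9701)), ann)), 0L)
})

test_that("clustering is order independent and members satisfy the predicate", {
  set.seed(42)
  ann <- toy_annotation(c("chr1", "chr2"), c("+", "-"), c(2000L, 8000L))
  pos <- c(5000:5003, 5040, 5100, 12000, 12020, 700)
  aln <- toy_alignment(sprintf("r%d", seq_along(pos)), "chr1", "+", pos)
  base <- find_novel_tss(aln, ann)
  for (i in 1:5) {
    perm <- aln[sample(nrow(aln)), ]
    got <- find_novel_tss(perm, ann)
    expect_equal(got$representative_pos, base$representative_pos)
    expect_equal(got$size, base$size)
    expect_equal(lapply(got$read_ids, sort), lapply(base$read_ids, sort))
  }
  # every member of every cluster is individually >= 300 from any TSS
  dist <- closest_tss_distance(aln, ann)
  for (k in seq_len(nrow(base))) {
    member_d <- dist$signed_distance[dist$read_id %in% base$read_ids[[k]]]
    expect_true(all(abs(member_d) >= 300))
  }
})

test_that("5' end merging collapses positions within the window to 5'-most reps", {
  ends <- tibble::tibble(chrom = "chr1", strand = "+",
                         pos = c(100L, 120L, 160L))
  expect_equal(merge_five_prime_ends(ends, window = 25)$pos, c(100L, 160L))
  expect_equal(merge_five_prime_ends(ends[1, ])$pos, 100L)
  dup <- tibble::tibble(chrom = "chr1", strand = "+", pos = rep(100L, 3))
  merged <- merge_five_prime_ends(dup)
  expect_equal(merged$pos, 100L)
  expect_equal(merged$n_members, 3L)
  # minus strand: the 5'-most member is the largest coordinate
  minus <- tibble::tibble(chrom = "chr1", strand = "-", pos = c(100L, 110L))
  expect_equal(merge_five_prime_ends(minus)$pos, 110L)
})

test_that("marker overlap respects half-open bounds, slop and empty markers", {
  ends <- tibble::tibble(chrom = "chr1", strand = "+",
                         pos = c(150L, 99L, 200L))
  markers <- tibble::tibble(chrom = "chr1", strand = "+",
                            start = 100L, end = 200L, marker = "cage")
  res <- marker_overlap(ends, markers)
  expect_equal(res$ends$cage, c(TRUE, FALSE, FALSE)) # 200 is outside [100,200)
  expect_equal(res$summary$fraction[res$summary$marker == "cage"], 1 / 3)
  # 1 nt outside with slop 1 overlaps
  res1 <- marker_overlap(ends, markers, slop = 1)
  expect_equal(res1$ends$cage, c(TRUE, TRUE, TRUE))
  # no markers -> fraction 0
  none <- marker_overlap(ends, markers[0, ])
  expect_equal(none$summary$fraction[none$summary$marker == "union"], 0)
})

test_that("reference-point matrices sample signal strand-orientedly", {
  pts <- tibble::tibble(chrom = "chr1", strand = c("+", "-"),
                        pos = c(500L, 800L))
  uniform <- tibble::tibble(chrom = "chr1", start = 0L, end = 5000L, score = 1)
  m <- marker_matrix(pts, uniform, flank = 10, merge_window = 0)
  expect_equal(dim(m), c(2L, 21L))
  expect_true(all(m == 1))
  # signal only at the reference point itself -> single nonzero column
  point <- tibble::tibble(chrom = "chr1", start = 500L, end = 501L, score = 7)
  m2 <- marker_matrix(pts[1, ], point, flank = 10, merge_window = 0)
  expect_equal(unname(m2[1, "0"]), 7)
  expect_equal(sum(m2 != 0), 1L)
  # strand orientation: signal 5 nt genomically left of a minus-strand point
  # appears at +5 (downstream in the gene frame)
  left <- tibble::tibble(chrom = "chr1", start = 795L, end = 796L, score = 3)
  m3 <- marker_matrix(pts[2, ], left, flank = 10, merge_window = 0)
  expect_equal(unname(m3[1, "5"]), 3)
  # downsampling larger than available rows keeps everything
  m4 <- marker_matrix(pts, uniform, flank = 5, downsample_n = 10,
                      merge_window = 0, seed = 3)
  expect_equal(nrow(m4), 2L)
  # seeded downsampling is deterministic
  many <- tibble::tibble(chrom = "chr1", strand = "+",
                         pos = seq(0L, 40000L, by = 200L))
  m5 <- marker_matrix(many, uniform, flank = 5, downsample_n = 20,
                      merge_window = 0, seed = 9)
  m6 <- marker_matrix(many, uniform, flank = 5, downsample_n = 20,
                      merge_window = 0, seed = 9)
  expect_identical(rownames(m5), rownames(m6))
  expect_equal(nrow(m5), 20L)
})
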