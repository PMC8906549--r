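# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written against the same contracts but with
# a different algorithmic layout (packed lexicographic keys instead of
# struct cells; full CIGAR expansion instead of run parsing).

# Exhaustive semi-global DP for barcode-in-read alignment. Lexicographic
# objective (score desc, match_start asc, matches desc, insertions asc) is
# packed into one additive numeric key:
#   key = score*2^17 + (63 - start)*2^11 + matches*2^6 + (63 - ins)
# so taking max() of candidate keys realises the tie-break order, and every
# transition is a constant key increment. Gap of length L costs
# open + (L-1)*extend.
oracle_semiglobal <- function(read, barcode, match = 3, mismatch = -6,
                              gap_open = -5, gap_extend = -2, window = 150) {
  s <- strsplit(toupper(substr(read, 1, window)), "")[[1]]
  b <- strsplit(toupper(barcode), "")[[1]]
  n <- length(s)
  m <- length(b)
  stopifnot(n <= 63, m <= 31) # bit budget of the packed key
  SC <- 2^17
  ST <- 2^11
  MA <- 2^6
  NEG <- -Inf
  # j index 1..n+1 represents read offset 0..n
  Mrow <- 0 * SC + (63 - (0:n)) * ST + 0 * MA + 63
  Drow <- rep(NEG, n + 1)
  Irow <- rep(NEG, n + 1)
  for (i in seq_len(m)) {
    Mnew <- rep(NEG, n + 1)
    Dnew <- rep(NEG, n + 1)
    Inew <- rep(NEG, n + 1)
    # D: consume barcode char against a read gap (same column)
    Dnew <- pmax(Mrow + gap_open * SC, Drow + gap_extend * SC,
                 Irow + gap_open * SC)
    if (n >= 1) {
      sub <- ifelse(b[i] == s, match, mismatch)
      dm <- ifelse(b[i] == s, 1, 0)
      diag_best <- pmax(Mrow[1:n], Drow[1:n], Irow[1:n])
      Mnew[2:(n + 1)] <- diag_best + sub * SC + dm * MA
      # I: consume read char against a barcode gap (running scan along j)
      for (j in 2:(n + 1)) {
        Inew[j] <- max(Mnew[j - 1] + gap_open * SC - 1,
                       Dnew[j - 1] + gap_open * SC - 1,
                       Inew[j - 1] + gap_extend * SC - 1)
      }
    }
    Mrow <- Mnew
    Drow <- Dnew
    Irow <- Inew
  }
  final <- pmax(Mrow, Drow)
  jbest <- which.max(final) # first max: smallest end offset on ties
  key <- final[jbest] + 4096 * SC # shift score positive for decoding
  ins <- 63 - (key %% 64)
  key <- key %/% 64
  matches <- key %% 32
  key <- key %/% 32
  start <- 63 - (key %% 64)
  score <- key %/% 64 - 4096
  list(
    identity_pct = 100 * matches / (m + ins),
    match_start = as.integer(start),
    match_end = as.integer(jbest - 1),
    score = as.integer(score),
    n_match = as.integer(matches)
  )
}

# Brute-force 5' clip: expand the CIGAR base by base and count the clip run
# at the strand-appropriate end.
oracle_five_prime_clip <- function(cigar, strand) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", m))
  ops <- sub("^[0-9]+", "", m)
  expanded <- rep(ops, lens)
  if (strand == "-") expanded <- rev(expanded)
  run <- 0L
  for (op in expanded) {
    if (op %in% c("S", "H")) run <- run + 1L else break
  }
  run
}

# Random CIGAR strings for fuzzing (always at least one aligned op).
random_cigar <- function() {
  n_ops <- sample(1:8, 1)
  ops <- sample(c("M", "I", "D", "N", "S", "H"), n_ops, replace = TRUE)
  ops[sample(n_ops, 1)] <- "M"
  lens <- sample(1:40, n_ops, replace = TRUE)
  paste0(paste0(lens, ops), collapse = "")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Minimal transcript annotation tibble for constructed test cases.
toy_annotation <- function(chrom, strand, tss, tes = tss + 500L,
                           gene_type = "protein_coding",
                           gene_id = sprintf("G%03d", seq_along(tss))) {
  tibble::tibble(
    transcript_id = paste0(gene_id, ".T1"),
    gene_id = gene_id,
    gene_name = gene_id,
    gene_type = gene_type,
    chrom = chrom,
    strand = strand,
    tss = as.integer(tss),
    tes = as.integer(tes)
  )
}

# Minimal primary-alignment tibble with derived end fields.
toy_alignment <- function(read_id, chrom, strand, five_prime_pos,
                          three_prime_pos = five_prime_pos + 400L,
                          five_prime_clip = 0L, mapq = 60L, flag = 0L) {
  tibble::tibble(
    read_id = read_id, flag = flag, chrom = chrom, strand = strand,
    ref_start = pmin(five_prime_pos, three_prime_pos),
    ref_end = pmax(five_prime_pos, three_prime_pos) + 1L,
    cigar = "100M", mapq = mapq,
    five_prime_clip = as.integer(five_prime_clip),
    five_prime_pos = as.integer(five_prime_pos),
    three_prime_pos = as.integer(three_prime_pos)
  )
}
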