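rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

mutate_at <- function(s, pos) {
  for (p in pos) {
    b <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  s
}

test_that("the seed index maps k-mers to their occurrence lists", {
  s <- rand_dna(1000, 61)
  idx <- build_index(toy_reference(c(chr1 = s)), seed_length = 32)
  expect_equal(nrow(idx$table), 1000 - 32 + 1)
  expect_true(all(table(idx$table$seed) == 1))

  # exact duplicate chromosome: every seed occurs twice
  idx2 <- build_index(toy_reference(c(chr1 = s, chr2 = s)), 32)
  expect_true(all(table(idx2$table$seed) == 2))

  # all-N chromosome contributes nothing
  idx3 <- build_index(toy_reference(c(chr1 = strrep("N", 500))), 32)
  expect_equal(nrow(idx3$table), 0L)
})

test_that("map_read follows the unique/repeat/unaligned contract", {
  s <- rand_dna(3000, 62)
  ref <- toy_reference(c(chr1 = s))
  idx <- build_index(ref, 32)
  params <- align_params()

  r <- map_read(substr(s, 501, 600), idx, params)
  expect_identical(r$category, "unique")
  expect_equal(r$pos, 501L)
  expect_equal(r$nm, 0L)

  # 6 mismatches exceed the -v 5 bound
  set.seed(63)
  r6 <- map_read(mutate_at(substr(s, 501, 600), c(5, 20, 40, 60, 80, 95)),
                 idx, params)
  expect_identical(r6$category, "unaligned")

  # short read
  expect_identical(map_read("ACGTACGT", idx, params)$category, "unaligned")

  # reverse-orientation read maps to the same locus
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 501, 600))))
  rr <- map_read(rc, idx, params)
  expect_identical(rr$category, "unique")
  expect_equal(rr$pos, 501L)
  expect_identical(rr$strand, "-")
})

test_that("a strictly better score wins over the other homoeolog", {
  a <- rand_dna(2000, 64)
  set.seed(65)
  cc <- mutate_at(a, sample(2000, 3))   # a near-identical homoeolog
  ref <- toy_reference(c(A01 = a, C01 = cc))
  idx <- build_index(ref, 32)
  # read from A01 spanning at least one divergent base: 0 mm on A01,
  # >=1 mm on C01 -> unique to A01
  div <- which(strsplit(a, "")[[1]] != strsplit(cc, "")[[1]])
  p <- max(1, div[1] - 50)
  r <- map_read(substr(a, p, p + 99), idx)
  expect_identical(r$category, "unique")
  expect_identical(r$chrom, "A01")
  # read from an identical region is a repeat (tie)
  far <- setdiff(seq(1, 1900), unlist(lapply(div, function(d) (d - 100):d)))
  q <- far[1]
  r2 <- map_read(substr(a, q, q + 99), idx)
  expect_identical(r2$category, "repeat")
})

check_against_oracle <- function(reads, ref, what) {
  masked <- apply_mask(ref, data.table::data.table(chrom = character(),
                                                   start = integer(),
                                                   end = integer()))
  idx <- build_index(masked, 32)
  params <- align_params()
  rs <- Biostrings::DNAStringSet(reads)
  names(rs) <- paste0("r", seq_along(rs))
  bulk <- map_reads(rs, masked, params)
  for (i in seq_along(reads)) {
    oracle <- brute_force_map(reads[i], ref$sequences, params$max_mismatches)
    expect_identical(bulk$category[i], oracle$category,
                     label = paste(what, "read", i, "bulk category"))
    single <- map_read(reads[i], idx, params)
    expect_identical(single$category, oracle$category,
                     label = paste(what, "read", i, "single category"))
    if (oracle$category == "unique") {
      expect_equal(bulk$pos[i], oracle$pos)
      expect_identical(bulk$chrom[i], oracle$chrom)
      expect_equal(bulk$nm[i], oracle$nm)
      expect_equal(single$pos, oracle$pos)
    }
  }
  invisible(bulk)
}

test_that("mapping matches the brute-force Hamming oracle", {
  # regime 1: unique genome, 0-6 mutations confined to the read middle
  # (an intact end seed always exists, so seed-and-extend is exhaustive)
  s <- rand_dna(4000, 66)
  set.seed(67)
  reads1 <- vapply(1:60, function(i) {
    p <- sample(3900, 1)
    rd <- substr(s, p, p + 99)
    n_mut <- sample(0:6, 1)
    if (n_mut > 0) rd <- mutate_at(rd, sample(33:68, n_mut))
    if (runif(1) < 0.5)
      rd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd)))
    rd
  }, character(1))
  check_against_oracle(reads1, toy_reference(c(chr1 = s)), "unique-genome")

  # regime 2: exact duplicate chromosomes (ties everywhere)
  d <- rand_dna(1500, 71)
  set.seed(72)
  reads2 <- vapply(1:25, function(i) {
    p <- sample(1400, 1)
    rd <- substr(d, p, p + 99)
    n_mut <- sample(0:4, 1)
    if (n_mut > 0) rd <- mutate_at(rd, sample(33:68, n_mut))
    rd
  }, character(1))
  check_against_oracle(reads2, toy_reference(c(chr1 = d, chr2 = d)),
                       "duplicate-genome")

  # regime 3: error-free reads from 3%-diverged homoeologs: a divergent
  # base in the span wins the read for its own subgenome; an identical
  # span is a conservative repeat tie
  a <- rand_dna(2000, 73)
  set.seed(74)
  cc <- mutate_at(a, sample(2000, 60))
  set.seed(75)
  reads3 <- vapply(1:50, function(i) {
    src <- if (runif(1) < 0.5) a else cc
    p <- sample(1900, 1)
    rd <- substr(src, p, p + 99)
    if (runif(1) < 0.5)
      rd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd)))
    rd
  }, character(1))
  bulk <- check_against_oracle(reads3, toy_reference(c(A01 = a, C01 = cc)),
                               "homoeolog-genome")
  expect_true(any(bulk$category == "unique"))

  # read order does not change the outcome
  masked <- apply_mask(toy_reference(c(A01 = a, C01 = cc)),
                       data.table::data.table(chrom = character(),
                                              start = integer(),
                                              end = integer()))
  rs <- Biostrings::DNAStringSet(reads3)
  names(rs) <- paste0("r", seq_along(rs))
  perm <- rev(seq_along(rs))
  bulk2 <- map_reads(rs[perm], masked)
  expect_identical(bulk2$category, bulk$category[perm])
  expect_identical(bulk2$pos, bulk$pos[perm])
})

test_that("category tallies conserve the read count", {
  s <- rand_dna(3000, 69)
  ref <- toy_reference(c(chr1 = s, chr2 = s))  # all-duplicate genome
  masked <- apply_mask(ref, data.table::data.table(chrom = character(),
                                                   start = integer(),
                                                   end = integer()))
  starts <- seq(1, 2900, by = 100)
  rs <- Biostrings::DNAStringSet(substring(s, starts, starts + 99))
  names(rs) <- paste0("r", seq_along(rs))
  aln <- map_reads(rs, masked)
  cc <- classify_counts(aln)
  expect_equal(sum(cc$tally), length(rs))
  # every read sits on duplicated sequence: all repeat
  expect_equal(cc$tally[["repeat"]], length(rs))
  expect_equal(cc$unique_fraction, 0)
})

test_that("minimal SAM output round-trips through samtools-compatible BAM", {
  s <- rand_dna(2000, 70)
  ref <- toy_reference(c(chr1 = s))
  masked <- apply_mask(ref, data.table::data.table(chrom = character(),
                                                   start = integer(),
                                                   end = integer()))
  starts <- c(11L, 501L, 1001L)
  rs <- Biostrings::DNAStringSet(substring(s, starts, starts + 99))
  names(rs) <- paste0("r", seq_along(rs))
  aln <- map_reads(rs, masked)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, rs, masked, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  got <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(sort(got$pos), starts)
  expect_true(all(got$cigar == "100M"))
  file.remove(sam)
})
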