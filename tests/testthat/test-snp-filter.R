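cnt <- function(A = 0L, C = 0L, G = 0L, T = 0L)
  c(A = A, C = C, G = G, T = T)

test_that("per-line genotype calling follows the depth and het rules", {
  thr <- filter_thresholds()
  expect_identical(call_genotype(cnt(A = 10), thr)$status, "called")
  expect_identical(call_genotype(cnt(A = 10), thr)$allele, "A")
  expect_identical(call_genotype(cnt(A = 3), thr)$status,
                   "missing_low_depth")
  g <- call_genotype(cnt(A = 6, G = 4), thr)
  expect_identical(g$status, "heterozygous")     # 4 >= 2 and 0.4 >= 0.1
  # a single sequencing error at depth >= 4 never triggers heterozygosity
  expect_identical(call_genotype(cnt(A = 3, G = 1), thr)$status, "called")
  expect_identical(call_genotype(cnt(A = 19, G = 1), thr)$status, "called")
  # an exact tie is conservatively heterozygous
  expect_identical(call_genotype(cnt(A = 5, G = 5), thr)$status,
                   "heterozygous")
  # two errors at high depth stay below the fraction bound
  expect_identical(call_genotype(cnt(A = 30, G = 2), thr)$status, "called")
})

test_that("site filtering applies the cascade rules in order", {
  thr <- filter_thresholds()
  mk <- function(...) {
    alleles <- c(...)
    data.frame(status = ifelse(is.na(alleles), "missing_low_depth",
                               ifelse(alleles == "HET", "heterozygous",
                                      "called")),
               allele = ifelse(is.na(alleles) | alleles == "HET",
                               NA_character_, alleles))
  }
  v <- filter_site(mk(rep("A", 5), rep("G", 5)), thr)
  expect_identical(v$status, "accepted")
  expect_identical(v$allelism, "biallelic")

  v <- filter_site(mk(rep("A", 9), "G"), thr)
  expect_identical(v$reason, "maf")

  v <- filter_site(mk(rep("A", 4), rep("G", 3), rep("T", 3)), thr)
  expect_identical(v$status, "accepted")
  expect_identical(v$allelism, "triallelic")

  v <- filter_site(mk(rep("A", 5), rep("G", 4), "HET"), thr)
  expect_identical(v$reason, "heterozygous_line")

  v <- filter_site(mk(rep(NA, 10)), thr)
  expect_identical(v$reason, "low_depth")

  v <- filter_site(mk(rep("A", 10)), thr)
  expect_identical(v$reason, "monomorphic")

  v <- filter_site(mk(rep("A", 3), rep("C", 3), rep("G", 2), rep("T", 2)),
                   thr)
  expect_identical(v$reason, "excess_alleles")
})

test_that("the vectorized cascade equals the brute-force site oracle", {
  set.seed(101)
  n_sites <- 1000L
  n_acc <- 10L
  rows <- list()
  for (s in seq_len(n_sites)) {
    # random depth profiles spanning the interesting regimes
    for (a in seq_len(n_acc)) {
      depth <- sample(0:20, 1L)
      if (depth == 0L) next
      major <- sample(c("A", "C", "G", "T"), 1L)
      minor <- sample(setdiff(c("A", "C", "G", "T"), major), 1L)
      n_minor <- stats::rbinom(1L, depth, sample(c(0, 0.05, 0.3, 0.5), 1L))
      counts <- integer(4L); names(counts) <- c("A", "C", "G", "T")
      counts[major] <- depth - n_minor
      counts[minor] <- counts[minor] + n_minor
      for (b in names(counts)[counts > 0L])
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = "chr1", pos = s, ref = "A", acc = sprintf("acc%02d", a),
          base = b, count = counts[[b]])
    }
  }
  cand <- data.table::rbindlist(rows)
  callset <- run_cascade(cand, filter_thresholds())

  for (s in unique(cand$pos)) {
    sub <- cand[cand$pos == s, ]
    m <- matrix(0L, nrow = length(unique(sub$acc)), ncol = 4L,
                dimnames = list(unique(sub$acc), c("A", "C", "G", "T")))
    for (i in seq_len(nrow(sub))) m[sub$acc[i], sub$base[i]] <- sub$count[i]
    oracle <- oracle_filter_column(m)
    got <- callset$sites[callset$sites$pos == s, ]
    expect_identical(got$status, oracle$status,
                     label = paste("site", s, "status"))
    if (oracle$status == "rejected")
      expect_identical(got$reason, oracle$reason,
                       label = paste("site", s, "reason"))
    else
      expect_identical(got$allelism, oracle$allelism,
                       label = paste("site", s, "allelism"))
  }

  # cascade bookkeeping: step counts plus accepted equal the candidates
  expect_equal(sum(callset$report$sites), nrow(callset$sites))
})

test_that("cascade output does not depend on accession ordering", {
  set.seed(102)
  rows <- list()
  for (s in 1:50) for (a in 1:6) {
    b <- sample(c("A", "G"), 1L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = "c", pos = s, ref = "A", acc = sprintf("acc%02d", a),
      base = b, count = sample(3:12, 1L))
  }
  cand <- data.table::rbindlist(rows)
  r1 <- run_cascade(cand)
  r2 <- run_cascade(cand[rev(seq_len(nrow(cand)))])
  data.table::setkey(r1$sites, chrom, pos)
  data.table::setkey(r2$sites, chrom, pos)
  expect_identical(r1$sites$status, r2$sites$status)
  expect_identical(r1$sites$reason, r2$sites$reason)
})

test_that("pileups separate accessions and respect strand orientation", {
  set.seed(55)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  ref <- toy_reference(c(chr1 = s))
  masked <- apply_mask(ref, data.table::data.table(chrom = character(),
                                                   start = integer(),
                                                   end = integer()))
  rd1 <- Biostrings::DNAStringSet(substr(s, 101, 200))
  names(rd1) <- "a"
  rd2 <- Biostrings::DNAStringSet(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(substr(s, 101,
                                                               200)))))
  names(rd2) <- "b"
  a1 <- map_reads(rd1, masked)
  a2 <- map_reads(rd2, masked)
  pile <- pileup_columns(list(acc01 = a1, acc02 = a2),
                         list(acc01 = rd1, acc02 = rd2), masked)
  expect_setequal(unique(pile$acc), c("acc01", "acc02"))
  # both reads cover 101..200 with identical reference-oriented bases
  for (a in c("acc01", "acc02")) {
    sub <- pile[pile$acc == a, ]
    expect_equal(sort(sub$pos), 101:200)
    expect_true(all(sub$count == 1L))
    expect_identical(
      sub$base[order(sub$pos)],
      strsplit(substr(s, 101, 200), "")[[1]])
  }
})

test_that("validation counts give the stated false positive rate", {
  expect_equal(validation_fpr(100, 93), 0.07)
  expect_equal(validation_fpr(50, 50), 0)
  expect_equal(validation_fpr(8, 6), 0.25)
  expect_error(validation_fpr(0, 0), "positive")
  expect_error(validation_fpr(10, 11))
})

test_that("VCF export writes valid records for accepted and rejected sites", {
  set.seed(103)
  rows <- list()
  for (a in 1:6) {
    b <- if (a <= 3) "A" else "G"
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = "chr1", pos = 42L, ref = "A", acc = sprintf("acc%02d", a),
      base = b, count = 10L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = "chr1", pos = 99L, ref = "C", acc = sprintf("acc%02d", a),
      base = if (a == 1L) "T" else "C", count = 10L)
  }
  callset <- run_cascade(data.table::rbindlist(rows))
  f <- tempfile(fileext = ".vcf")
  write_vcf(callset, f, include_rejected = TRUE)
  txt <- readLines(f)
  body <- txt[!startsWith(txt, "#")]
  expect_equal(length(body), 2L)
  rec <- strsplit(body, "\t")
  pass <- rec[[which(vapply(rec, `[[`, character(1), 2L) == "42")]]
  expect_identical(pass[7], "PASS")
  expect_identical(pass[4], "A")
  expect_identical(pass[5], "G")
  expect_true(all(pass[9:11] == "0/0"))
  expect_true(all(pass[12:14] == "1/1"))
  rej <- rec[[which(vapply(rec, `[[`, character(1), 2L) == "99")]]
  expect_identical(rej[7], "maf")
  file.remove(f)
})
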