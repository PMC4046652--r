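test_that("substitution classes follow the purine/pyrimidine definition", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("G", "A"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("T", "C"), "transition")
  for (pair in list(c("C", "A"), c("A", "T"), c("G", "T"), c("C", "G"),
                    c("A", "C"), c("G", "C"))) {
    expect_identical(classify_substitution(pair[1], pair[2]), "transversion")
    expect_identical(classify_substitution(pair[2], pair[1]), "transversion")
  }
  expect_error(classify_substitution("A", "A"), "identical")
})

test_that("printed class shares imply the published Ts/Tv ratio", {
  expect_equal(tstv_ratio_from_shares(57.5, 42.5), 1.35)
})

test_that("AS-PCR suitability uses the +/-3 reference-strand context", {
  expect_true(aspcr_suitable("A", "T", "G", "A"))   # upstream G qualifies
  expect_true(aspcr_suitable("T", "A", "T", "G"))   # upstream T qualifies
  expect_true(aspcr_suitable("A", "T", "C", "C"))   # downstream C qualifies
  expect_false(aspcr_suitable("A", "T", "C", "G"))  # neither side qualifies
  expect_false(aspcr_suitable("C", "T", "G", "A"))  # not an A/T SNP
  expect_warning(v <- aspcr_suitable("A", "T", NA, NA), "truncated")
  expect_false(v)
})

make_gene_fixture <- function() {
  # plus-strand gene at 101..115: ATG TGG GAA TAC TAA
  # minus-strand gene at 301..315: genomic revcomp of ATG CAT CCA GTC TAA
  set.seed(121)
  chars <- sample(c("A", "C", "G", "T"), 500, TRUE)
  plus_cds <- "ATGTGGGAATACTAA"
  minus_cds <- "ATGCATCCAGTCTAA"
  chars[101:115] <- strsplit(plus_cds, "")[[1]]
  chars[301:315] <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(minus_cds))), "")[[1]]
  ref <- toy_reference(c(chr1 = paste(chars, collapse = "")))
  gm <- structure(list(
    genes = data.table::data.table(
      gene_id = c("gplus", "gminus"), chrom = "chr1",
      start = c(101L, 301L), end = c(115L, 315L),
      strand = c("+", "-"), n_codons = 5L),
    cds = data.table::data.table(
      gene_id = c("gplus", "gminus"), chrom = "chr1",
      start = c(101L, 301L), end = c(115L, 315L),
      strand = c("+", "-"), exon_rank = 1L),
    go_map = data.table::data.table(gene_id = character(),
                                    go_id = character()),
    ontology = go_ontology()), class = "gene_models")
  list(ref = ref, gm = gm)
}

test_that("coding effects cover all four classes on both strands", {
  fx <- make_gene_fixture()
  # TGG -> TGA (codon 2, position 3): G at genomic 106 -> A, stop gained;
  # GAA -> CAA (codon 3, position 1, E -> Q); TAC -> TCC (codon 4,
  # position 2, Y -> S); TAA -> TAC (codon 5, position 3, stop lost)
  snps <- data.table::data.table(
    chrom = "chr1",
    pos = c(106L, 107L, 111L, 115L),
    ref = c("G", "G", "A", "A"),
    alt = c("A", "C", "C", "C"))
  eff <- coding_effect(snps, fx$gm, fx$ref)
  eff <- eff[order(eff$pos)]
  expect_identical(eff$class, c("stop_gain", "nonsynonymous",
                                "nonsynonymous", "stop_loss"))
  expect_equal(eff$codon_index, c(2L, 3L, 4L, 5L))
  expect_equal(eff$pos_in_codon, c(3L, 1L, 2L, 3L))
  expect_identical(eff$ref_codon[1], "TGG")
  expect_identical(eff$alt_codon[1], "TGA")

  # synonymous: GAA -> GAG, codon 3 position 3 (genomic 109 A -> G)
  syn <- coding_effect(data.table::data.table(chrom = "chr1", pos = 109L,
                                              ref = "A", alt = "G"),
                       fx$gm, fx$ref)
  expect_identical(syn$class, "synonymous")

  # minus strand: genomic 303 is position 1 of the terminal stop codon
  # read on the minus strand; A -> G complements into TAA -> CAA
  m <- coding_effect(data.table::data.table(chrom = "chr1", pos = 303L,
                                            ref = "A", alt = "G"),
                     fx$gm, fx$ref)
  expect_identical(m$gene_id, "gminus")
  expect_identical(m$strand, "-")
  expect_identical(m$class, "stop_loss")

  # noncoding SNP is absent from the output
  nc <- coding_effect(data.table::data.table(chrom = "chr1", pos = 50L,
                                             ref = "A", alt = "G"),
                      fx$gm, fx$ref)
  expect_equal(nrow(nc), 0L)
})

test_that("coding effects agree with whole-protein retranslation", {
  cfg <- tiny_sim_config(seed = 131L, n_genes = 10L)
  r <- generate_reference(cfg)
  gmres <- generate_gene_models(r$reference, r$truth, cfg)
  gm <- gmres$gene_models
  ref <- gmres$reference
  set.seed(132)
  checked <- 0L
  for (g in gm$genes$gene_id) {
    ex <- gm$cds[gm$cds$gene_id == g, ]
    positions <- unlist(lapply(seq_len(nrow(ex)), function(i)
      ex$start[i]:ex$end[i]))
    for (p in sample(positions, min(6L, length(positions)))) {
      ch <- ex$chrom[1]
      refb <- as.character(Biostrings::subseq(ref$sequences[[ch]], p, p))
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      got <- coding_effect(data.table::data.table(chrom = ch, pos = p,
                                                  ref = refb, alt = alt),
                           gm, ref)
      want <- oracle_coding_effect(ch, p, alt, gm, ref)
      expect_identical(got$class, want,
                       label = paste(g, "pos", p, refb, ">", alt))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 50L)
})

test_that("densities reproduce the printed per-100kb arithmetic", {
  d <- density_table(counts = c(A05 = 48510, C05 = 14756, X = 10),
                     chrom_lengths = c(A05 = 23750921, C05 = 32828344,
                                       X = 1000000))
  expect_equal(d$table$density_100kb, c(204, 45, 1))
})

test_that("window counts partition the per-chromosome totals", {
  set.seed(141)
  snps <- data.table::data.table(
    chrom = sample(c("A01", "C01"), 500, TRUE),
    pos = sample(250000, 500))
  d <- density_table(snps, c(A01 = 250000, C01 = 250000))
  agg <- d$windows[, list(n = sum(count)), by = "chrom"]
  expect_equal(agg$n[match(d$table$chrom, agg$chrom)], d$table$snps)
})

test_that("pairwise counts need both lines called and differing", {
  gm <- matrix(c("A", "A", "G", NA,
                 "A", "G", "G", "G",
                 "C", "C", "C", "C"),
               nrow = 3, byrow = TRUE,
               dimnames = list(NULL, paste0("acc0", 1:4)))
  m <- pairwise_snp_matrix(gm)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0L))
  expect_equal(m["acc01", "acc02"], 1L)  # site 2 differs
  expect_equal(m["acc01", "acc03"], 2L)  # sites 1 and 2 differ
  expect_equal(m["acc01", "acc04"], 1L)  # site-1 NA never counts
  # identical accessions share a zero pair count
  gm2 <- cbind(gm, acc05 = gm[, "acc03"])
  expect_equal(pairwise_snp_matrix(gm2)["acc03", "acc05"], 0L)
})

test_that("annotated accepted sites carry consistent Ts/Tv bookkeeping", {
  cfg <- tiny_sim_config(seed = 151L)
  r <- generate_reference(cfg)
  truth <- generate_panel(r$reference, r$truth, cfg)
  # build counts directly from truth: every line at depth 10
  rows <- list()
  snps <- truth$simple_snps
  for (i in seq_len(nrow(snps))) for (a in accession_ids(10)) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = snps$chrom[i], pos = snps$pos[i], ref = snps$ref[i],
      acc = a, base = snps[[a]][i], count = 10L)
  }
  callset <- run_cascade(data.table::rbindlist(rows))
  ann <- annotate_snps(callset$accepted, r$reference)
  bi <- ann[ann$allelism == "biallelic", ]
  ts <- tstv_summary(bi$allele_a, bi$allele_b)
  expect_equal(ts$transitions + ts$transversions, nrow(bi))
  expect_true(all(ann$aspcr[!ann$at_type] == FALSE))
})
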