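# Independent oracles used across the suite. These re-derive expected
# behaviour from first principles (brute force, enumeration, closed forms)
# and never call the package code paths they check.

# --- brute-force read mapper -------------------------------------------------
# Hamming alignment of `read` at every position of every chromosome, both
# orientations; same contract as the seed-and-extend mapper but with no
# seeding shortcut. Only full-length interior placements are considered.
brute_force_map <- function(read, seqs, max_mismatches = 5L) {
  read <- as.character(read)
  rl <- nchar(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits <- list()
  for (ch in names(seqs)) {
    s <- as.character(seqs[[ch]])
    L <- nchar(s)
    if (L < rl) next
    sv <- strsplit(s, "")[[1L]]
    for (orient in c("+", "-")) {
      rv <- strsplit(if (orient == "+") read else rc, "")[[1L]]
      for (p in seq_len(L - rl + 1L)) {
        mm <- sum(sv[p:(p + rl - 1L)] != rv)
        if (mm <= max_mismatches)
          hits[[length(hits) + 1L]] <- list(chrom = ch, pos = p,
                                            strand = orient, nm = mm)
      }
    }
  }
  if (length(hits) == 0L) return(list(category = "unaligned"))
  nms <- vapply(hits, `[[`, integer(1L), "nm")
  best <- which(nms == min(nms))
  if (length(best) > 1L) return(list(category = "repeat"))
  c(list(category = "unique"), hits[[best]])
}

# --- site-filter oracle ------------------------------------------------------
# Direct restatement of the genotype and site rules over a per-accession
# count matrix (rows = accessions, cols = A/C/G/T).
oracle_filter_column <- function(counts, min_depth = 4L, min_minor = 2L,
                                 het_reads = 2L, het_frac = 0.1) {
  statuses <- character(nrow(counts))
  alleles <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    v <- sort(counts[i, ], decreasing = TRUE)
    depth <- sum(v)
    if (depth < min_depth) {
      statuses[i] <- "missing_low_depth"
    } else if (v[2L] == v[1L] || (v[2L] >= het_reads &&
                                  v[2L] >= het_frac * depth)) {
      statuses[i] <- "heterozygous"
    } else {
      statuses[i] <- "called"
      alleles[i] <- names(v)[1L]
    }
  }
  if (any(statuses == "heterozygous"))
    return(list(status = "rejected", reason = "heterozygous_line"))
  called <- alleles[statuses == "called"]
  if (length(called) == 0L)
    return(list(status = "rejected", reason = "low_depth"))
  tab <- table(called)
  if (length(tab) < 2L) return(list(status = "rejected",
                                    reason = "monomorphic"))
  if (length(tab) > 3L) return(list(status = "rejected",
                                    reason = "excess_alleles"))
  if (min(tab) < min_minor) return(list(status = "rejected", reason = "maf"))
  list(status = "accepted",
       reason = NA_character_,
       allelism = if (length(tab) == 2L) "biallelic" else "triallelic")
}

# --- Fisher exact oracle -----------------------------------------------------
# Two-sided Fisher p by explicit hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more probable than the
# observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b           # study size
  n <- c + d
  k <- a + c           # with-term margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1L))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form Pearson chi-squared statistic for a 2x2 table
oracle_chisq_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

# --- whole-protein retranslation oracle --------------------------------------
# Apply one SNP to the chromosome, re-splice and translate the whole
# protein, and classify the effect from the full before/after sequences.
oracle_coding_effect <- function(snp_chrom, snp_pos, snp_alt, gene_models,
                                 reference) {
  cds <- gene_models$cds
  hit <- cds[cds$chrom == snp_chrom & cds$start <= snp_pos &
               cds$end >= snp_pos, ]
  if (nrow(hit) == 0L) return("noncoding")
  g <- hit$gene_id[1L]
  before <- allosnp::spliced_cds(gene_models, reference, g)
  mut_ref <- reference
  mut_ref$sequences[[snp_chrom]] <- Biostrings::replaceLetterAt(
    mut_ref$sequences[[snp_chrom]], snp_pos, snp_alt)
  after <- allosnp::spliced_cds(gene_models, mut_ref, g)
  aa_before <- as.character(suppressWarnings(Biostrings::translate(before)))
  aa_after <- as.character(suppressWarnings(Biostrings::translate(after)))
  if (aa_before == aa_after) return("synonymous")
  d <- which(strsplit(aa_before, "")[[1L]] != strsplit(aa_after, "")[[1L]])[1L]
  b <- substr(aa_before, d, d); a <- substr(aa_after, d, d)
  if (b != "*" && a == "*") "stop_gain"
  else if (b == "*" && a != "*") "stop_loss"
  else "nonsynonymous"
}

# --- small fixtures ----------------------------------------------------------
toy_reference <- function(seqs) {
  structure(list(sequences = Biostrings::DNAStringSet(seqs),
                 pairs = NULL),
            class = "reference_set")
}

tiny_sim_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               chrom_plan = data.frame(pair = "01", length = 20000L),
               repeat_families = data.frame(unit_length = 200L, copies = 6L),
               per_accession_depth = rep(12, 10),
               snp_rate = 1e-3, n_genes = 5L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(allosnp::sim_config, args)
}
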