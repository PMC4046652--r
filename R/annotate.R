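#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) exchanges are
#' transitions; all purine-pyrimidine exchanges are transversions.
#'
#' @param ref_allele,alt_allele Single bases (vectorized).
#' @return Character vector `"transition"`/`"transversion"`.
#' @export
classify_substitution <- function(ref_allele, alt_allele) {
  if (any(ref_allele == alt_allele))
    stop("identical alleles are not a substitution")
  ti <- (ref_allele %in% PURINES & alt_allele %in% PURINES) |
    (ref_allele %in% PYRIMIDINES & alt_allele %in% PYRIMIDINES)
  ifelse(ti, "transition", "transversion")
}

#' Transition/transversion summary of a biallelic SNP set
#'
#' Triallelic sites are excluded from the ratio by default (each extra
#' allele pair is reported separately when `per_pair = TRUE`).
#'
#' @param ref,alt Allele vectors of the biallelic sites.
#' @return List with counts, shares (percent) and the Ts/Tv ratio.
#' @export
tstv_summary <- function(ref, alt) {
  cls <- classify_substitution(ref, alt)
  n_ti <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  list(transitions = n_ti, transversions = n_tv,
       share_ti = 100 * n_ti / (n_ti + n_tv),
       share_tv = 100 * n_tv / (n_ti + n_tv),
       ratio = n_ti / n_tv)
}

#' Ts/Tv ratio implied by printed class shares
#' @param share_ti,share_tv Transition and transversion shares in percent.
#' @param digits Rounding applied to the ratio (default 2).
#' @return The ratio of the two shares.
#' @export
tstv_ratio_from_shares <- function(share_ti, share_tv, digits = 2L) {
  round(share_ti / share_tv, digits)
}

#' Allele-specific-PCR suitability of an A/T SNP
#'
#' True only for SNPs whose alleles are \{A, T\} and whose reference-strand
#' context has a `G` or `T` three bases upstream of the SNP, or a `C` or
#' `A` three bases downstream. A/T SNPs are otherwise hard to genotype by
#' AS-PCR because the two allele-specific primers differ only at their 3'
#' terminal base; the +/-3 context restores discrimination.
#'
#' @param ref_allele,alt_allele SNP alleles (vectorized).
#' @param upstream3,downstream3 The base 3 positions upstream / downstream
#'   on the reference strand (`NA` when truncated by a contig end, which
#'   yields `FALSE` with a warning).
#' @return Logical vector.
#' @export
aspcr_suitable <- function(ref_allele, alt_allele, upstream3, downstream3) {
  at <- (ref_allele == "A" & alt_allele == "T") |
    (ref_allele == "T" & alt_allele == "A")
  if (any(is.na(upstream3) | is.na(downstream3)))
    warning("flank truncated by contig end: not AS-PCR suitable")
  ok <- (upstream3 %in% c("G", "T")) | (downstream3 %in% c("C", "A"))
  ok[is.na(upstream3) & is.na(downstream3)] <- FALSE
  at & ok
}

#' Annotate accepted SNPs with substitution class and AS-PCR context
#'
#' @param accepted Accepted-site table (`chrom`, `pos`, `ref`, `alleles`)
#'   from [run_cascade()].
#' @param reference The `reference_set` (for +/-3 flanking bases).
#' @return The table with `allele_a`, `allele_b`, `substitution`, `at_type`
#'   and `aspcr` columns added (biallelic sites; triallelic sites get `NA`
#'   substitution columns).
#' @export
annotate_snps <- function(accepted, reference) {
  out <- data.table::copy(accepted)
  if (nrow(out) == 0L) {
    out[, c("allele_a", "allele_b", "substitution", "at_type", "aspcr") :=
          list(character(), character(), character(), logical(), logical())]
    return(out)
  }
  parts <- strsplit(out$alleles, ",", fixed = TRUE)
  first_two <- t(vapply(parts, function(p)
    sub(":.*", "", p)[1:2], character(2L)))
  out$allele_a <- first_two[, 1L]
  out$allele_b <- first_two[, 2L]
  bi <- out$allelism == "biallelic"
  out$substitution <- NA_character_
  out$substitution[bi] <- classify_substitution(out$allele_a[bi],
                                                out$allele_b[bi])
  seqs <- ref_seqs(reference)
  up <- down <- rep(NA_character_, nrow(out))
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    L <- length(seqs[[ch]])
    chars <- strsplit(as.character(seqs[[ch]]), "")[[1L]]
    pu <- out$pos[i] - 3L
    pd <- out$pos[i] + 3L
    up[i] <- ifelse(pu >= 1L, chars[pmax(pu, 1L)], NA_character_)
    down[i] <- ifelse(pd <= L, chars[pmin(pd, L)], NA_character_)
  }
  out$at_type <- bi &
    ((out$allele_a == "A" & out$allele_b == "T") |
     (out$allele_a == "T" & out$allele_b == "A"))
  out$aspcr <- FALSE
  if (any(bi))
    out$aspcr[bi] <- suppressWarnings(
      aspcr_suitable(out$allele_a[bi], out$allele_b[bi], up[bi], down[bi]))
  out
}

#' Codon-level coding effect of SNPs against toy gene models
#'
#' Maps each SNP into spliced CDS coordinates (minus-strand genes:
#' alleles complemented, positions reversed), rebuilds the affected codon
#' and classifies the exchange with the standard genetic code as
#' synonymous, non-synonymous, stop_gain (sense codon to stop) or
#' stop_loss (stop codon to sense).
#'
#' @param snps Table with `chrom`, `pos`, `ref` and alternate allele column
#'   `alt` (one alternate per row; explode multiallelic sites upstream).
#' @param gene_models A `gene_models` object.
#' @param reference The `reference_set` carrying the gene sequence.
#' @return data.table with one row per SNP-in-CDS: gene id, codon index,
#'   position in codon, ref/alt codons and amino acids, and `class`;
#'   SNPs outside any CDS are absent (noncoding).
#' @export
coding_effect <- function(snps, gene_models, reference) {
  cds <- gene_models$cds
  res <- list()
  gcode <- Biostrings::GENETIC_CODE
  for (g in unique(cds$gene_id)) {
    ex <- cds[g, on = "gene_id"][order(exon_rank)]
    ch <- ex$chrom[1L]
    strand <- ex$strand[1L]
    # genomic positions of the spliced CDS, in genomic order
    gpos <- unlist(lapply(seq_len(nrow(ex)), function(i)
      ex$start[i]:ex$end[i]))
    cds_seq <- as.character(spliced_cds(gene_models, reference, g))
    cds_len <- nchar(cds_seq)
    hits <- snps[snps$chrom == ch & snps$pos %in% gpos, ]
    if (nrow(hits) == 0L) next
    for (i in seq_len(nrow(hits))) {
      gidx <- match(hits$pos[i], gpos)
      cds_pos <- if (strand == "+") gidx else cds_len - gidx + 1L
      alt <- hits$alt[i]
      cds_alt <- if (strand == "+") alt else
        as.character(Biostrings::complement(Biostrings::DNAString(alt)))
      codon_idx <- (cds_pos - 1L) %/% 3L + 1L
      pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
      codon <- substr(cds_seq, 3L * codon_idx - 2L, 3L * codon_idx)
      if (grepl("N", codon, fixed = TRUE)) {
        warning("reference codon contains N; SNP left unannotated")
        next
      }
      alt_codon <- codon
      substr(alt_codon, pos_in_codon, pos_in_codon) <- cds_alt
      ref_aa <- gcode[[codon]]
      alt_aa <- gcode[[alt_codon]]
      cls <- if (ref_aa == alt_aa) "synonymous"
        else if (ref_aa != "*" && alt_aa == "*") "stop_gain"
        else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
        else "nonsynonymous"
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = ch, pos = hits$pos[i], gene_id = g, strand = strand,
        codon_index = codon_idx, pos_in_codon = pos_in_codon,
        ref_codon = codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa, class = cls)
    }
  }
  if (length(res) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  gene_id = character(), strand = character(),
                                  codon_index = integer(),
                                  pos_in_codon = integer(),
                                  ref_codon = character(),
                                  alt_codon = character(),
                                  ref_aa = character(), alt_aa = character(),
                                  class = character()))
  data.table::rbindlist(res)
}

#' Per-chromosome SNP density table
#'
#' Density is SNPs per 100 kb, rounded to the nearest integer; optional
#' fixed-width window counts support distribution plots. Works either from
#' a SNP table plus chromosome lengths, or directly from precomputed
#' per-chromosome counts.
#'
#' @param snps Table with `chrom`, `pos`, or `NULL` when `counts` given.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param counts Optional named vector of per-chromosome SNP counts.
#' @param window Window width for the per-window counts (default 1e5).
#' @return List: `table` (chrom, length, snp count, density per 100 kb) and
#'   `windows` (chrom, window start, count).
#' @export
density_table <- function(snps = NULL, chrom_lengths, counts = NULL,
                          window = 100000L) {
  stopifnot(all(chrom_lengths > 0))
  if (is.null(counts)) {
    if (any(!snps$chrom %in% names(chrom_lengths)))
      stop("SNP on unknown chromosome")
    counts <- table(factor(snps$chrom, levels = names(chrom_lengths)))
  }
  tab <- data.table::data.table(
    chrom = names(chrom_lengths),
    length = as.numeric(chrom_lengths),
    snps = as.integer(counts[names(chrom_lengths)]))
  tab$density_100kb <- round(tab$snps / tab$length * 1e5)
  windows <- NULL
  if (!is.null(snps) && nrow(snps)) {
    windows <- data.table::as.data.table(snps)[, {
      br <- seq(0L, chrom_lengths[[chrom[1L]]] + window, by = window)
      w <- table(cut(pos, br, right = TRUE))
      list(window_start = br[-length(br)] + 1L, count = as.integer(w))
    }, by = "chrom"]
  }
  list(table = tab, windows = windows)
}

#' Genome-level density summary (A vs C subgenome)
#'
#' @param density A density table from [density_table()] (`$table`).
#' @return List with per-subgenome densities per 100 kb, the overall
#'   density, and the A:C density ratio rounded to one decimal.
#' @export
subgenome_density_summary <- function(density) {
  sub <- substr(density$chrom, 1L, 1L)
  dens <- function(keep)
    round(sum(density$snps[keep]) / sum(density$length[keep]) * 1e5)
  a <- dens(sub == "A"); cc <- dens(sub == "C")
  list(density_A = a, density_C = cc,
       density_total = dens(rep(TRUE, nrow(density))),
       ratio_A_over_C = round(a / cc, 1L))
}

#' Pairwise SNP count matrix between accessions
#'
#' Entry (i, j) counts accepted sites where both lines are called and carry
#' different alleles; missing genotypes never count as differences.
#'
#' @param genotypes Long-form genotype table from [run_cascade()]
#'   (`$genotypes`), restricted to accepted sites by the caller, or a wide
#'   site-by-accession allele matrix.
#' @param accessions Accession ids (columns of the matrix form).
#' @return A symmetric integer matrix with zero diagonal.
#' @export
pairwise_snp_matrix <- function(genotypes, accessions = NULL) {
  if (is.matrix(genotypes)) {
    gm <- genotypes
    if (is.null(accessions)) accessions <- colnames(gm)
  } else {
    stopifnot(!is.null(accessions))
    called <- genotypes[status == "called"]
    if (nrow(called) == 0L) {
      n <- length(accessions)
      return(matrix(0L, n, n, dimnames = list(accessions, accessions)))
    }
    wide <- data.table::dcast(called, chrom + pos ~ acc,
                              value.var = "allele")
    for (a in setdiff(accessions, names(wide)))
      wide[, (a) := NA_character_]
    gm <- as.matrix(wide[, accessions, with = FALSE])
  }
  n <- length(accessions)
  m <- matrix(0L, n, n, dimnames = list(accessions, accessions))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- !is.na(gm[, i]) & !is.na(gm[, j])
    m[i, j] <- m[j, i] <- sum(gm[both, i] != gm[both, j])
  }
  m
}

#' Summaries of a pairwise SNP count matrix
#'
#' @param m Symmetric pairwise count matrix.
#' @param total_biallelic Total accepted biallelic SNP count, used to
#'   express the extreme pairs as a share of the discovered set.
#' @return List: mean over the distinct pairs, the max and min pairs with
#'   identities, and their shares (percent, one decimal).
#' @export
pairwise_summary <- function(m, total_biallelic = NULL) {
  vals <- m[lower.tri(m)]
  pairs <- which(lower.tri(m), arr.ind = TRUE)
  i_max <- which.max(vals); i_min <- which.min(vals)
  name_of <- function(k) paste(rownames(m)[pairs[k, 2L]],
                               rownames(m)[pairs[k, 1L]], sep = " / ")
  out <- list(n_pairs = length(vals),
              mean = round(mean(vals)),
              max = vals[i_max], max_pair = name_of(i_max),
              min = vals[i_min], min_pair = name_of(i_min))
  if (!is.null(total_biallelic)) {
    out$max_share <- round(100 * vals[i_max] / total_biallelic, 1L)
    out$min_share <- round(100 * vals[i_min] / total_biallelic, 1L)
  }
  out
}
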