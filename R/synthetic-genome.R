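#' Generate the synthetic allotetraploid reference and its truth table
#'
#' Each row of `config$chrom_plan` yields one homoeologous chromosome pair:
#' a common ancestral sequence is drawn at random, exact repeat-family copies
#' are inserted into it, and the sequence is then copied into an A and a C
#' version. The C copy is mutated at a fraction `homoeolog_divergence` of the
#' non-repeat positions, emulating the fixed inter-subgenome differences that
#' masquerade as SNPs in an allopolyploid. Repeat copies are kept identical
#' on both subgenomes so that multiplicity-based masking is unambiguous.
#'
#' The returned truth table records every divergent homoeolog position and
#' every repeat interval; downstream modules are validated against it.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference` (class `reference_set`: a named
#'   [Biostrings::DNAStringSet] plus a pair map) and `truth` (class
#'   `truth_table`).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "reference"))

  # one unit sequence per repeat family, shared by all pairs
  fam <- config$repeat_families
  units <- lapply(seq_len(nrow(fam)), function(i)
    random_bases(fam$unit_length[i]))

  seqs <- list()
  pair_map <- list()
  rep_iv <- list()
  div_sites <- list()

  for (p in seq_len(nrow(config$chrom_plan))) {
    pair <- as.character(config$chrom_plan$pair[p])
    L <- as.integer(config$chrom_plan$length[p])
    a_chrom <- paste0("A", pair)
    c_chrom <- paste0("C", pair)

    anc <- random_bases(L)
    occupied <- rep(FALSE, L)

    # distribute each family's copies across pairs; place without overlap
    for (f in seq_len(nrow(fam))) {
      n_here <- distribute_copies(fam$copies[f], nrow(config$chrom_plan))[p]
      w <- fam$unit_length[f]
      placed <- 0L
      tries <- 0L
      while (placed < n_here && tries < 200L * n_here) {
        tries <- tries + 1L
        s <- sample.int(L - w - 200L, 1L) + 100L
        if (any(occupied[s:(s + w - 1L)])) next
        anc[s:(s + w - 1L)] <- units[[f]]
        occupied[s:(s + w - 1L)] <- TRUE
        rep_iv[[length(rep_iv) + 1L]] <-
          data.table::data.table(chrom = c(a_chrom, c_chrom),
                                 start = s, end = s + w - 1L)
        placed <- placed + 1L
      }
      if (placed < n_here)
        warning("could not place all copies of repeat family ", f,
                " on pair ", pair)
    }

    a_seq <- anc
    c_seq <- anc
    div <- which(stats::runif(L) < config$homoeolog_divergence & !occupied)
    if (length(div) > 0L) {
      c_seq[div] <- other_base(anc[div])
      div_sites[[length(div_sites) + 1L]] <-
        data.table::data.table(pair = pair, pos = div,
                               a_chrom = a_chrom, c_chrom = c_chrom,
                               a_base = a_seq[div], c_base = c_seq[div])
    }

    seqs[[a_chrom]] <- a_seq
    seqs[[c_chrom]] <- c_seq
    pair_map[[p]] <- data.frame(pair = pair, a_chrom = a_chrom,
                                c_chrom = c_chrom, length = L)
  }

  reference <- structure(
    list(sequences = Biostrings::DNAStringSet(
           vapply(seqs, paste, character(1L), collapse = "")),
         pairs = do.call(rbind, pair_map)),
    class = "reference_set")

  truth <- structure(
    list(simple_snps = data.table::data.table(),
         homoeolog_sites = data.table::rbindlist(div_sites),
         repeat_intervals = if (length(rep_iv))
           data.table::rbindlist(rep_iv)[order(chrom, start)]
         else data.table::data.table(chrom = character(),
                                     start = integer(), end = integer()),
         hemi_assays = character(0L)),
    class = "truth_table")

  list(reference = reference, truth = truth)
}

distribute_copies <- function(total, n_pairs) {
  # round-robin allocation of repeat copies across chromosome pairs
  base <- total %/% n_pairs
  extra <- total %% n_pairs
  base + as.integer(seq_len(n_pairs) <= extra)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Synthetic allotetraploid reference:",
      length(x$sequences), "chromosomes (",
      nrow(x$pairs), "homoeologous pairs ),",
      sum(Biostrings::width(x$sequences)), "bp total\n")
  invisible(x)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Truth table:",
      nrow(x$simple_snps), "planted simple SNPs,",
      nrow(x$homoeolog_sites), "homoeolog-divergent sites,",
      nrow(x$repeat_intervals), "repeat intervals,",
      length(x$hemi_assays), "hemi assays\n")
  invisible(x)
}

chrom_seq_chars <- function(reference, chrom) {
  strsplit(as.character(reference$sequences[[chrom]]), "", fixed = TRUE)[[1L]]
}

#' Plant simple SNPs into the accession panel
#'
#' Places bi-allelic (and a small fraction of tri-allelic) single-locus SNPs
#' into non-repeat sequence of every chromosome at rate `snp_rate`. Each
#' SNP's minor allele is assigned to `k` accessions drawn from
#' `minor_count_spectrum`; all accessions are fully homozygous (inbred
#' panel), so the truth genotype matrix carries one base per accession and
#' site. Sites never stack: positions are sampled without replacement.
#'
#' Sites whose every allele is carried by at least two accessions are marked
#' `expected_pass = TRUE`: these are the sites the minor-allele filter is
#' supposed to retain, while planted singletons must later be rejected.
#'
#' @param reference A `reference_set`.
#' @param truth The matching `truth_table`; returned updated.
#' @param config A [sim_config()].
#' @return The updated `truth_table` with `simple_snps` filled in
#'   (columns `chrom`, `pos`, `ref`, `alt1`, `alt2`, `expected_pass` and one
#'   genotype column per accession).
#' @export
generate_panel <- function(reference, truth, config) {
  set.seed(stage_seed(config, "panel"))
  n_acc <- config$n_accessions
  acc <- accession_ids(n_acc)
  spectrum <- config$minor_count_spectrum
  kk <- as.integer(names(spectrum))

  rows <- list()
  for (ch in names(reference$sequences)) {
    L <- Biostrings::width(reference$sequences[ch])
    in_rep <- rep(FALSE, L)
    ri <- truth$repeat_intervals[ch, on = "chrom", nomatch = NULL]
    if (nrow(ri)) for (j in seq_len(nrow(ri)))
      in_rep[ri$start[j]:ri$end[j]] <- TRUE
    eligible <- which(!in_rep)
    n_snp <- stats::rbinom(1L, length(eligible), config$snp_rate)
    if (n_snp == 0L) next
    pos <- sort(sample(eligible, n_snp))
    seq_chars <- chrom_seq_chars(reference, ch)
    ref <- seq_chars[pos]
    alt1 <- mutate_biased(ref, config$transition_prob)
    k1 <- kk[sample.int(length(kk), n_snp, replace = TRUE, prob = spectrum)]
    tri <- stats::runif(n_snp) < config$triallelic_fraction

    geno <- matrix(rep(ref, n_acc), nrow = n_snp, ncol = n_acc)
    alt2 <- rep(NA_character_, n_snp)
    k2 <- rep(NA_integer_, n_snp)
    for (i in seq_len(n_snp)) {
      carriers <- sample.int(n_acc, k1[i])
      geno[i, carriers] <- alt1[i]
      if (tri[i]) {
        room <- n_acc - k1[i] - 2L   # keep >=2 reference carriers
        ok <- kk[kk <= room]
        if (length(ok) > 0L) {
          k2[i] <- ok[sample.int(length(ok), 1L,
                                 prob = spectrum[as.character(ok)])]
          alt2[i] <- sample(setdiff(BASES, c(ref[i], alt1[i])), 1L)
          geno[i, sample(setdiff(seq_len(n_acc), carriers), k2[i])] <- alt2[i]
        }
      }
    }

    dt <- data.table::data.table(chrom = ch, pos = pos, ref = ref,
                                 alt1 = alt1, alt2 = alt2)
    gm <- data.table::as.data.table(geno)
    data.table::setnames(gm, acc)
    rows[[length(rows) + 1L]] <- cbind(dt, gm)
  }

  snps <- if (length(rows)) data.table::rbindlist(rows)
          else data.table::data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt1 = character(),
                                      alt2 = character())
  if (nrow(snps)) {
    gmat <- as.matrix(snps[, acc, with = FALSE])
    snps$expected_pass <- apply(gmat, 1L, function(g) {
      tab <- table(g)
      length(tab) >= 2L && all(tab >= 2L)
    })
  } else snps$expected_pass <- logical(0L)

  truth$simple_snps <- snps
  truth
}

#' Accession identifiers used throughout the synthetic panel
#' @param n Number of accessions.
#' @return Character vector `acc01`, `acc02`, ...
#' @export
accession_ids <- function(n) sprintf("acc%02d", seq_len(n))

#' Personalized genome of one accession
#'
#' Applies the accession's planted alleles to the reference, yielding the
#' genome its reads are drawn from.
#'
#' @param reference A `reference_set`.
#' @param truth The `truth_table` holding panel genotypes.
#' @param accession Accession id, e.g. `"acc03"`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
accession_genome <- function(reference, truth, accession) {
  seqs <- reference$sequences
  snps <- truth$simple_snps
  if (nrow(snps) == 0L) return(seqs)
  for (ch in unique(snps$chrom)) {
    sub <- snps[ch, on = "chrom"]
    allele <- sub[[accession]]
    differs <- allele != sub$ref
    if (any(differs)) {
      seqs[[ch]] <- Biostrings::replaceLetterAt(
        seqs[[ch]], sub$pos[differs], allele[differs])
    }
  }
  seqs
}
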