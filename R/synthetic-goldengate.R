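#' Simulate two-channel GoldenGate genotyping intensities
#'
#' Emulates a multiplexed two-colour genotyping experiment on a
#' doubled-haploid (DH) and an F2 mapping population. Each assay interrogates
#' one planted SNP: allele A drives the Cy3 channel and allele B the Cy5
#' channel (`mu_on` for a homozygous carrier, `mu_off` otherwise;
#' heterozygotes split the signal), with Gaussian channel noise truncated
#' at zero. A configurable fraction of assays is planted as hemi-SNPs:
#' their probes co-amplify a second locus whose fixed homozygous genotype
#' differs between the two populations, so the pooled populations form four
#' or more theta groups while each single population still looks ordinary.
#' One DH sample is emitted in triplicate for the reproducibility check.
#'
#' Candidate assays additionally receive a designability rank score:
#' `n_assays` of the `n_candidates` score above the 0.85 design cutoff by
#' construction, the remainder below (the score itself is treated as a
#' given input, as it comes from a proprietary scoring service in the real
#' workflow).
#'
#' @param truth A `truth_table`; returned with `hemi_assays` filled in.
#' @param config A [sim_config()]; constants under `config$goldengate`.
#' @return A list of class `goldengate_data`: `intensities` (sample,
#'   population, replicate, assay, Cy3, Cy5), `samples`, `assays` (per-assay
#'   truth: hemi flag, parent genotypes), `designability` (all candidates
#'   with scores), and the updated `truth`.
#' @export
simulate_goldengate <- function(truth, config) {
  set.seed(stage_seed(config, "goldengate"))
  gg <- config$goldengate
  n_cand <- gg$n_candidates
  n_assay <- gg$n_assays
  stopifnot(n_assay <= n_cand)

  cand_ids <- sprintf("SNP%03d", seq_len(n_cand))
  pass <- sort(sample.int(n_cand, n_assay))
  score <- numeric(n_cand)
  score[pass] <- round(stats::runif(n_assay, 0.86, 0.99), 2L)
  score[-pass] <- round(stats::runif(n_cand - n_assay, 0.56, 0.85), 2L)
  designability <- data.table::data.table(assay = cand_ids,
                                          rank_score = score)
  assay_ids <- cand_ids[pass]

  n_hemi <- max(0L, round(gg$hemi_fraction * n_assay))
  hemi <- sort(sample.int(n_assay, n_hemi))
  poly_dh <- stats::runif(n_assay) < gg$polymorphic_fraction
  poly_f2 <- stats::runif(n_assay) < gg$polymorphic_fraction
  # hemi detection needs segregation in both populations
  poly_dh[hemi] <- TRUE
  poly_f2[hemi] <- TRUE

  # parent genotypes per population ("A" = homozygous allele A, ...)
  dh_p1 <- sample(c("AA", "BB"), n_assay, replace = TRUE)
  dh_p2 <- ifelse(poly_dh, ifelse(dh_p1 == "AA", "BB", "AA"), dh_p1)
  f2_p1 <- sample(c("AA", "BB"), n_assay, replace = TRUE)
  f2_p2 <- ifelse(poly_f2, ifelse(f2_p1 == "AA", "BB", "AA"), f2_p1)

  assays <- data.table::data.table(
    assay = assay_ids, hemi = seq_len(n_assay) %in% hemi,
    rank_score = score[pass],
    dh_p1 = dh_p1, dh_p2 = dh_p2, f2_p1 = f2_p1, f2_p2 = f2_p2,
    # second-locus background genotype of hemi assays, per population
    bg_dh = ifelse(seq_len(n_assay) %in% hemi, "AA", NA_character_),
    bg_f2 = ifelse(seq_len(n_assay) %in% hemi, "BB", NA_character_))

  dh_lines <- sprintf("DH_L%02d", seq_len(gg$n_dh))
  f2_lines <- sprintf("F2_L%02d", seq_len(gg$n_f2))
  samples <- data.table::data.table(
    sample = c("DH_P1", "DH_P2", dh_lines,
               paste0(dh_lines[1L], c("_rep2", "_rep3")),
               "F2_P1", "F2_P2", f2_lines),
    population = c(rep("DH", 2L + gg$n_dh + 2L), rep("F2", 2L + gg$n_f2)),
    role = c("parent", "parent", rep("line", gg$n_dh),
             "replicate", "replicate",
             "parent", "parent", rep("line", gg$n_f2)),
    replicate_of = NA_character_)
  samples$replicate_of[samples$role == "replicate"] <- dh_lines[1L]

  # genotype matrix: samples x assays
  geno <- matrix(NA_character_, nrow(samples), n_assay,
                 dimnames = list(samples$sample, assay_ids))
  for (j in seq_len(n_assay)) {
    geno["DH_P1", j] <- dh_p1[j]; geno["DH_P2", j] <- dh_p2[j]
    geno["F2_P1", j] <- f2_p1[j]; geno["F2_P2", j] <- f2_p2[j]
    if (poly_dh[j]) {
      geno[dh_lines, j] <- sample(c("AA", "BB"), gg$n_dh, replace = TRUE)
    } else geno[dh_lines, j] <- dh_p1[j]
    if (poly_f2[j]) {
      geno[f2_lines, j] <- sample(c("AA", "AB", "BB"), gg$n_f2,
                                  replace = TRUE, prob = c(1, 2, 1) / 4)
    } else geno[f2_lines, j] <- f2_p1[j]
  }
  reps <- samples$sample[samples$role == "replicate"]
  geno[reps, ] <- geno[rep(dh_lines[1L], length(reps)), ]

  dose_a <- c(AA = 1, AB = 0.5, BB = 0)
  rows <- vector("list", n_assay)
  for (j in seq_len(n_assay)) {
    dA <- dose_a[geno[, j]]
    cy3 <- gg$mu_off + dA * (gg$mu_on - gg$mu_off)
    cy5 <- gg$mu_off + (1 - dA) * (gg$mu_on - gg$mu_off)
    if (assays$hemi[j]) {
      bg <- ifelse(samples$population == "DH", assays$bg_dh[j],
                   assays$bg_f2[j])
      dBg <- dose_a[bg]
      cy3 <- cy3 + gg$mu_off + dBg * (gg$mu_on - gg$mu_off)
      cy5 <- cy5 + gg$mu_off + (1 - dBg) * (gg$mu_on - gg$mu_off)
    }
    cy3 <- pmax(0, cy3 + stats::rnorm(nrow(samples), 0, gg$sd))
    cy5 <- pmax(0, cy5 + stats::rnorm(nrow(samples), 0, gg$sd))
    rows[[j]] <- data.table::data.table(
      sample = samples$sample, population = samples$population,
      role = samples$role, assay = assay_ids[j],
      Cy3 = cy3, Cy5 = cy5, true_genotype = unname(geno[, j]))
  }

  truth$hemi_assays <- assays$assay[assays$hemi]
  structure(list(intensities = data.table::rbindlist(rows),
                 samples = samples, assays = assays,
                 designability = designability, truth = truth),
            class = "goldengate_data")
}

#' @export
print.goldengate_data <- function(x, ...) {
  cat("GoldenGate simulation:", nrow(x$assays), "assays,",
      nrow(x$samples), "samples,", length(x$truth$hemi_assays),
      "planted hemi assays\n")
  invisible(x)
}
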