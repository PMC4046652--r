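#' Simulation configuration for the synthetic allotetraploid study design
#'
#' Bundles every knob of the synthetic data generator into a single validated
#' object. The defaults mirror the study design the pipeline was built around:
#' ten fully inbred accessions of an A+C allotetraploid, short paired reads of
#' 75 or 100 bp, per-accession depths spanning roughly 5-38 fold, a per-base
#' homoeolog divergence of 3% between the two subgenomes, and a small panel of
#' GoldenGate assays typed on a doubled-haploid (DH, 50 lines) and an F2
#' (80 lines) population with deliberately planted hemi-SNP assays.
#'
#' @param seed Integer seed; fully determines every output of the generator.
#' @param n_accessions Number of inbred accessions in the resequencing panel.
#' @param chrom_plan Data frame with columns `pair` (label) and `length` (bp).
#'   Each row yields one homoeologous chromosome pair: an A and a C copy
#'   derived from a common ancestral sequence.
#' @param homoeolog_divergence Per-base substitution probability between the
#'   A and C copies of a pair (outside repeats and conserved gene bodies).
#' @param repeat_families Data frame with columns `unit_length` and `copies`;
#'   each family is inserted as exact copies into the ancestral sequence so
#'   both subgenomes carry it.
#' @param snp_rate Simple-SNP planting rate per non-repeat base, per subgenome.
#' @param transition_prob Probability that a planted alternate allele is the
#'   transition partner of the reference base (default 0.575, matching the
#'   transition share typically seen in plant resequencing panels); the two
#'   transversion partners split the remainder equally.
#' @param triallelic_fraction Fraction of planted SNPs receiving a third allele.
#' @param minor_count_spectrum Named numeric vector of weights over the number
#'   of accessions carrying the minor allele (names "1".."n/2"). The default
#'   includes singletons, which the minor-allele filter must later reject.
#' @param read_length Read length in bp (75 or 100).
#' @param per_accession_depth Numeric vector of fold-coverages, one per
#'   accession. The default reproduces the 5.3-37.5 fold spread of the study
#'   design (mean 10.7 fold when scaled to ten accessions).
#' @param base_error_rate Per-base sequencing error probability.
#' @param n_genes Number of toy gene models written into each chromosome pair.
#' @param goldengate List of GoldenGate simulation constants: `n_dh`, `n_f2`
#'   (population sizes), `n_assays`, `n_candidates` (assays submitted to
#'   designability scoring), `mu_on`, `mu_off`, `sd` (channel intensity means
#'   and noise), `hemi_fraction` (fraction of assays planted as hemi-SNPs),
#'   `polymorphic_fraction` (fraction polymorphic between population parents).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 10L,
                       chrom_plan = data.frame(pair = c("01", "02"),
                                               length = c(60000L, 60000L)),
                       homoeolog_divergence = 0.03,
                       repeat_families = data.frame(unit_length = c(300L, 150L),
                                                    copies = c(12L, 20L)),
                       snp_rate = 1e-4,
                       transition_prob = 0.575,
                       triallelic_fraction = 3e-4,
                       minor_count_spectrum = c("1" = 0.30, "2" = 0.25,
                                                "3" = 0.20, "4" = 0.15,
                                                "5" = 0.10),
                       read_length = 100L,
                       per_accession_depth = c(37.5, 22.2, 9.0, 7.2, 6.5,
                                               6.6, 5.3, 6.0, 7.6, 6.7),
                       base_error_rate = 0.002,
                       n_genes = 24L,
                       goldengate = list(n_dh = 50L, n_f2 = 80L,
                                         n_assays = 96L, n_candidates = 110L,
                                         mu_on = 4000, mu_off = 300, sd = 200,
                                         hemi_fraction = 3 / 96,
                                         polymorphic_fraction = 0.5)) {
  cfg <- list(seed = as.integer(seed),
              n_accessions = as.integer(n_accessions),
              chrom_plan = as.data.frame(chrom_plan),
              homoeolog_divergence = homoeolog_divergence,
              repeat_families = as.data.frame(repeat_families),
              snp_rate = snp_rate,
              transition_prob = transition_prob,
              triallelic_fraction = triallelic_fraction,
              minor_count_spectrum = minor_count_spectrum,
              read_length = as.integer(read_length),
              per_accession_depth = per_accession_depth,
              base_error_rate = base_error_rate,
              n_genes = as.integer(n_genes),
              goldengate = goldengate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (nrow(cfg$chrom_plan) == 0L)
    stop("chrom_plan must contain at least one homoeologous pair")
  if (!all(c("pair", "length") %in% names(cfg$chrom_plan)))
    stop("chrom_plan needs columns 'pair' and 'length'")
  rates <- c(cfg$homoeolog_divergence, cfg$snp_rate, cfg$triallelic_fraction,
             cfg$base_error_rate, cfg$transition_prob)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]")
  if (any(cfg$chrom_plan$length < 10L * cfg$read_length))
    stop("invalid configuration: chromosome shorter than 10x read_length")
  if (length(cfg$per_accession_depth) != cfg$n_accessions)
    stop("per_accession_depth must have one entry per accession")
  if (any(cfg$per_accession_depth <= 0))
    stop("invalid configuration: depth must be positive")
  if (!cfg$read_length %in% c(75L, 100L))
    warning("read_length outside the 75/100 bp design")
  sp <- cfg$minor_count_spectrum
  if (is.null(names(sp)) || any(sp < 0) || sum(sp) <= 0)
    stop("minor_count_spectrum must be a named non-negative weight vector")
  if (any(as.integer(names(sp)) > cfg$n_accessions %/% 2L))
    stop("minor_count_spectrum support must not exceed n_accessions/2")
  cfg
}

# Stage order used to derive independent sub-seeds from the master seed, so
# each generator stage is reproducible on its own.
.sim_stages <- c("reference", "genes", "panel", "reads", "goldengate",
                 "enrich", "extra")

#' Derive the deterministic sub-seed for a generator stage
#'
#' @param config A [sim_config()].
#' @param stage One of `"reference"`, `"genes"`, `"panel"`, `"reads"`,
#'   `"goldengate"`, `"enrich"`, `"extra"`.
#' @return An integer seed below 2^31, a pure function of (seed, stage).
#' @export
stage_seed <- function(config, stage) {
  i <- match(stage, .sim_stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((abs(as.integer(config$seed)) %% 100000L) * 13007L + i)
}
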