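#' Published B. napus resequencing summary tables
#'
#' Small reference datasets shipped with the package: the pairwise SNP
#' counts among the ten resequenced *Brassica napus* accessions, the
#' per-chromosome SNP distribution over the A and C pseudochromosomes, and
#' the headline counts of the published discovery set (bi-/tri-allelic
#' totals, substitution-class shares, validation read counts). They serve
#' as worked-example inputs for the summary arithmetic implemented here
#' (pairwise means and extreme-pair shares, per-100 kb densities, Ts/Tv
#' ratio, validation false-positive rate); the underlying genome-scale
#' read data (GenBank SRA057227; dbSNP ss647660101-ss657954846) is never
#' required.
#'
#' @return `napus_pairwise_counts()`: a symmetric 10x10 integer matrix.
#'   `napus_chromosome_table()`: a data.table with chromosome lengths, SNP
#'   counts and printed per-100 kb densities. `napus_reported_counts()`: a
#'   named numeric vector of headline counts.
#' @export
napus_pairwise_counts <- function() {
  f <- system.file("extdata", "napus_pairwise_snps.tsv", package = "allosnp")
  long <- utils::read.delim(f, check.names = FALSE)
  accs <- unique(c(long$acc2, long$acc1))
  m <- matrix(0L, length(accs), length(accs), dimnames = list(accs, accs))
  for (i in seq_len(nrow(long)))
    m[long$acc1[i], long$acc2[i]] <- m[long$acc2[i], long$acc1[i]] <-
      long$snps[i]
  m
}

#' @rdname napus_pairwise_counts
#' @export
napus_chromosome_table <- function() {
  f <- system.file("extdata", "napus_chromosome_snps.tsv",
                   package = "allosnp")
  data.table::fread(f)
}

#' @rdname napus_pairwise_counts
#' @export
napus_reported_counts <- function() {
  f <- system.file("extdata", "napus_reported_counts.tsv",
                   package = "allosnp")
  kv <- utils::read.delim(f)
  stats::setNames(kv$value, kv$key)
}
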