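BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- {
  cods <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  setdiff(cods, STOP_CODONS)
}

random_bases <- function(n) sample(BASES, n, replace = TRUE)

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# alternate allele with a set transition probability; the two transversion
# partners split the remainder equally
mutate_biased <- function(base, transition_prob) {
  vapply(base, function(b) {
    if (stats::runif(1L) < transition_prob) TRANSITION_PARTNER[[b]]
    else sample(setdiff(BASES, c(b, TRANSITION_PARTNER[[b]])), 1L)
  }, character(1L), USE.NAMES = FALSE)
}

other_base <- function(base) {
  # one uniformly chosen base different from `base`, vectorized
  vapply(base, function(b) sample(setdiff(BASES, b), 1L), character(1L),
         USE.NAMES = FALSE)
}
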