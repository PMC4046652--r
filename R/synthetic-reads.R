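#' Simulate short reads for every accession
#'
#' Reads are drawn uniformly from each accession's personalized genome
#' (reference plus its planted alleles), on forward or reverse strand with
#' equal probability, at the per-accession fold-coverage given in the
#' configuration. Each base is flipped to a uniformly chosen different base
#' with probability `base_error_rate`. Quality strings are constant; read
#' names encode the true origin as `accession:chrom:start:strand:serial`
#' so any downstream placement can be audited.
#'
#' @param reference A `reference_set` (post gene-model insertion).
#' @param truth The `truth_table` holding panel genotypes.
#' @param config A [sim_config()].
#' @param accessions Optional subset of accession ids to simulate.
#' @return A named list (one element per accession) of named
#'   [Biostrings::DNAStringSet] read sets.
#' @export
simulate_reads <- function(reference, truth, config,
                           accessions = accession_ids(config$n_accessions)) {
  if (any(config$per_accession_depth <= 0))
    stop("invalid configuration: depth must be positive")
  set.seed(stage_seed(config, "reads"))
  rl <- config$read_length
  all_acc <- accession_ids(config$n_accessions)
  out <- vector("list", length(accessions))
  names(out) <- accessions

  for (a in accessions) {
    depth <- config$per_accession_depth[match(a, all_acc)]
    genome <- accession_genome(reference, truth, a)
    per_chrom <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      ch <- names(genome)[ci]
      L <- Biostrings::width(genome)[ci]
      n_reads <- as.integer(round(depth * L / rl))
      if (n_reads == 0L) next
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      v <- Biostrings::Views(genome[[ci]], start = starts, width = rl)
      reads <- as(v, "DNAStringSet")
      minus <- strand == "-"
      if (any(minus))
        reads[minus] <- Biostrings::reverseComplement(reads[minus])
      reads <- inject_errors(reads, config$base_error_rate)
      names(reads) <- sprintf("%s:%s:%d:%s:%d", a, ch, starts, strand,
                              seq_len(n_reads))
      per_chrom[[ci]] <- reads
    }
    out[[a]] <- do.call(c, per_chrom[!vapply(per_chrom, is.null, logical(1L))])
  }
  out
}

#' Flip random bases of a read set at a fixed per-base error rate
#'
#' @param reads A [Biostrings::DNAStringSet] of constant-width reads.
#' @param error_rate Per-base substitution probability.
#' @return The read set with errors injected (names preserved).
#' @export
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  rl <- Biostrings::width(reads)[1L]
  total <- length(reads) * rl
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(reads)
  idx <- sample.int(total, n_err)
  read_i <- ((idx - 1L) %/% rl) + 1L
  pos_i <- ((idx - 1L) %% rl) + 1L
  xs <- as.character(reads)
  old <- substr(xs[read_i], pos_i, pos_i)
  new <- other_base(old)
  # substr<- assigns one position per element; resolve reads hit repeatedly
  # in successive rounds
  remaining <- seq_along(idx)
  while (length(remaining) > 0L) {
    first <- remaining[!duplicated(read_i[remaining])]
    r <- read_i[first]; p <- pos_i[first]
    substr(xs[r], p, p) <- new[first]
    remaining <- setdiff(remaining, first)
  }
  out <- Biostrings::DNAStringSet(xs)
  names(out) <- names(reads)
  out
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @param quality_char Constant per-base quality character (default `"I"`,
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  quals <- Biostrings::BStringSet(
    strrep(quality_char, Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
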