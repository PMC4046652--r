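#' K-mer multiplicity repeat masking
#'
#' Masks every position covered exclusively by k-mers that occur more than
#' `max_copies` times genome-wide (strand-collapsed canonical counting).
#' The default `max_copies = 2` deliberately tolerates the two legitimate
#' homoeologous copies an allotetraploid carries, so diverged A/C pairs stay
#' unmasked while true repeat families (and their inter-subgenome copies)
#' are caught. Masking before alignment restricts the analysis to low-copy
#' DNA, which is what makes unique-read SNP calling meaningful in a
#' polyploid.
#'
#' @param reference A `reference_set` or named [Biostrings::DNAStringSet].
#' @param k K-mer length (default 31; must be at least 11).
#' @param max_copies Maximum tolerated genome-wide canonical k-mer count.
#' @return A data.table of merged mask intervals
#'   (`chrom`, `start`, `end`, 1-based inclusive).
#' @export
kmer_mask <- function(reference, k = 31L, max_copies = 2L) {
  seqs <- ref_seqs(reference)
  if (k < 11L) stop("k must be >= 11")
  if (k > min(Biostrings::width(seqs)))
    stop("k exceeds the shortest chromosome")

  # genome-wide canonical k-mer counts
  per_chrom_kmers <- lapply(seq_along(seqs), function(i) {
    x <- seqs[[i]]
    n <- length(x) - k + 1L
    fwd <- as.character(Biostrings::Views(x, start = seq_len(n), width = k))
    rev <- as.character(Biostrings::Views(
      Biostrings::reverseComplement(x),
      start = length(x) - (seq_len(n) + k - 1L) + 1L, width = k))
    pmin(fwd, rev)
  })
  counts <- table(unlist(per_chrom_kmers))

  out <- list()
  for (i in seq_along(seqs)) {
    can <- per_chrom_kmers[[i]]
    high <- as.vector(counts[can]) > max_copies
    high[is.na(high)] <- FALSE
    L <- length(seqs[[i]])
    n <- length(can)
    # position j is covered by k-mer starts max(1, j-k+1) .. min(j, n);
    # masked iff all covering k-mers are high-copy
    cs <- cumsum(c(0L, as.integer(high)))
    lo <- pmax(1L, seq_len(L) - k + 1L)
    hi <- pmin(seq_len(L), n)
    n_cov <- hi - lo + 1L
    n_high <- cs[hi + 1L] - cs[lo]
    masked <- n_cov > 0L & n_high == n_cov
    out[[i]] <- runs_to_intervals(masked, names(seqs)[i])
  }
  merge_intervals(data.table::rbindlist(out))
}

ref_seqs <- function(reference) {
  if (inherits(reference, "reference_set")) reference$sequences
  else if (inherits(reference, "masked_reference")) reference$dna
  else reference
}

runs_to_intervals <- function(flag, chrom) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.table::data.table(chrom = chrom, start = starts[keep],
                         end = ends[keep])
}

#' Mask matches to a repeat library
#'
#' Scans both strands of the reference for ungapped full-length matches of
#' each library unit at identity `>= min_identity`, and masks the matched
#' intervals. Units shorter than `min_length` are skipped.
#'
#' @param reference A `reference_set` or named [Biostrings::DNAStringSet].
#' @param repeat_library A [Biostrings::DNAStringSet] of repeat unit
#'   sequences (e.g. read from FASTA).
#' @param min_identity Minimum fraction of matching bases (default 0.9).
#' @param min_length Minimum unit length considered (default 50).
#' @return A data.table of merged mask intervals.
#' @export
library_mask <- function(reference, repeat_library, min_identity = 0.9,
                         min_length = 50L) {
  seqs <- ref_seqs(reference)
  if (length(repeat_library) == 0L) {
    warning("empty repeat library: empty mask")
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  out <- list()
  for (u in seq_along(repeat_library)) {
    unit <- repeat_library[[u]]
    w <- length(unit)
    if (w < min_length) next
    max_mm <- floor((1 - min_identity) * w)
    for (i in seq_along(seqs)) {
      for (pat in list(unit, Biostrings::reverseComplement(unit))) {
        m <- Biostrings::matchPattern(pat, seqs[[i]],
                                      max.mismatch = max_mm, fixed = TRUE)
        if (length(m))
          out[[length(out) + 1L]] <- data.table::data.table(
            chrom = names(seqs)[i],
            start = Biostrings::start(m), end = Biostrings::end(m))
      }
    }
  }
  if (length(out) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  merge_intervals(data.table::rbindlist(out))
}

#' Merge, sort and bound-check mask intervals
#' @param intervals data.table with `chrom`, `start`, `end` (1-based closed).
#' @return The merged intervals, sorted by chromosome and start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  ir <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  red <- GenomicRanges::reduce(ir)
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                         start = GenomicRanges::start(red),
                         end = GenomicRanges::end(red))[order(chrom, start)]
}

#' Apply mask intervals to a reference
#'
#' Style `"lowercase"` preserves the masked bases as lowercase letters (the
#' usual soft-masked FASTA convention); style `"hard"` replaces them with
#' `N`. The hard-masked sequence set is always computed alongside, because
#' the aligner indexes only unmasked sequence.
#'
#' @param reference A `reference_set` or named [Biostrings::DNAStringSet].
#' @param intervals Mask intervals (`chrom`, `start`, `end`).
#' @param style `"lowercase"` or `"hard"`.
#' @return An object of class `masked_reference`: fields `dna` (original
#'   sequences), `dna_hard` (N-masked), `text` (character vector per the
#'   chosen style), `intervals`, `style`, `masked_fraction`.
#' @export
apply_mask <- function(reference, intervals, style = c("lowercase", "hard")) {
  style <- match.arg(style)
  seqs <- ref_seqs(reference)
  intervals <- merge_intervals(data.table::as.data.table(intervals))
  txt <- as.character(seqs)
  hard <- txt
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    if (!ch %in% names(txt)) stop("mask interval on unknown chromosome ", ch)
    if (s < 1L || e > nchar(txt[[ch]])) stop("mask interval out of bounds")
    piece <- substr(txt[[ch]], s, e)
    substr(hard[[ch]], s, e) <- strrep("N", e - s + 1L)
    if (style == "lowercase")
      substr(txt[[ch]], s, e) <- tolower(piece)
  }
  masked_bp <- if (nrow(intervals))
    sum(intervals$end - intervals$start + 1L) else 0L
  structure(list(dna = seqs,
                 dna_hard = Biostrings::DNAStringSet(hard),
                 text = if (style == "lowercase") txt else hard,
                 intervals = intervals,
                 style = style,
                 masked_fraction = masked_bp / sum(Biostrings::width(seqs))),
            class = "masked_reference")
}

#' @export
print.masked_reference <- function(x, ...) {
  cat(sprintf("Masked reference: %d sequences, %.2f%% masked (%s style), %d intervals\n",
              length(x$dna), 100 * x$masked_fraction, x$style,
              nrow(x$intervals)))
  invisible(x)
}

#' Write a (masked) reference to FASTA
#' @param x A `masked_reference`, `reference_set` or named DNAStringSet.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "masked_reference")) {
    writeLines(paste0(">", names(x$text), "\n",
                      vapply(x$text, identity, character(1L))), path)
  } else {
    Biostrings::writeXStringSet(ref_seqs(x), path)
  }
  invisible(path)
}

#' Export mask intervals as BED (0-based half-open)
#' @param intervals data.table of 1-based closed intervals.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(intervals, path) {
  utils::write.table(
    data.frame(chrom = intervals$chrom, start = intervals$start - 1L,
               end = intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
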