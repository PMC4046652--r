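#' Alignment parameters (mismatch, seed, minimal alignment length)
#'
#' The defaults mirror the short-read mapping contract the SNP discovery
#' rests on: at most 5 mismatches per read (`-v 5`), a 32 bp exact seed
#' (`-l 32`), and a minimal aligned length of 40 bp (`-s 40`) for reads
#' overhanging a contig end. Alignment is ungapped; the SNP set is
#' substitution-only by design.
#'
#' @param max_mismatches Maximum mismatches for a reported placement.
#' @param seed_length Exact-match seed length in bp.
#' @param min_align_length Minimal aligned length when a read overhangs a
#'   contig end; interior reads always align full-length.
#' @return An object of class `align_params`.
#' @export
align_params <- function(max_mismatches = 5L, seed_length = 32L,
                         min_align_length = 40L) {
  structure(list(max_mismatches = as.integer(max_mismatches),
                 seed_length = as.integer(seed_length),
                 min_align_length = as.integer(min_align_length)),
            class = "align_params")
}

#' Build an exact-seed index over the unmasked reference
#'
#' Hashes every `seed_length`-mer of the hard-masked reference (forward
#' strand; read orientation is handled at query time) to its occurrence
#' list. Seeds containing `N` (masked or ambiguous) are excluded.
#'
#' @param masked_reference A `masked_reference` (or reference set; then
#'   nothing is masked).
#' @param seed_length Seed length in bp.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(masked_reference, seed_length = 32L) {
  seqs <- hard_seqs(masked_reference)
  tabs <- list()
  for (i in seq_along(seqs)) {
    L <- length(seqs[[i]])
    n <- L - seed_length + 1L
    if (n < 1L) next
    mers <- as.character(Biostrings::Views(seqs[[i]], start = seq_len(n),
                                           width = seed_length))
    keep <- !grepl("N", mers, fixed = TRUE)
    if (!any(keep)) next
    tabs[[length(tabs) + 1L]] <- data.table::data.table(
      seed = mers[keep], chrom = names(seqs)[i], pos = which(keep))
  }
  tab <- if (length(tabs)) data.table::rbindlist(tabs)
         else data.table::data.table(seed = character(), chrom = character(),
                                     pos = integer())
  data.table::setkey(tab, seed)
  structure(list(table = tab, seed_length = as.integer(seed_length),
                 seqs = seqs),
            class = "seed_index")
}

hard_seqs <- function(x) {
  if (inherits(x, "masked_reference")) x$dna_hard else ref_seqs(x)
}

#' Map a single read by seed-and-extend (reference implementation)
#'
#' Candidate loci are found through any exact seed hit at any read offset,
#' on either read orientation; each candidate is then extended ungapped
#' across the full read (clipped at contig ends). Placements with at most
#' `max_mismatches` mismatches over an aligned length of at least
#' `min_align_length` are kept; a single best-score placement makes the read
#' `unique`, a tie at the best score makes it `repeat` (conservative
#' exclusion of redundant hits), and no placement leaves it `unaligned`.
#'
#' @param read A [Biostrings::DNAString] or character read sequence.
#' @param index A `seed_index` from [build_index()].
#' @param params An [align_params()].
#' @return One-row data.table: `category` plus `chrom`, `pos`, `strand`,
#'   `nm` when unique.
#' @export
map_read <- function(read, index, params = align_params()) {
  read <- Biostrings::DNAString(as.character(read))
  s <- index$seed_length
  if (length(read) < s)
    return(aln_row("unaligned", reason = "read shorter than seed"))

  cands <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else Biostrings::reverseComplement(read)
    ors <- as.character(oriented)
    offs <- seq_len(length(read) - s + 1L)
    seeds <- substring(ors, offs, offs + s - 1L)
    hits <- index$table[.(unique(seeds)), on = "seed", nomatch = NULL]
    if (nrow(hits) == 0L) next
    hits <- merge(hits, data.table::data.table(seed = seeds, off = offs),
                  by = "seed", allow.cartesian = TRUE)
    hits$start <- hits$pos - hits$off + 1L
    hits$strand <- strand
    cands[[length(cands) + 1L]] <- unique(hits[, c("chrom", "start", "strand")])
  }
  if (length(cands) == 0L) return(aln_row("unaligned"))
  cands <- unique(data.table::rbindlist(cands))

  best <- NULL
  placements <- list()
  for (i in seq_len(nrow(cands))) {
    ch <- cands$chrom[i]
    st <- cands$start[i]
    chrom_seq <- index$seqs[[ch]]
    oriented <- if (cands$strand[i] == "+") read
                else Biostrings::reverseComplement(read)
    lo <- max(1L, st)
    hi <- min(length(chrom_seq), st + length(read) - 1L)
    alen <- hi - lo + 1L
    if (alen < params$min_align_length) next
    ref_part <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
    read_part <- substr(as.character(oriented), lo - st + 1L,
                        hi - st + 1L)
    mm <- sum(strsplit(ref_part, "")[[1L]] != strsplit(read_part, "")[[1L]])
    if (mm > params$max_mismatches) next
    placements[[length(placements) + 1L]] <- data.table::data.table(
      chrom = ch, pos = lo, strand = cands$strand[i], nm = mm)
  }
  if (length(placements) == 0L) return(aln_row("unaligned"))
  pl <- unique(data.table::rbindlist(placements))
  best_nm <- min(pl$nm)
  top <- pl[pl$nm == best_nm, ]
  if (nrow(top) == 1L)
    aln_row("unique", top$chrom, top$pos, top$strand, top$nm)
  else
    aln_row("repeat")
}

aln_row <- function(category, chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, nm = NA_integer_,
                    reason = NA_character_) {
  data.table::data.table(category = category, chrom = chrom, pos = pos,
                         strand = strand, nm = nm, reason = reason)
}

#' Map a read set against a masked reference (bulk path)
#'
#' Vectorized seed-and-extend over a whole read set: candidate placements
#' come from exact trusted-band seeds at the two ends of each read (either
#' end suffices, on either orientation), extension is ungapped across the
#' full read with mismatch counting against the hard-masked reference, and
#' classification follows the same unique / repeat / unaligned contract as
#' [map_read()]. Reads overhanging contig ends are not considered (the
#' generator never produces them); [map_read()] is the single-read
#' reference implementation covering that edge.
#'
#' @param reads A [Biostrings::DNAStringSet] of constant-width reads.
#' @param masked_reference A `masked_reference` (hard mask used).
#' @param params An [align_params()].
#' @return data.table with one row per read: `read`, `category`, `chrom`,
#'   `pos`, `strand`, `nm`.
#' @export
map_reads <- function(reads, masked_reference, params = align_params()) {
  seqs <- hard_seqs(masked_reference)
  n <- length(reads)
  if (n == 0L)
    return(data.table::data.table(read = character(), category = character(),
                                  chrom = character(), pos = integer(),
                                  strand = character(), nm = integer()))
  rl <- Biostrings::width(reads)[1L]
  stopifnot(all(Biostrings::width(reads) == rl))
  s <- params$seed_length
  if (rl < s) {
    return(data.table::data.table(read = names(reads), category = "unaligned",
                                  chrom = NA_character_, pos = NA_integer_,
                                  strand = NA_character_, nm = NA_integer_))
  }

  tb_list <- list(c(1L, s), c(rl - s + 1L, rl))
  orientations <- list(`+` = reads, `-` = Biostrings::reverseComplement(reads))

  cand <- list()
  for (strand in names(orientations)) {
    orr <- orientations[[strand]]
    for (tb in tb_list) {
      pd <- Biostrings::PDict(orr, tb.start = tb[1L], tb.end = tb[2L])
      for (ci in seq_along(seqs)) {
        m <- Biostrings::matchPDict(pd, seqs[[ci]],
                                    max.mismatch = params$max_mismatches,
                                    fixed = TRUE)
        st <- Biostrings::startIndex(m)
        hit_n <- lengths(st)
        if (sum(hit_n) == 0L) next
        cand[[length(cand) + 1L]] <- data.table::data.table(
          read_i = rep.int(seq_len(n), hit_n),
          chrom = names(seqs)[ci],
          pos = unlist(st, use.names = FALSE),
          strand = strand)
      }
    }
  }

  res <- data.table::data.table(read = names(reads), category = "unaligned",
                                chrom = NA_character_, pos = NA_integer_,
                                strand = NA_character_, nm = NA_integer_)
  if (length(cand) == 0L) return(res)
  cand <- unique(data.table::rbindlist(cand))

  # count mismatches for every candidate, chunked per (chrom, strand)
  cand$nm <- NA_integer_
  for (ci in names(seqs)) {
    for (strand in c("+", "-")) {
      sel <- which(cand$chrom == ci & cand$strand == strand)
      if (length(sel) == 0L) next
      for (chunk in split(sel, ceiling(seq_along(sel) / 20000L))) {
        v <- Biostrings::Views(seqs[[ci]], start = cand$pos[chunk], width = rl)
        refmat <- as.matrix(as(v, "DNAStringSet"))
        readmat <- as.matrix(orientations[[strand]][cand$read_i[chunk]])
        cand$nm[chunk] <- as.integer(rowSums(refmat != readmat))
      }
    }
  }
  cand <- cand[cand$nm <= params$max_mismatches, ]
  if (nrow(cand) == 0L) return(res)

  data.table::setorder(cand, read_i, nm, chrom, pos)
  best <- cand[, {
    b <- nm[1L]
    ties <- sum(nm == b)
    list(category = if (ties > 1L) "repeat" else "unique",
         chrom = chrom[1L], pos = pos[1L], strand = strand[1L], nm = b)
  }, by = "read_i"]

  res$category[best$read_i] <- best$category
  keep <- best$category == "unique"
  res$chrom[best$read_i[keep]] <- best$chrom[keep]
  res$pos[best$read_i[keep]] <- best$pos[keep]
  res$strand[best$read_i[keep]] <- best$strand[keep]
  res$nm[best$read_i[keep]] <- best$nm[keep]
  res
}

#' Tally read categories
#'
#' @param alignments Output of [map_reads()].
#' @return A list with the per-category counts and the unique fraction.
#' @export
classify_counts <- function(alignments) {
  tally <- c(unique = sum(alignments$category == "unique"),
             `repeat` = sum(alignments$category == "repeat"),
             unaligned = sum(alignments$category == "unaligned"))
  list(tally = tally,
       total = nrow(alignments),
       unique_fraction = if (nrow(alignments)) tally[["unique"]] /
         nrow(alignments) else NA_real_)
}

#' Write alignments as minimal SAM
#'
#' Emits `QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL NM`
#' records: unique reads as plain ungapped matches (FLAG 16 on minus
#' strand), repeat and unaligned reads as unmapped (FLAG 4) so they are
#' excluded from any pileup while remaining auditable.
#'
#' @param alignments Output of [map_reads()] (row order matches `reads`).
#' @param reads The mapped [Biostrings::DNAStringSet].
#' @param masked_reference The reference mapped against (for `@SQ` lines).
#' @param path Output SAM path.
#' @param quality_char Constant base quality character.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, masked_reference, path,
                      quality_char = "I") {
  seqs <- hard_seqs(masked_reference)
  rl <- Biostrings::width(reads)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs),
                      Biostrings::width(seqs)))
  qname <- names(reads)
  if (is.null(qname)) qname <- sprintf("read%06d", seq_along(reads))
  is_uniq <- alignments$category == "unique"
  minus <- is_uniq & alignments$strand == "-"
  seq_out <- as.character(reads)
  if (any(minus))
    seq_out[minus] <- as.character(
      Biostrings::reverseComplement(reads[minus]))
  flag <- ifelse(is_uniq, ifelse(minus, 16L, 0L), 4L)
  rname <- ifelse(is_uniq, alignments$chrom, "*")
  pos <- ifelse(is_uniq, alignments$pos, 0L)
  mapq <- ifelse(is_uniq, 60L, 0L)
  cigar <- ifelse(is_uniq, paste0(rl, "M"), "*")
  qual <- strrep(quality_char, rl)
  nm <- ifelse(is_uniq, paste0("NM:i:", alignments$nm), "NM:i:0")
  body <- paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L,
                seq_out, qual, nm, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
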