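revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' The small molecular-function ontology used by the gene-model generator
#'
#' A miniature is-a hierarchy rooted at molecular_function, with binding,
#' catalytic activity, transporter activity and structural molecule activity
#' as mid-level terms and a handful of leaves beneath them. Enrichment
#' results on synthetic data are expressed in these terms.
#'
#' @return A data.table with columns `go_id`, `parent`, `name`, `namespace`
#'   (`parent` is `NA` for the root).
#' @export
go_ontology <- function() {
  data.table::data.table(
    go_id = c("GO:0003674",
              "GO:0005488", "GO:0003824", "GO:0005215", "GO:0005198",
              "GO:0003677", "GO:0003723", "GO:0046872",
              "GO:0016787", "GO:0016740", "GO:0016491",
              "GO:0022857"),
    parent = c(NA,
               "GO:0003674", "GO:0003674", "GO:0003674", "GO:0003674",
               "GO:0005488", "GO:0005488", "GO:0005488",
               "GO:0003824", "GO:0003824", "GO:0003824",
               "GO:0005215"),
    name = c("molecular_function",
             "binding", "catalytic activity", "transporter activity",
             "structural molecule activity",
             "DNA binding", "RNA binding", "metal ion binding",
             "hydrolase activity", "transferase activity",
             "oxidoreductase activity",
             "transmembrane transporter activity"),
    namespace = "molecular_function")
}

#' Write toy gene models into the synthetic reference
#'
#' Carves non-overlapping protein-coding genes into both homoeologous copies
#' of each chromosome pair: every gene starts with ATG, has stop-free
#' internal codons, ends with a stop codon, and is single- or two-exon on a
#' randomly chosen strand. Gene bodies are written identically into the A
#' and C copies (coding sequence conserved between subgenomes), so
#' homoeolog-divergent sites inside gene spans are removed from the truth
#' table. Genes avoid repeat intervals so their SNPs survive masking.
#'
#' Each gene copy receives 1-5 molecular-function GO terms drawn from
#' [go_ontology()], leaf-biased.
#'
#' @param reference A `reference_set`; returned with gene loci rewritten.
#' @param truth The matching `truth_table`; returned with divergent sites
#'   under gene spans dropped.
#' @param config A [sim_config()]; `config$n_genes` genes are attempted per
#'   chromosome pair (fewer, with a warning, if they do not fit).
#' @return A list: `reference`, `truth`, and `gene_models` (class
#'   `gene_models`: tables `genes`, `cds`, `go_map` plus the `ontology`).
#' @export
generate_gene_models <- function(reference, truth, config) {
  set.seed(stage_seed(config, "genes"))
  onto <- go_ontology()
  leaves <- setdiff(onto$go_id, onto$parent[!is.na(onto$parent)])
  mid <- setdiff(onto$go_id[!is.na(onto$parent)], leaves)

  genes <- list(); cds <- list(); go_map <- list()
  seqs <- lapply(names(reference$sequences), function(ch)
    chrom_seq_chars(reference, ch))
  names(seqs) <- names(reference$sequences)

  for (p in seq_len(nrow(reference$pairs))) {
    pr <- reference$pairs[p, ]
    L <- pr$length
    occupied <- rep(FALSE, L)
    ri <- truth$repeat_intervals[pr$a_chrom, on = "chrom", nomatch = NULL]
    if (nrow(ri)) for (j in seq_len(nrow(ri)))
      occupied[max(1L, ri$start[j] - 100L):min(L, ri$end[j] + 100L)] <- TRUE

    placed <- 0L; tries <- 0L
    while (placed < config$n_genes && tries < 200L * config$n_genes) {
      tries <- tries + 1L
      n_codons <- sample(40:150, 1L)
      cds_len <- 3L * n_codons
      two_exon <- stats::runif(1L) < 0.4
      intron_len <- if (two_exon) sample(60:200, 1L) else 0L
      span <- cds_len + intron_len
      s <- sample.int(L - span - 400L, 1L) + 200L
      e <- s + span - 1L
      if (any(occupied[max(1L, s - 150L):min(L, e + 150L)])) next

      cds_seq <- paste0("ATG",
                        paste(sample(SENSE_CODONS, n_codons - 2L, TRUE),
                              collapse = ""),
                        sample(STOP_CODONS, 1L))
      strand <- sample(c("+", "-"), 1L)
      genomic_cds <- if (strand == "+") cds_seq else revcomp_chr(cds_seq)

      if (two_exon) {
        # split the genomic-orientation CDS; intron sits between the parts
        cut <- sample(seq(30L, cds_len - 30L, by = 1L), 1L)
        exon1 <- substr(genomic_cds, 1L, cut)
        exon2 <- substr(genomic_cds, cut + 1L, cds_len)
        intron <- paste(random_bases(intron_len), collapse = "")
        genomic <- paste0(exon1, intron, exon2)
        exon_tbl <- data.table::data.table(
          start = c(s, s + cut + intron_len),
          end = c(s + cut - 1L, e))
      } else {
        genomic <- genomic_cds
        exon_tbl <- data.table::data.table(start = s, end = e)
      }

      gchars <- strsplit(genomic, "", fixed = TRUE)[[1L]]
      # the C copy diverges at ~homoeolog_divergence of gene positions,
      # constrained to keep its ORF intact (no internal stops, start and
      # terminal codons untouched) so both homoeologs stay translatable
      div <- diverge_gene_copy(gchars, exon_tbl, s, strand,
                               config$homoeolog_divergence)
      for (ch in c(pr$a_chrom, pr$c_chrom)) {
        gid <- sprintf("%s_g%03d", ch, placed + 1L)
        seqs[[ch]][s:e] <- if (ch == pr$c_chrom) div$chars else gchars
        genes[[length(genes) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = ch, start = s, end = e, strand = strand,
          n_codons = n_codons)
        cds[[length(cds) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = ch, start = exon_tbl$start,
          end = exon_tbl$end, strand = strand,
          exon_rank = seq_len(nrow(exon_tbl)))
        n_terms <- sample(1:5, 1L)
        terms <- unique(c(sample(leaves, min(n_terms, length(leaves))),
                          if (n_terms > 2L) sample(mid, 1L)))
        go_map[[length(go_map) + 1L]] <- data.table::data.table(
          gene_id = gid, go_id = terms[seq_len(min(n_terms, length(terms)))])
      }
      # overwriting the locus erases the reference-stage divergence there
      if (nrow(truth$homoeolog_sites))
        truth$homoeolog_sites <- truth$homoeolog_sites[
          !(truth$homoeolog_sites$pair == pr$pair &
              truth$homoeolog_sites$pos >= s &
              truth$homoeolog_sites$pos <= e), ]
      if (length(div$positions)) {
        gp <- s + div$positions - 1L
        truth$homoeolog_sites <- rbind(
          truth$homoeolog_sites,
          data.table::data.table(pair = pr$pair, pos = gp,
                                 a_chrom = pr$a_chrom,
                                 c_chrom = pr$c_chrom,
                                 a_base = gchars[div$positions],
                                 c_base = div$chars[div$positions]))
      }
      occupied[s:e] <- TRUE
      placed <- placed + 1L
    }
    if (placed < config$n_genes)
      warning("only ", placed, " of ", config$n_genes,
              " genes fit on pair ", pr$pair)
  }
  data.table::setorder(truth$homoeolog_sites, pair, pos)

  reference$sequences <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1L), collapse = ""))

  gm <- structure(list(genes = data.table::rbindlist(genes),
                       cds = data.table::rbindlist(cds),
                       go_map = data.table::rbindlist(go_map),
                       ontology = onto),
                  class = "gene_models")
  list(reference = reference, truth = truth, gene_models = gm)
}

# Mutate a gene's C-subgenome copy at ~rate per base while keeping its ORF
# valid: the start and terminal codons are never touched and no internal
# codon may become a stop. `gchars` is the genomic-orientation gene text,
# `exon_tbl` its exon coordinates on the chromosome, `s` the gene start.
# Returns the mutated chars and the 1-based positions (within the gene)
# that differ.
diverge_gene_copy <- function(gchars, exon_tbl, s, strand, rate) {
  out <- gchars
  span <- length(gchars)
  gpos <- unlist(lapply(seq_len(nrow(exon_tbl)), function(i)
    exon_tbl$start[i]:exon_tbl$end[i])) - s + 1L   # CDS, gene-local coords
  cds_len <- length(gpos)
  hit <- which(stats::runif(span) < rate)
  changed <- integer(0L)
  for (g in hit) {
    idx <- match(g, gpos)
    if (is.na(idx)) {                     # intronic: unconstrained
      out[g] <- other_base(out[g])
      changed <- c(changed, g)
      next
    }
    cds_pos <- if (strand == "+") idx else cds_len - idx + 1L
    codon_idx <- (cds_pos - 1L) %/% 3L + 1L
    if (codon_idx == 1L || codon_idx == cds_len %/% 3L) next
    new_gen <- other_base(out[g])
    # rebuild the affected codon in coding orientation from current state
    trial <- out
    trial[g] <- new_gen
    cod_cds_pos <- (codon_idx - 1L) * 3L + 1:3
    cod_gene_pos <- if (strand == "+") gpos[cod_cds_pos]
                    else sort(gpos[cds_len - cod_cds_pos + 1L])
    codon <- paste(trial[cod_gene_pos], collapse = "")
    if (strand == "-") codon <- revcomp_chr(codon)
    if (codon %in% STOP_CODONS) next
    out[g] <- new_gen
    changed <- c(changed, g)
  }
  list(chars = out, positions = changed)
}

#' Spliced coding sequence of one gene
#'
#' Concatenates the gene's CDS exons in genomic order and reverse-complements
#' the result for minus-strand genes, yielding the translatable CDS.
#'
#' @param gene_models A `gene_models` object.
#' @param reference The `reference_set` the models sit on.
#' @param gene_id Gene identifier.
#' @return A [Biostrings::DNAString] starting with ATG and ending in a stop.
#' @export
spliced_cds <- function(gene_models, reference, gene_id) {
  ex <- gene_models$cds[gene_id, on = "gene_id"]
  ex <- ex[order(ex$exon_rank), ]
  chrom <- ex$chrom[1L]
  parts <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(reference$sequences[[chrom]],
                                    ex$start[i], ex$end[i])),
    character(1L))
  s <- Biostrings::DNAString(paste(parts, collapse = ""))
  if (ex$strand[1L] == "-") Biostrings::reverseComplement(s) else s
}

#' Export gene models as GFF3
#'
#' Writes gene and CDS features (1-based inclusive coordinates per the GFF3
#' standard) through [rtracklayer::export.gff3]. GO terms are carried in an
#' `Ontology_term` attribute on gene features.
#'
#' @param gene_models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  g <- gene_models$genes
  go <- gene_models$go_map[, .(terms = paste(go_id, collapse = ",")),
                           by = "gene_id"]
  g <- merge(g, go, by = "gene_id", all.x = TRUE)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand,
    type = "gene", ID = g$gene_id, Ontology_term = g$terms)
  cd <- data.table::copy(gene_models$cds)
  # CDS phase: bases to skip before the first complete codon, accumulated
  # in transcription order (reversed for minus-strand genes)
  cd[, phase := {
    o <- if (strand[1L] == "+") order(exon_rank) else order(-exon_rank)
    lens <- (end - start + 1L)[o]
    ph <- integer(length(lens))
    if (length(lens) > 1L)
      ph[-1L] <- (3L - cumsum(lens)[-length(lens)] %% 3L) %% 3L
    ph[order(o)]
  }, by = "gene_id"]
  gr_cds <- GenomicRanges::GRanges(
    seqnames = cd$chrom,
    ranges = IRanges::IRanges(cd$start, cd$end),
    strand = cd$strand,
    type = "CDS", Parent = cd$gene_id, phase = cd$phase)
  rtracklayer::export.gff3(c(gr_genes, gr_cds), path)
  invisible(path)
}
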