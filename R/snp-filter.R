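#' Thresholds of the four-step SNP filter cascade
#'
#' `min_depth` is the minimum read support for a per-line genotype call
#' (lines below it are missing at the site); `min_minor_accessions` is the
#' minimum number of called lines that must carry the least common allele
#' for a site to be retained (the minor-allele rule); `het_minor_reads` and
#' `het_minor_fraction` define when a line's second-most-common base marks
#' the line heterozygous. The heterozygosity pair is chosen so that a single
#' sequencing error can never trigger heterozygosity at the minimum depth.
#'
#' @param min_depth Minimum per-line read depth for a genotype call.
#' @param min_minor_accessions Minimum called lines carrying each allele.
#' @param het_minor_reads Minimum minor-base reads for heterozygosity.
#' @param het_minor_fraction Minimum minor-base fraction for heterozygosity.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 4L, min_minor_accessions = 2L,
                              het_minor_reads = 2L,
                              het_minor_fraction = 0.1) {
  stopifnot(min_depth > 0L, min_minor_accessions > 0L,
            het_minor_reads > 0L, het_minor_fraction > 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_minor_accessions = as.integer(min_minor_accessions),
                 het_minor_reads = as.integer(het_minor_reads),
                 het_minor_fraction = het_minor_fraction),
            class = "filter_thresholds")
}

#' Build per-accession pileup columns from unique alignments
#'
#' Writes each accession's uniquely aligned reads to BAM (via a minimal SAM)
#' and piles them up with [Rsamtools::pileup], so that reverse-strand reads
#' contribute their bases in reference orientation and `N` calls are
#' discarded. Only `unique`-category reads ever reach the pileup: repeat
#' and unaligned reads are flagged unmapped in the SAM.
#'
#' @param alignments_by_acc Named list (per accession) of [map_reads()]
#'   results.
#' @param reads_by_acc Named list (per accession) of the mapped read sets.
#' @param masked_reference The `masked_reference` mapped against.
#' @return A data.table in long form: `chrom`, `pos`, `acc`, `base`
#'   (A/C/G/T), `count`.
#' @export
pileup_columns <- function(alignments_by_acc, reads_by_acc,
                           masked_reference) {
  stopifnot(identical(names(alignments_by_acc), names(reads_by_acc)))
  out <- list()
  for (a in names(alignments_by_acc)) {
    sam <- tempfile(fileext = ".sam")
    write_sam(alignments_by_acc[[a]], reads_by_acc[[a]], masked_reference,
              sam)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    pp <- Rsamtools::PileupParam(max_depth = 100000L,
                                 min_base_quality = 0L,
                                 min_mapq = 0L,
                                 min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = TRUE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    p <- Rsamtools::pileup(bam, pileupParam = pp)
    file.remove(sam)
    if (nrow(p) == 0L) next
    dt <- data.table::data.table(chrom = as.character(p$seqnames),
                                 pos = p$pos, acc = a,
                                 base = as.character(p$nucleotide),
                                 count = p$count)
    out[[a]] <- dt[dt$base %in% BASES, ]
  }
  if (length(out) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  acc = character(), base = character(),
                                  count = integer()))
  data.table::rbindlist(out)
}

#' Candidate variant sites of a pileup
#'
#' A position becomes a candidate when any accession contributed at least
#' one base different from the reference.
#'
#' @param pile Long-form pileup from [pileup_columns()].
#' @param reference The reference the reads were mapped to.
#' @return `pile` restricted to candidate sites, with a `ref` column added.
#' @export
candidate_sites <- function(pile, reference) {
  if (nrow(pile) == 0L) {
    pile$ref <- character(0L)
    return(pile)
  }
  seqs <- if (inherits(reference, "masked_reference")) reference$dna
          else ref_seqs(reference)
  pile <- data.table::copy(pile)
  pile[, ref := {
    ch <- chrom[1L]
    strsplit(as.character(Biostrings::subseq(
      seqs[[ch]], min(pos), max(pos))), "")[[1L]][pos - min(pos) + 1L]
  }, by = "chrom"]
  keys <- unique(pile[base != ref, c("chrom", "pos")])
  pile[keys, on = c("chrom", "pos")]
}

#' Call one accession's genotype at one pileup column
#'
#' Depth below `min_depth` leaves the line missing; otherwise the line is
#' heterozygous when the second most common base reaches both
#' `het_minor_reads` reads and `het_minor_fraction` of the depth (an exact
#' tie between the top two bases is conservatively heterozygous), else the
#' majority base is called.
#'
#' @param counts Named integer vector of A/C/G/T read counts for one line.
#' @param thresholds A [filter_thresholds()].
#' @return A list: `status` (`called` / `heterozygous` /
#'   `missing_low_depth`), `allele`, `depth`.
#' @export
call_genotype <- function(counts, thresholds = filter_thresholds()) {
  counts <- counts[order(-counts)]
  depth <- sum(counts)
  if (depth < thresholds$min_depth)
    return(list(status = "missing_low_depth", allele = NA_character_,
                depth = depth))
  top <- counts[1L]
  second <- if (length(counts) > 1L) counts[2L] else 0L
  if (second == top ||
      (second >= thresholds$het_minor_reads &&
       second >= thresholds$het_minor_fraction * depth))
    return(list(status = "heterozygous", allele = NA_character_,
                depth = depth))
  list(status = "called", allele = names(counts)[1L], depth = depth)
}

#' Classify a single candidate site from its per-line genotype calls
#'
#' Applies, in order: any heterozygous line rejects the site
#' (`heterozygous_line` - in an inbred panel such sites betray co-piled
#' homoeologs, not allelic heterozygosity); zero called lines reject it
#' (`low_depth`); fewer than two distinct called alleles reject it
#' (`monomorphic`); more than three alleles reject it (`excess_alleles`);
#' and every allele must be carried by at least `min_minor_accessions`
#' called lines (`maf`). Surviving sites are accepted as biallelic or
#' triallelic. The reference base is recorded but never counted as an
#' allele unless some line carries it.
#'
#' @param calls Per-line call list as produced by [call_genotype()] (a list
#'   of lists), or a data.frame with columns `status`, `allele`.
#' @param thresholds A [filter_thresholds()].
#' @return A list: `status` (`accepted`/`rejected`), `reason`, `alleles`
#'   (named carrier counts), `allelism`.
#' @export
filter_site <- function(calls, thresholds = filter_thresholds()) {
  if (is.data.frame(calls)) {
    status <- calls$status; allele <- calls$allele
  } else {
    status <- vapply(calls, `[[`, character(1L), "status")
    allele <- vapply(calls, function(x)
      if (is.na(x$allele)) NA_character_ else x$allele, character(1L))
  }
  if (any(status == "heterozygous"))
    return(site_verdict("rejected", "heterozygous_line"))
  called <- allele[status == "called"]
  if (length(called) == 0L)
    return(site_verdict("rejected", "low_depth"))
  tab <- sort(table(called), decreasing = TRUE)
  if (length(tab) < 2L)
    return(site_verdict("rejected", "monomorphic", tab))
  if (length(tab) > 3L)
    return(site_verdict("rejected", "excess_alleles", tab))
  if (min(tab) < thresholds$min_minor_accessions)
    return(site_verdict("rejected", "maf", tab))
  site_verdict("accepted", NA_character_, tab,
               if (length(tab) == 2L) "biallelic" else "triallelic")
}

site_verdict <- function(status, reason, alleles = NULL,
                         allelism = NA_character_) {
  list(status = status, reason = reason, alleles = alleles,
       allelism = allelism)
}

# Vectorized per-line genotype calling over a long-form candidate pileup.
# Returns one row per (site, accession) with status/allele/depth.
call_genotypes_bulk <- function(cand, thresholds = filter_thresholds()) {
  g <- cand[, {
    o <- order(-count)
    top <- count[o[1L]]
    second <- if (.N > 1L) count[o[2L]] else 0L
    depth <- sum(count)
    status <- if (depth < thresholds$min_depth) "missing_low_depth"
      else if (second == top ||
               (second >= thresholds$het_minor_reads &&
                second >= thresholds$het_minor_fraction * depth))
        "heterozygous"
      else "called"
    list(status = status,
         allele = if (status == "called") base[o[1L]] else NA_character_,
         depth = depth)
  }, by = c("chrom", "pos", "ref", "acc")]
  g
}

#' Run the four-step SNP filter cascade over candidate sites
#'
#' Reproduces the consecutive detection steps of the discovery pipeline:
#' only uniquely aligned reads feed the pileup (upstream), per-line
#' genotypes require at least `min_depth` reads, any line heterozygous
#' rejects the site, and the least common allele must be carried by at
#' least `min_minor_accessions` called lines. Candidate sites that resolve
#' to a single allele after genotype calling are reported as `monomorphic`;
#' sites with more than three called alleles as `excess_alleles`.
#'
#' @param cand Long-form candidate pileup from [candidate_sites()].
#' @param thresholds A [filter_thresholds()].
#' @return A list of class `snp_callset`: `sites` (one row per candidate
#'   site with status, reason, alleles, allelism and per-line calls in long
#'   form under `genotypes`), `accepted` (accepted subset with allele
#'   strings), `report` (counts removed per step, in cascade order).
#' @export
run_cascade <- function(cand, thresholds = filter_thresholds()) {
  if (nrow(cand) == 0L) {
    empty <- data.table::data.table(chrom = character(), pos = integer(),
                                    ref = character(), status = character(),
                                    reason = character(),
                                    allelism = character(),
                                    alleles = character())
    return(structure(list(sites = empty, accepted = empty,
                          genotypes = data.table::data.table(),
                          report = cascade_report(empty)),
                     class = "snp_callset"))
  }
  geno <- call_genotypes_bulk(cand, thresholds)

  sites <- geno[, {
    het <- any(status == "heterozygous")
    called <- allele[status == "called"]
    tab <- sort(table(called), decreasing = TRUE)
    if (het) {
      st <- "rejected"; rs <- "heterozygous_line"; al <- NA_character_
    } else if (length(called) == 0L) {
      st <- "rejected"; rs <- "low_depth"; al <- NA_character_
    } else if (length(tab) < 2L) {
      st <- "rejected"; rs <- "monomorphic"; al <- NA_character_
    } else if (length(tab) > 3L) {
      st <- "rejected"; rs <- "excess_alleles"; al <- NA_character_
    } else if (min(tab) < thresholds$min_minor_accessions) {
      st <- "rejected"; rs <- "maf"; al <- NA_character_
    } else {
      st <- "accepted"; rs <- NA_character_
      al <- if (length(tab) == 2L) "biallelic" else "triallelic"
    }
    list(status = st, reason = rs, allelism = al,
         alleles = paste(names(tab), tab, sep = ":", collapse = ","),
         n_called = length(called))
  }, by = c("chrom", "pos", "ref")]

  structure(list(sites = sites,
                 accepted = sites[status == "accepted"],
                 genotypes = geno,
                 report = cascade_report(sites)),
            class = "snp_callset")
}

cascade_report <- function(sites) {
  steps <- c("low_depth", "heterozygous_line", "monomorphic",
             "excess_alleles", "maf")
  removed <- vapply(steps, function(s)
    sum(sites$reason == s, na.rm = TRUE), integer(1L))
  data.table::data.table(
    step = c(steps, "accepted_biallelic", "accepted_triallelic"),
    sites = c(removed,
              sum(sites$allelism == "biallelic", na.rm = TRUE),
              sum(sites$allelism == "triallelic", na.rm = TRUE)))
}

#' @export
print.snp_callset <- function(x, ...) {
  cat("SNP callset:", nrow(x$sites), "candidate sites,",
      nrow(x$accepted), "accepted\n")
  print(x$report)
  invisible(x)
}

#' False positive rate from validation resequencing counts
#'
#' @param n_validated Number of high-quality validation reads aligned to the
#'   reference.
#' @param n_matching Number of those whose SNP content matched the
#'   predictions.
#' @return The false positive rate `1 - n_matching / n_validated`.
#' @export
validation_fpr <- function(n_validated, n_matching) {
  if (length(n_validated) != 1L || n_validated <= 0L)
    stop("n_validated must be a single positive count")
  if (n_matching < 0L || n_matching > n_validated)
    stop("n_matching must lie in [0, n_validated]")
  1 - n_matching / n_validated
}

#' Write accepted (and optionally rejected) sites as VCF 4.2
#'
#' Positions are 1-based; rejected sites carry their rejection reason in
#' FILTER (audit mode), accepted sites say PASS. Triallelic sites appear as
#' multi-ALT records. Per-accession homozygous genotypes go into GT fields.
#'
#' @param callset A `snp_callset` from [run_cascade()].
#' @param path Output VCF path.
#' @param include_rejected Also write rejected sites (default FALSE).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path, include_rejected = FALSE) {
  sites <- if (include_rejected) callset$sites else callset$accepted
  geno <- data.table::as.data.table(callset$genotypes)
  accs <- sort(unique(geno$acc))
  header <- c("##fileformat=VCFv4.2",
              "##FILTER=<ID=PASS,Description=\"Accepted simple SNP\">",
              paste0("##FILTER=<ID=", c("low_depth", "heterozygous_line",
                                        "monomorphic", "excess_alleles",
                                        "maf"),
                     ",Description=\"Rejected by the filter cascade\">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "FORMAT", accs), collapse = "\t"))
  if (nrow(sites) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  sites <- data.table::as.data.table(sites)[order(chrom, pos)]
  geno <- geno[sites[, c("chrom", "pos")], on = c("chrom", "pos")]

  # per-site allele codes: reference first (code 0), then alternates by
  # descending carrier count
  called <- geno[status == "called",
                 list(n = .N), by = c("chrom", "pos", "allele")]
  called <- merge(called, sites[, c("chrom", "pos", "ref")],
                  by = c("chrom", "pos"))
  data.table::setorder(called, chrom, pos, -n, allele)
  called[, is_ref := allele == ref]
  called[, code := {
    o <- order(!is_ref)          # reference allele (if carried) first
    m <- integer(.N); m[o] <- seq_len(.N) - 1L + as.integer(!any(is_ref))
    m
  }, by = c("chrom", "pos")]
  alts <- called[is_ref == FALSE,
                 list(alt = paste(allele, collapse = ",")),
                 by = c("chrom", "pos")]

  g <- merge(geno, called[, c("chrom", "pos", "allele", "code")],
             by = c("chrom", "pos", "allele"), all.x = TRUE)
  g[, gt := ifelse(status == "called" & !is.na(code),
                   paste0(code, "/", code), "./.")]
  wide <- data.table::dcast(g, chrom + pos ~ acc, value.var = "gt",
                            fill = "./.")
  for (a in setdiff(accs, names(wide))) wide[, (a) := "./."]

  rec <- merge(sites, alts, by = c("chrom", "pos"), all.x = TRUE)
  rec <- merge(rec, wide, by = c("chrom", "pos"))
  data.table::setorder(rec, chrom, pos)
  rec[is.na(alt), alt := "."]
  filt <- ifelse(rec$status == "accepted", "PASS", rec$reason)
  body <- do.call(paste, c(list(rec$chrom, rec$pos, ".", rec$ref, rec$alt,
                                ".", filt, "GT"),
                           lapply(accs, function(a) rec[[a]]),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
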