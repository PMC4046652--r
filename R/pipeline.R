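#' Run the full synthetic SNP-discovery pipeline
#'
#' Executes every stage in order on one seeded configuration: reference and
#' truth-table generation, gene-model insertion, SNP panel planting, read
#' simulation, k-mer repeat masking, unique-alignment read classification,
#' per-accession pileup, the four-step filter cascade, annotation (Ts/Tv,
#' AS-PCR context, coding effects, densities, pairwise counts), GO
#' enrichment of genes carrying non-synonymous SNPs, GoldenGate simulation
#' and analysis, and evaluation of the accepted SNP set against the truth
#' table.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the main tables (VCF,
#'   filter report, density, pairwise matrix, enrichment, GoldenGate
#'   results, metrics, manifest) and reference FASTA/GFF3 are written there.
#' @param thresholds A [filter_thresholds()].
#' @param params An [align_params()].
#' @param mask_k,mask_max_copies K-mer masking parameters.
#' @param verbose Print one line per stage.
#' @return A list of class `pipeline_run` with all intermediate products,
#'   the `metrics` report and the run `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         thresholds = filter_thresholds(),
                         params = align_params(),
                         mask_k = 31L, mask_max_copies = 2L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   started = format(t0), stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    say("[%s] %s", stage, paste(names(list(...)), unlist(list(...)),
                                sep = "=", collapse = " "))
  }

  ref0 <- generate_reference(config)
  note("reference", chromosomes = length(ref0$reference$sequences),
       bp = sum(Biostrings::width(ref0$reference$sequences)),
       homoeolog_sites = nrow(ref0$truth$homoeolog_sites))

  gm <- generate_gene_models(ref0$reference, ref0$truth, config)
  reference <- gm$reference; truth <- gm$truth
  note("genes", genes = nrow(gm$gene_models$genes))

  truth <- generate_panel(reference, truth, config)
  note("panel", planted_snps = nrow(truth$simple_snps),
       expected_pass = sum(truth$simple_snps$expected_pass))

  reads <- simulate_reads(reference, truth, config)
  note("reads", total = sum(vapply(reads, length, integer(1L))))

  mask_iv <- kmer_mask(reference, k = mask_k, max_copies = mask_max_copies)
  masked <- apply_mask(reference, mask_iv, style = "lowercase")
  note("mask", intervals = nrow(mask_iv),
       masked_fraction = round(masked$masked_fraction, 4L))

  alignments <- lapply(reads, map_reads, masked_reference = masked,
                       params = params)
  tall <- data.table::rbindlist(alignments)
  cc <- classify_counts(tall)
  note("align", unique = cc$tally[["unique"]],
       repeat_hits = cc$tally[["repeat"]],
       unaligned = cc$tally[["unaligned"]])

  pile <- pileup_columns(alignments, reads, masked)
  cand <- candidate_sites(pile, reference)
  note("pileup", candidate_sites = nrow(unique(cand[, c("chrom", "pos")])))

  callset <- run_cascade(cand, thresholds)
  note("cascade", accepted = nrow(callset$accepted))

  accepted <- annotate_snps(callset$accepted, reference)
  tstv <- if (any(accepted$allelism == "biallelic"))
    tstv_summary(accepted$allele_a[accepted$allelism == "biallelic"],
                 accepted$allele_b[accepted$allelism == "biallelic"])
  else NULL
  lens <- stats::setNames(Biostrings::width(reference$sequences),
                          names(reference$sequences))
  dens <- density_table(accepted, lens)
  acc_geno <- callset$genotypes[
    callset$accepted[, c("chrom", "pos")], on = c("chrom", "pos")]
  pw <- pairwise_snp_matrix(acc_geno,
                            accessions = accession_ids(config$n_accessions))
  note("annotate",
       transitions = if (is.null(tstv)) 0L else tstv$transitions,
       transversions = if (is.null(tstv)) 0L else tstv$transversions)

  # coding effects: one row per non-reference called allele
  alt_rows <- explode_alt_alleles(accepted)
  effects <- coding_effect(alt_rows, gm$gene_models, reference)
  ns_genes <- unique(effects$gene_id[effects$class %in%
                                       c("nonsynonymous", "stop_gain",
                                         "stop_loss")])
  enrichment <- if (length(ns_genes))
    enrich_all(ns_genes, unique(gm$gene_models$genes$gene_id),
               gm$gene_models$go_map, gm$gene_models$ontology)
  else data.table::data.table()
  note("effects", coding_snps = nrow(effects),
       ns_genes = length(ns_genes))

  gg <- simulate_goldengate(truth, config)
  truth <- gg$truth
  gg_res <- analyze_goldengate(gg)
  hemi_truth <- gg$assays$hemi
  hemi_called <- gg_res$assays$hemi_flag[match(gg$assays$assay,
                                               gg_res$assays$assay)] == "hemi"
  hemi_acc <- mean(hemi_called == hemi_truth, na.rm = TRUE)
  note("goldengate", assays = nrow(gg_res$assays),
       mean_call_rate = round(mean(gg_res$assays$call_rate), 3L),
       hemi_accuracy = hemi_acc)

  metrics <- evaluate_against_truth(callset, truth)
  metrics$hemi_accuracy <- hemi_acc
  metrics$mean_call_rate <- mean(gg_res$assays$call_rate)
  metrics$tstv_ratio <- if (is.null(tstv)) NA_real_ else tstv$ratio
  note("evaluate", precision = round(metrics$precision, 4L),
       recall = round(metrics$recall, 4L))

  manifest$finished <- format(Sys.time())
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  run <- structure(list(config = config, reference = reference,
                        truth = truth, gene_models = gm$gene_models,
                        reads = reads, mask = mask_iv, masked = masked,
                        alignments = alignments, callset = callset,
                        accepted = accepted, tstv = tstv, density = dens,
                        pairwise = pw, effects = effects,
                        enrichment = enrichment, goldengate = gg,
                        goldengate_result = gg_res, metrics = metrics,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

#' Expand accepted sites into one row per non-reference called allele
#' @param accepted Accepted-site table from [run_cascade()].
#' @return data.table with `chrom`, `pos`, `ref`, `alt`.
#' @export
explode_alt_alleles <- function(accepted) {
  if (nrow(accepted) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  rows <- lapply(seq_len(nrow(accepted)), function(i) {
    alleles <- sub(":.*", "", strsplit(accepted$alleles[i], ",")[[1L]])
    alt <- setdiff(alleles, accepted$ref[i])
    if (length(alt) == 0L) return(NULL)
    data.table::data.table(chrom = accepted$chrom[i], pos = accepted$pos[i],
                           ref = accepted$ref[i], alt = alt)
  })
  data.table::rbindlist(rows)
}

config_hash <- function(config) {
  f <- tempfile()
  writeLines(deparse(config[order(names(config))]), f)
  h <- unname(tools::md5sum(f))
  file.remove(f)
  h
}

#' Compare an accepted SNP set against the planted truth
#'
#' True positives are accepted sites planted with every allele carried by
#' at least two accessions (`expected_pass`); planted sites below that bar
#' are expected rejections and never count against recall. False positives
#' are accepted sites never planted; false negatives are expected-pass
#' planted sites that were not accepted, tabulated by the cascade reason
#' that removed them (or `not_candidate` when no pileup evidence reached
#' the cascade).
#'
#' @param callset A `snp_callset` from [run_cascade()].
#' @param truth The `truth_table` of the run.
#' @return A list of class `metrics_report`: `tp`, `fp`, `fn`, `precision`
#'   (reported as 1 with `precision_defined = FALSE` when nothing was
#'   accepted), `recall`, `f1`, `fn_reasons`, `fp_sites`.
#' @export
evaluate_against_truth <- function(callset, truth) {
  planted <- truth$simple_snps
  acc <- callset$accepted[, c("chrom", "pos")]
  exp_pass <- planted[planted$expected_pass == TRUE, ]
  key <- function(d) paste(d$chrom, d$pos)
  tp <- sum(key(acc) %in% key(exp_pass))
  fp <- sum(!key(acc) %in% key(planted))
  fn_sites <- exp_pass[!key(exp_pass) %in% key(acc), ]
  fn <- nrow(fn_sites)
  fn_reasons <- if (fn > 0L) {
    st <- callset$sites
    reasons <- st$reason[match(key(fn_sites), key(st))]
    reasons[is.na(reasons)] <- "not_candidate"
    table(reasons)
  } else table(character(0L))
  precision_defined <- (tp + fp) > 0L
  list_out <- list(
    tp = tp, fp = fp, fn = fn,
    precision = if (precision_defined) tp / (tp + fp) else 1,
    precision_defined = precision_defined,
    recall = if (nrow(exp_pass)) tp / nrow(exp_pass) else NA_real_,
    fn_reasons = fn_reasons,
    fp_sites = acc[!key(acc) %in% key(planted), ])
  list_out$f1 <- if (precision_defined && !is.na(list_out$recall) &&
                     (list_out$precision + list_out$recall) > 0)
    2 * list_out$precision * list_out$recall /
      (list_out$precision + list_out$recall)
  else NA_real_
  class(list_out) <- "metrics_report"
  list_out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics: TP=%d FP=%d FN=%d precision=%.4f recall=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite <- function(x, f)
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_fasta(run$masked, file.path(out_dir, "reference_masked.fasta"))
  write_gff3(run$gene_models, file.path(out_dir, "genes.gff3"))
  write_mask_bed(run$mask, file.path(out_dir, "mask.bed"))
  write_vcf(run$callset, file.path(out_dir, "snps.vcf"),
            include_rejected = FALSE)
  fwrite(run$callset$report, "filter_report.tsv")
  fwrite(run$density$table, "density.tsv")
  utils::write.table(run$pairwise, file.path(out_dir, "pairwise_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  if (nrow(run$enrichment)) fwrite(run$enrichment, "enrichment.tsv")
  fwrite(run$goldengate_result$assays, "goldengate_assays.tsv")
  jsonlite::write_json(
    list(manifest = run$manifest,
         metrics = run$metrics[c("tp", "fp", "fn", "precision", "recall",
                                 "f1", "hemi_accuracy", "mean_call_rate",
                                 "tstv_ratio")]),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}
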