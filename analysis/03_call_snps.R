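#!/usr/bin/env Rscript
# Pile up the uniquely aligned reads per accession and run the four-step
# filter cascade (unique reads only; per-line depth >= 4; no heterozygous
# line; minor allele in >= 2 accessions), then score the accepted set
# against the planted truth.

source("analysis/00_config.R")

masked <- load_cache("masked")
alignments <- load_cache("alignments")
reads <- load_cache("reads")
reference <- load_cache("reference")
truth <- load_cache("truth")

pile <- pileup_columns(alignments, reads, masked)
cand <- candidate_sites(pile, reference)
message(sprintf("pileup: %d candidate variant sites",
                nrow(unique(cand[, c("chrom", "pos")]))))

callset <- run_cascade(cand)
print(callset$report)
write_tsv(callset$report, "filter_report.tsv")
write_vcf(callset, file.path(RESULTS, "snps.vcf"))
write_vcf(callset, file.path(RESULTS, "snps_audit.vcf"),
          include_rejected = TRUE)

metrics <- evaluate_against_truth(callset, truth)
print(metrics)
message("false negatives by cause:")
print(metrics$fn_reasons)
write_tsv(data.frame(metric = c("tp", "fp", "fn", "precision", "recall"),
                     value = c(metrics$tp, metrics$fp, metrics$fn,
                               metrics$precision, metrics$recall)),
          "snp_metrics.tsv")

save_cache(callset, "callset")
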