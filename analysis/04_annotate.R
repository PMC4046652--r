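#!/usr/bin/env Rscript
# Annotate the accepted SNPs: transition/transversion shares, A/T
# AS-PCR-suitable context, per-chromosome densities, pairwise counts
# between accessions, codon-level coding effects and GO enrichment of the
# genes carrying non-synonymous SNPs.

source("analysis/00_config.R")

reference <- load_cache("reference")
callset <- load_cache("callset")
gene_models <- load_cache("gene_models")
cfg <- load_cache("config")

ann <- annotate_snps(callset$accepted, reference)
bi <- ann[ann$allelism == "biallelic", ]
ts <- tstv_summary(bi$allele_a, bi$allele_b)
message(sprintf("Ts/Tv: %.1f%% transitions, %.1f%% transversions, ratio %.2f",
                ts$share_ti, ts$share_tv, ts$ratio))
message(sprintf("A/T SNPs: %d, of which %d AS-PCR suitable",
                sum(ann$at_type), sum(ann$aspcr)))
write_tsv(ann, "annotated_snps.tsv")

lens <- stats::setNames(Biostrings::width(reference$sequences),
                        names(reference$sequences))
dens <- density_table(ann, lens, window = 10000L)
sg <- subgenome_density_summary(dens$table)
message(sprintf("density: %d (A) vs %d (C) SNPs/100kb, ratio %.1f",
                sg$density_A, sg$density_C, sg$ratio_A_over_C))
write_tsv(dens$table, "density.tsv")
write_tsv(dens$windows, "density_windows.tsv")

geno <- callset$genotypes[callset$accepted[, c("chrom", "pos")],
                          on = c("chrom", "pos")]
pw <- pairwise_snp_matrix(geno, accession_ids(cfg$n_accessions))
pws <- pairwise_summary(pw, total_biallelic = nrow(bi))
message(sprintf("pairwise: mean %d, max %d (%s), min %d (%s)",
                pws$mean, pws$max, pws$max_pair, pws$min, pws$min_pair))
utils::write.table(pw, file.path(RESULTS, "pairwise_matrix.tsv"),
                   sep = "\t", quote = FALSE)

alt_rows <- explode_alt_alleles(callset$accepted)
effects <- coding_effect(alt_rows, gene_models, reference)
message(sprintf("coding effects: %s", paste(names(table(effects$class)),
                                            table(effects$class),
                                            sep = "=", collapse = " ")))
write_tsv(effects, "coding_effects.tsv")

ns_genes <- unique(effects$gene_id[effects$class %in%
                                     c("nonsynonymous", "stop_gain",
                                       "stop_loss")])
if (length(ns_genes)) {
  enr <- enrich_all(ns_genes, unique(gene_models$genes$gene_id),
                    gene_models$go_map, gene_models$ontology)
  message("top enrichment: ", enr$name[1], " p=", signif(enr$p[1], 3),
          " (", enr$test_used[1], ")")
  write_tsv(enr, "go_enrichment.tsv")
} else message("no genes with non-synonymous SNPs in this run")
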