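#!/usr/bin/env Rscript
# Generate the synthetic allotetraploid study inputs: reference with
# homoeologous A/C chromosome pairs, toy gene models, the inbred accession
# panel with planted simple SNPs, and per-accession short reads.

source("analysis/00_config.R")

cfg <- analysis_config()
message("simulating with seed ", cfg$seed)

ref0 <- generate_reference(cfg)
gm <- generate_gene_models(ref0$reference, ref0$truth, cfg)
truth <- generate_panel(gm$reference, gm$truth, cfg)
reads <- simulate_reads(gm$reference, truth, cfg)

message(sprintf("reference: %d chromosomes, %d bp; %d homoeolog-divergent sites",
                length(gm$reference$sequences),
                sum(Biostrings::width(gm$reference$sequences)),
                nrow(truth$homoeolog_sites)))
message(sprintf("panel: %d planted simple SNPs (%d expected to survive the filters)",
                nrow(truth$simple_snps), sum(truth$simple_snps$expected_pass)))
message(sprintf("reads: %s total across %d accessions",
                format(sum(vapply(reads, length, integer(1L))), big.mark = ","),
                cfg$n_accessions))

write_fasta(gm$reference, file.path(RESULTS, "reference.fasta"))
write_gff3(gm$gene_models, file.path(RESULTS, "genes.gff3"))
write_tsv(truth$simple_snps, "truth_simple_snps.tsv")
write_tsv(truth$repeat_intervals, "truth_repeat_intervals.tsv")
write_fastq(reads[[1]], file.path(RESULTS, "acc01.fastq"))  # one exhibit

save_cache(cfg, "config")
save_cache(gm$reference, "reference")
save_cache(truth, "truth")
save_cache(gm$gene_models, "gene_models")
save_cache(reads, "reads")
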