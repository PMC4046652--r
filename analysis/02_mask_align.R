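#!/usr/bin/env Rscript
# Mask repetitive sequence by k-mer multiplicity (tolerating the two
# legitimate homoeologous copies) and classify every read as uniquely
# aligned, repeatedly aligned or unaligned under the -v 5 / -l 32 / -s 40
# mapping contract.

source("analysis/00_config.R")

reference <- load_cache("reference")
reads <- load_cache("reads")

mask_iv <- kmer_mask(reference)
masked <- apply_mask(reference, mask_iv, style = "lowercase")
message(sprintf("mask: %d intervals, %.1f%% of the genome",
                nrow(mask_iv), 100 * masked$masked_fraction))
write_mask_bed(mask_iv, file.path(RESULTS, "mask.bed"))
write_fasta(masked, file.path(RESULTS, "reference_masked.fasta"))

alignments <- lapply(reads, map_reads, masked_reference = masked)
tally <- classify_counts(data.table::rbindlist(alignments))
message(sprintf("alignment: %d unique, %d repeat, %d unaligned (%.1f%% unique)",
                tally$tally[["unique"]], tally$tally[["repeat"]],
                tally$tally[["unaligned"]], 100 * tally$unique_fraction))
write_tsv(data.frame(category = names(tally$tally), reads = tally$tally),
          "read_categories.tsv")
write_sam(alignments[[1]], reads[[1]], masked,
          file.path(RESULTS, "acc01.sam"))  # one exhibit

save_cache(masked, "masked")
save_cache(alignments, "alignments")
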