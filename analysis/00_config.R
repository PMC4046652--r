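# Shared configuration of the analysis workflow. Every numbered script
# sources this file; intermediate artifacts are cached under results/cache
# so the steps can be run in sequence (01 -> 06). Delete results/ to start
# over.

library(allosnp)

RESULTS <- "results"
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

# Study-design configuration: two homoeologous chromosome pairs of 60 kb,
# ten inbred accessions at the depth spread of the resequencing panel
# (5.3-37.5x), 100 bp reads with 0.2% base error, 3% homoeolog divergence,
# planted SNP density matching the observed per-chromosome SNP density
# (~1.2 per kb).
ANALYSIS_SEED <- 1L
analysis_config <- function(seed = ANALYSIS_SEED) {
  sim_config(seed = seed, snp_rate = 1.2e-3)
}

cache_path <- function(name) file.path(CACHE, paste0(name, ".rds"))
save_cache <- function(object, name) saveRDS(object, cache_path(name))
load_cache <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p))
    stop("missing cache '", name, "' - run the earlier scripts first")
  readRDS(p)
}
write_tsv <- function(x, name) {
  utils::write.table(x, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("  wrote ", file.path(RESULTS, name))
}
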