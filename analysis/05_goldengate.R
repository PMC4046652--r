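#!/usr/bin/env Rscript
# Simulate and analyze the two-channel genotyping experiment: theta
# clustering per population and pooled, genotype calls with the 0.8
# call-rate exclusion, 1:1 / 1:2:1 segregation tests, replicate
# reproducibility, designability filtering and hemi-SNP detection.

source("analysis/00_config.R")

truth <- load_cache("truth")
cfg <- load_cache("config")

gg <- simulate_goldengate(truth, cfg)
des <- designability_filter(gg$designability$rank_score)
message(sprintf("designability: %d candidates, %d excluded at <= 0.85",
                nrow(des), sum(!des$kept)))

res <- analyze_goldengate(gg)
a <- res$assays
message(sprintf("call rate: %.1f%% mean over %d assays; %d samples excluded",
                100 * mean(a$call_rate), nrow(a),
                length(res$excluded_samples)))
message(sprintf("polymorphic in >= 1 population: %d / %d",
                sum(a$polymorphic), nrow(a)))
message(sprintf("undistorted segregation: DH %d/%d, F2 %d/%d",
                sum(a$seg_p_dh > 0.05, na.rm = TRUE), sum(!is.na(a$seg_p_dh)),
                sum(a$seg_p_f2 > 0.05, na.rm = TRUE), sum(!is.na(a$seg_p_f2))))
truth_hemi <- gg$assays$hemi
called_hemi <- a$hemi_flag[match(gg$assays$assay, a$assay)] == "hemi"
message(sprintf("hemi-SNP detection: %d planted, %d flagged, accuracy %.1f%%",
                sum(truth_hemi), sum(called_hemi, na.rm = TRUE),
                100 * mean(called_hemi == truth_hemi, na.rm = TRUE)))
message(sprintf("reproducibility: %d/%d assays concordant across the triplicate",
                sum(a$reproducible, na.rm = TRUE), sum(!is.na(a$reproducible))))
write_tsv(a, "goldengate_assays.tsv")
write_tsv(res$sample_rates, "goldengate_sample_rates.tsv")
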