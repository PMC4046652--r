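key	value
biallelic_snps	892536
triallelic_snps	267
transition_share_pct	57.5
transversion_share_pct	42.5
at_snps	108270
aspcr_suitable_snps	79533
validation_reads	100
validation_matching	93
chromosome_total_snps	758494
chromosome_total_length	635365519
max_pair_snps	385432
min_pair_snps	30950
density_A_per_100kb	119
density_C_per_100kb	89
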