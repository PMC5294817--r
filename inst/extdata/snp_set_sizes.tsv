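set	n_snps
gwas_ld_universe	191482
snps_under_peaks	574
snps_under_peaks_scored	572
significant_snps	42
consensus_loci	23409
phenotypes_total	930
phenotypes_under_peaks	211
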