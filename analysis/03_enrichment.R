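#!/usr/bin/env Rscript
# Stage 3: per-phenotype hypergeometric enrichment of trait SNPs under
# the consensus cistrome (and under each contributing dataset), with
# Bonferroni correction across the phenotypes tested.
#
# Reads results/tables from stage 2.

suppressMessages(library(cistrovar))
tab_dir <- "results/tables"

assocs <- read_tsv_table(file.path(tab_dir, "associations.tsv"))
assignments <- read_tsv_table(file.path(tab_dir, "assignments.tsv"))
assignments$snp_id <- as.character(assignments$snp_id)
assignments$sources <- as.character(assignments$sources)
ov <- list(assignments = assignments,
           n_snps_under_loci = length(unique(assignments$snp_id)))

set_labels <- sort(unique(unlist(strsplit(assignments$sources, ","))))
enr <- trait_enrichment(assocs, ov, peak_sets = set_labels,
                        m_policy = "tested")
write_tsv_table(enr, file.path(tab_dir, "enrichment.tsv"))

comb <- enr[enr$peak_set == "combined", ]
message("universe N = ", comb$N[1], "; SNPs under peaks n = ", comb$n[1])
message("phenotypes tested (k >= 1): ", comb$m[1])
sig <- comb[comb$p_corrected < 0.05, ]
message(nrow(sig), " trait(s) significant after Bonferroni:")
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-20s K=%-4d k=%-3d p_corrected=%.3g", sig$trait[i],
                  sig$K[i], sig$k[i], sig$p_corrected[i]))
}
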