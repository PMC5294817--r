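#!/usr/bin/env Rscript
# Stage 5: join the SNP sets to the regulatory-score table, tabulate the
# score distribution for the universe / under-peak / significant sets,
# classify "likely to affect TF binding" SNPs, rank co-binding
# transcription factors, and summarize allele-sensitive binding signal
# for one significant SNP.

suppressMessages(library(cistrovar))
fix_dir <- "results/fixtures"
tab_dir <- "results/tables"

reg <- read_reg_scores(file.path(fix_dir, "reg_scores.tsv"))
assocs <- read_tsv_table(file.path(tab_dir, "associations.tsv"))
assignments <- read_tsv_table(file.path(tab_dir, "assignments.tsv"))
enr <- read_tsv_table(file.path(tab_dir, "enrichment.tsv"))
comb <- enr[enr$peak_set == "combined", ]

universe_ids <- unique(assocs$snp_id)
under_ids <- unique(as.character(assignments$snp_id))
sig_rows <- comb[comb$p_corrected < 0.05 & comb$k > 0, ]
sig_ids <- unique(unlist(lapply(
  strsplit(sig_rows$snps_under_peaks, ",", fixed = TRUE),
  function(p) sub("/.*$", "", p))))

dist <- score_distribution(list(universe = universe_ids,
                                under_peaks = under_ids,
                                significant = sig_ids), reg)
write_tsv_table(dist, file.path(tab_dir, "score_distribution.tsv"))
for (set in c("universe", "under_peaks", "significant")) {
  ids <- list(universe = universe_ids, under_peaks = under_ids,
              significant = sig_ids)[[set]]
  cls <- classify_likely_affecting(reg[reg$snp_id %in% ids, ])
  message(sprintf("%-12s %4d SNPs, %3d likely-affecting (%.1f%%)", set,
                  length(ids), cls$n_likely,
                  100 * cls$fraction_likely))
}

# enrichment of likely-affecting status in the significant set vs the
# universe background (one-tailed Fisher)
cls_sig <- classify_likely_affecting(reg[reg$snp_id %in% sig_ids, ])
cls_bg <- classify_likely_affecting(reg[reg$snp_id %in% universe_ids, ])
p_fisher <- fisher_exact_one_tailed(
  cls_sig$n_likely, cls_sig$n_other,
  cls_bg$n_likely - cls_sig$n_likely,
  cls_bg$n_other - cls_sig$n_other)
message("one-tailed Fisher, significant vs background likely-affecting: p = ",
        signif(p_fisher, 3))

tf <- tf_cooccurrence(cls_sig$likely$snp_id, reg)
write_tsv_table(tf, file.path(tab_dir, "tf_frequency.tsv"))
if (nrow(tf) > 0) {
  message("top co-binding TFs: ",
          paste(utils::head(paste0(tf$tf, " (", tf$n_snps, ")"), 5),
                collapse = ", "))
}

# allele-sensitive binding at one site (Fig.-3c-style summary)
cfg <- sim_config(seed = 11)
gb <- sim_genotype_binding(cfg, af = 0.3, n_samples = 20,
                           base_signal = 10, noise_sd = 1)
summ <- binding_by_genotype(gb$genotypes, gb$signals)
write_tsv_table(summ$classes, file.path(tab_dir,
                                        "genotype_binding.tsv"))
message("binding by genotype: ",
        paste(sprintf("%s n=%d mean=%.2f", summ$classes$class,
                      summ$classes$n, summ$classes$mean),
              collapse = "; "),
        " -> ", summ$monotonicity, " with alt dosage")
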