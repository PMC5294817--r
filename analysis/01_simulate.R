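#!/usr/bin/env Rscript
# Stage 1: generate the complete synthetic study (haplotype panel with LD
# blocks, GWAS-style catalog with one planted enriched trait, two ChIP-seq
# peak sets, genome sequence with planted DR3 motifs, regulatory scores,
# and a second cistrome for the co-binding comparison), written in the
# same external formats a real study would arrive in.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(cistrovar))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 11L
fix_dir <- "results/fixtures"
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

# 10 traits of 5 lead SNPs over 500 panel sites: most sites enter the
# universe only as LD proxies, as in a real catalog; the planted trait's
# whole LD neighborhoods are covered so its signal survives proxy
# expansion
cfg <- sim_config(seed = seed, genome_length_bp = 2e6, n_blocks = 50,
                  block_size_bp = 20000, sites_per_block = 10,
                  n_haplotypes = 120, n_peaks = 300,
                  peak_width_mean = 400, peak_width_sd = 80,
                  n_traits = 10, snps_per_trait = 5,
                  enrichment_factor = 8, motif_plant_count = 40,
                  plant_ld_neighborhood = TRUE)

panel <- sim_panel(cfg)
message("panel: ", nrow(panel$haplotypes), " haplotypes x ",
        nrow(panel$sites), " sites; MAF range ",
        paste(round(range(allele_freq(panel)), 3), collapse = "-"))

cp <- sim_catalog_and_peaks(cfg, panel)
message("catalog: ", nrow(cp$catalog), " associations over ",
        length(unique(cp$catalog$trait)), " traits; planted trait '",
        cfg$planted_trait, "' at ", cfg$enrichment_factor,
        "x background coverage")

cons0 <- merge_consensus(cp$peak_sets)
snps0 <- unique(cp$catalog[c("snp_id", "chrom", "pos")])
sq <- sim_sequences_with_motifs(cfg, cons0, motif_model(), snps = snps0)
panel <- harmonize_panel_to_genome(panel, sq$genome)
message("planted ", nrow(sq$truth), " DR3 motifs, ",
        sum(!is.na(sq$truth$snp_id)), " overlapping catalog SNPs")

for (i in seq_along(cp$peak_sets)) {
  write_bed(cp$peak_sets[[i]],
            file.path(fix_dir, sprintf("peaks_%s.bed",
                                       peak_set_name(cp$peak_sets[[i]]))))
}
write_gwas_catalog(cp$catalog, file.path(fix_dir, "catalog.tsv"))
write_panel_vcf(panel, file.path(fix_dir, "panel.vcf"))
write_genome_fasta(sq$genome, file.path(fix_dir, "genome.fa"))
write_tsv_table(sq$truth, file.path(fix_dir, "truth_motifs.tsv"))
write_tsv_table(cp$truth, file.path(fix_dir, "truth_coverage.tsv"))
write_tsv_table(sim_reg_scores(cfg, cp$catalog$snp_id),
                file.path(fix_dir, "reg_scores.tsv"))

# an independent second cistrome (e.g. another TF's consensus peaks)
other_cfg <- cfg
other_cfg$seed <- seed + 1L
other_cfg$enrichment_factor <- 1
other <- sim_catalog_and_peaks(other_cfg, sim_panel(other_cfg))
write_bed(merge_consensus(other$peak_sets),
          file.path(fix_dir, "other_cistrome.bed"))

message("fixtures written under ", fix_dir)
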