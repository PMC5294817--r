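#!/usr/bin/env Rscript
# Stage 2: build the consensus cistrome from the individual peak sets,
# expand GWAS lead SNPs with LD proxies from the phased panel
# (r2 >= 0.8, MAF >= 0.05, +/- 500 kb), and assign the expanded SNP
# universe to consensus loci.
#
# Reads results/fixtures, writes results/tables.

suppressMessages(library(cistrovar))
fix_dir <- "results/fixtures"
tab_dir <- "results/tables"
dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)

bed_files <- list.files(fix_dir, pattern = "^peaks_.*\\.bed$",
                        full.names = TRUE)
sets <- lapply(bed_files, read_bed)
consensus <- merge_consensus(sets)
write_bed(consensus, file.path(tab_dir, "consensus.bed"))
message("consensus cistrome: ", length(consensus),
        " non-overlapping loci from ", length(sets), " datasets (",
        sum(GenomicRanges::width(consensus)), " bp covered)")

catalog <- read_gwas_catalog(file.path(fix_dir, "catalog.tsv"))
panel <- read_panel_vcf(file.path(fix_dir, "panel.vcf"))
leads <- catalog[!duplicated(catalog$snp_id),
                 c("snp_id", "chrom", "pos")]
snps <- expand_leads(leads, panel, ld_config())
write_tsv_table(snps, file.path(tab_dir, "snps.tsv"))
message(nrow(leads), " lead SNPs expanded to ",
        length(unique(snps$snp_id)), " distinct lead+proxy SNPs (",
        sum(snps$provenance == "PROXY"), " proxy relationships)")

# proxies inherit the traits of their lead
assoc <- merge(catalog[c("trait", "snp_id")],
               snps[c("snp_id", "lead_id")],
               by.x = "snp_id", by.y = "lead_id")
assoc <- data.frame(trait = assoc$trait, snp_id = assoc$snp_id.y,
                    lead_id = assoc$snp_id)
assoc <- assoc[!duplicated(assoc[c("trait", "snp_id")]), ]
assoc <- assoc[order(assoc$trait, assoc$snp_id), ]
write_tsv_table(assoc, file.path(tab_dir, "associations.tsv"))

ov <- overlap_snps(snps[!duplicated(snps$snp_id), ], consensus)
write_tsv_table(ov$assignments, file.path(tab_dir, "assignments.tsv"))
message(ov$n_snps_under_loci, " distinct SNPs fall under consensus loci")
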