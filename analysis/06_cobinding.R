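#!/usr/bin/env Rscript
# Stage 6: intersect the consensus cistrome with a second cistrome under
# the 25%-of-locus fractional-overlap criterion (query-fraction
# convention; rerun with reciprocal = TRUE for the stricter mutual
# criterion), and count significant SNPs falling in the shared loci.

suppressMessages(library(cistrovar))
tab_dir <- "results/tables"
fix_dir <- "results/fixtures"

consensus <- read_bed(file.path(tab_dir, "consensus.bed"),
                      name = "consensus")
names(S4Vectors::mcols(consensus))[1] <- "sources"
other <- read_bed(file.path(fix_dir, "other_cistrome.bed"),
                  name = "other")

cb <- fractional_intersect(consensus, other, min_fraction = 0.25)
write_tsv_table(data.frame(n_shared = cb$n_shared,
                           n_only_a = cb$n_only_a,
                           n_only_b = cb$n_only_b,
                           min_fraction = cb$min_fraction,
                           reciprocal = cb$reciprocal),
                file.path(tab_dir, "cobinding.tsv"))
write_bed(cb$shared_loci, file.path(tab_dir, "shared_loci.bed"))
message(cb$n_shared, " of ", cb$n_shared + cb$n_only_a,
        " consensus loci shared with the second cistrome at >= 25% overlap")

# SNPs from significant traits falling in the shared loci
snps <- read_tsv_table(file.path(tab_dir, "snps.tsv"))
snps <- snps[!duplicated(snps$snp_id), ]
ov <- overlap_snps(snps, cb$shared_loci)
message(ov$n_snps_under_loci, " universe SNPs fall in shared loci")

rec <- fractional_intersect(consensus, other, min_fraction = 0.25,
                            reciprocal = TRUE)
message("reciprocal criterion: ", rec$n_shared, " shared loci")
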