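# Small in-code fixture builders shared across tests.

# panel from an explicit haplotype matrix, sites spaced every `gap` bp
tiny_panel <- function(haps, gap = 100, chrom = "chr1") {
  n_sites <- ncol(haps)
  sites <- data.frame(
    snp_id = paste0("s", seq_len(n_sites)),
    chrom = chrom,
    pos = seq(0, by = gap, length.out = n_sites),
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  haplotype_panel(sites, haps)
}

# random peak set on one chromosome with small coordinates
random_peak_set <- function(n, name, max_coord = 1000, max_width = 60) {
  start <- sample.int(max_coord - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(chrom = "chr1", start = start, end = start + width, name = name)
}

# a small but complete simulated study used by several suites
small_sim <- function(seed = 11, enrichment_factor = 5) {
  cfg <- sim_config(seed = seed, genome_length_bp = 2e5, n_blocks = 10,
                    block_size_bp = 10000, sites_per_block = 10,
                    n_haplotypes = 60, n_peaks = 60, peak_width_mean = 300,
                    peak_width_sd = 50, n_traits = 10, snps_per_trait = 5,
                    enrichment_factor = enrichment_factor,
                    motif_plant_count = 10,
                    plant_ld_neighborhood = TRUE)
  panel <- sim_panel(cfg)
  cp <- sim_catalog_and_peaks(cfg, panel)
  list(cfg = cfg, panel = panel, catalog = cp$catalog,
       peak_sets = cp$peak_sets, truth = cp$truth)
}

# write a complete fixture directory for the pipeline driver and return
# its pipeline_config
pipeline_fixture <- function(dir, seed = 11) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- small_sim(seed = seed)
  model <- motif_model()
  cons <- merge_consensus(sim$peak_sets)
  snps <- unique(sim$catalog[c("snp_id", "chrom", "pos")])
  sq <- sim_sequences_with_motifs(sim$cfg, cons, model, snps = snps)
  panel <- harmonize_panel_to_genome(sim$panel, sq$genome)
  beds <- character(0)
  for (i in seq_along(sim$peak_sets)) {
    p <- file.path(dir, sprintf("peaks_%d.bed", i))
    write_bed(sim$peak_sets[[i]], p)
    beds[peak_set_name(sim$peak_sets[[i]])] <- p
  }
  catalog_path <- file.path(dir, "catalog.tsv")
  write_gwas_catalog(sim$catalog, catalog_path)
  vcf_path <- file.path(dir, "panel.vcf")
  write_panel_vcf(panel, vcf_path)
  fasta_path <- file.path(dir, "genome.fa")
  write_genome_fasta(sq$genome, fasta_path)
  reg <- sim_reg_scores(sim$cfg, sim$catalog$snp_id)
  reg_path <- file.path(dir, "reg_scores.tsv")
  write_tsv_table(reg, reg_path)
  # second cistrome for the intersection stage
  other_cfg <- sim_config(seed = seed + 1000, genome_length_bp = 2e5,
                          n_blocks = 10, block_size_bp = 10000,
                          sites_per_block = 10, n_haplotypes = 60,
                          n_peaks = 60, peak_width_mean = 300,
                          peak_width_sd = 50, n_traits = 10,
                          snps_per_trait = 5, enrichment_factor = 1)
  other <- sim_catalog_and_peaks(other_cfg, sim_panel(other_cfg))
  other_path <- file.path(dir, "other_cistrome.bed")
  write_bed(merge_consensus(other$peak_sets), other_path)
  pipeline_config(beds = beds, catalog = catalog_path,
                  panel_vcf = vcf_path, genome_fasta = fasta_path,
                  reg_scores = reg_path, cobinding_bed = other_path,
                  seed = seed)
}

extdata <- function(f) system.file("extdata", f, package = "cistrovar")
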