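test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 42, genome_length_bp = 1e5, n_blocks = 5,
                    block_size_bp = 20000, n_peaks = 30, n_traits = 5,
                    snps_per_trait = 5, n_haplotypes = 40,
                    enrichment_factor = 2, motif_plant_count = 5)
  p1 <- sim_panel(cfg)
  p2 <- sim_panel(cfg)
  expect_identical(p1, p2)
  c1 <- sim_catalog_and_peaks(cfg, p1)
  c2 <- sim_catalog_and_peaks(cfg, p1)
  expect_identical(c1, c2)
  model <- motif_model()
  loci <- merge_consensus(c1$peak_sets)
  s1 <- sim_sequences_with_motifs(cfg, loci, model)
  s2 <- sim_sequences_with_motifs(cfg, loci, model)
  expect_identical(s1, s2)
  # substreams are independent: drawing the panel twice does not move
  # the catalog stream
  sim_panel(cfg)
  expect_identical(sim_catalog_and_peaks(cfg, p1), c1)
})

test_that("substream seeds are distinct, stable and below 2^31", {
  s <- vapply(c("panel", "catalog_peaks", "sequences", "reg_scores",
                "genotype_binding"),
              function(nm) substream_seed(123, nm), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(substream_seed(123, "panel"),
                   substream_seed(123, "panel"))
})

test_that("panel blocks give high within-block and null cross-block LD", {
  within_med <- cross_mean <- numeric(0)
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_haplotypes = 200, n_blocks = 6,
                      block_size_bp = 20000, sites_per_block = 8,
                      genome_length_bp = 2e5, n_peaks = 10, n_traits = 2,
                      snps_per_trait = 2, enrichment_factor = 1)
    panel <- sim_panel(cfg)
    blk <- panel$sites$block
    w <- c()
    for (b in unique(blk)) {
      idx <- which(blk == b)
      prs <- utils::combn(idx, 2)
      w <- c(w, apply(prs, 2, function(p) r2(panel, p[1], p[2])))
    }
    within_med <- c(within_med, stats::median(w, na.rm = TRUE))
    idx1 <- which(blk == 1)
    idx2 <- which(blk == 2)
    x <- as.vector(outer(idx1, idx2,
                         Vectorize(function(i, j) r2(panel, i, j))))
    cross_mean <- c(cross_mean, mean(x, na.rm = TRUE))
  }
  expect_gt(stats::median(within_med), 0.8)
  expect_lt(mean(cross_mean), 0.05)
})

test_that("site MAFs straddle the proxy filter threshold", {
  cfg <- sim_config(seed = 9, n_blocks = 30, sites_per_block = 10,
                    block_size_bp = 10000, genome_length_bp = 3e5,
                    n_haplotypes = 100, n_peaks = 10, n_traits = 2,
                    snps_per_trait = 2, enrichment_factor = 1)
  maf <- allele_freq(sim_panel(cfg))
  expect_gt(sum(maf < 0.05), 0)
  expect_gt(sum(maf >= 0.05), 0)
})

test_that("the simulated truth file matches the package's own overlap
          computation", {
  sim <- small_sim(seed = 31)
  loci <- merge_consensus(sim$peak_sets)
  ov <- overlap_snps(unique(sim$catalog[c("snp_id", "chrom", "pos")]),
                     loci)
  covered_pkg <- sim$truth$snp_id[sim$truth$snp_id %in%
                                    ov$assignments$snp_id]
  expect_setequal(covered_pkg, sim$truth$snp_id[sim$truth$covered])
})

test_that("at enrichment factor 1 the planted trait is covered at the
          background rate", {
  # pooled binomial check across replicates
  n_cov <- n_tot <- 0
  p_cov <- NULL
  cfg0 <- sim_config(seed = 1, genome_length_bp = 1e6, n_blocks = 20,
                     block_size_bp = 20000, sites_per_block = 10,
                     n_haplotypes = 20, n_peaks = 200, n_traits = 10,
                     snps_per_trait = 20, enrichment_factor = 1)
  panel <- sim_panel(cfg0)
  p_cov <- cfg0$n_peaks * cfg0$peak_width_mean / cfg0$genome_length_bp
  for (seed in 1:50) {
    cfg <- cfg0
    cfg$seed <- 60000 + seed
    cp <- sim_catalog_and_peaks(cfg, panel)
    pl <- cp$truth[cp$truth$planted, ]
    n_cov <- n_cov + sum(pl$covered)
    n_tot <- n_tot + nrow(pl)
  }
  se <- sqrt(p_cov * (1 - p_cov) / n_tot)
  expect_lt(abs(n_cov / n_tot - p_cov), 3 * se)
})

test_that("an over-demanding enrichment factor is rejected", {
  cfg <- sim_config(seed = 1, n_peaks = 500, peak_width_mean = 500,
                    genome_length_bp = 1e6, enrichment_factor = 10,
                    n_traits = 2, snps_per_trait = 2)
  expect_error(sim_catalog_and_peaks(cfg, sim_panel(cfg)), "> 1")
})

test_that("planted motif ground truth is found by the scanner, on either
          strand, with matching SNP positions", {
  sim <- small_sim(seed = 17)
  model <- motif_model()
  loci <- merge_consensus(sim$peak_sets)
  snps <- unique(sim$catalog[c("snp_id", "chrom", "pos")])
  sq <- sim_sequences_with_motifs(sim$cfg, loci, model, snps = snps)
  hits <- scan_loci(sq$genome, loci, model, flank_from_midpoint = NULL)
  tr <- sq$truth
  key_h <- paste(hits$chrom, hits$start, hits$strand)
  expect_true(all(paste(tr$chrom, tr$start, tr$strand) %in% key_h))
  # plus- and minus-strand plants score identically (consensus plant)
  sc <- hits$score[match(paste(tr$chrom, tr$start, tr$strand), key_h)]
  expect_true(all(abs(sc - model$max_score) < 1e-9))
  # SNP-overlapping plants annotate at the recorded in-motif position
  with_snp <- tr[!is.na(tr$snp_id), ]
  if (nrow(with_snp) > 0) {
    ann <- snp_in_motif(snps, hits)
    for (i in seq_len(nrow(with_snp))) {
      row <- ann[ann$snp_id == with_snp$snp_id[i] &
                   ann$start == with_snp$start[i] &
                   ann$strand == with_snp$strand[i], ]
      expect_equal(row$position_in_motif, with_snp$position_in_motif[i])
    }
  }
})

test_that("genotype-binding simulation honours its degenerate settings", {
  cfg <- sim_config(seed = 4)
  noiseless <- sim_genotype_binding(cfg, af = 0.5, n_samples = 40,
                                    base_signal = 8, noise_sd = 0)
  alt_hom <- noiseless$signals[noiseless$genotypes == 2]
  expect_true(all(alt_hom == 0))
  all_ref <- sim_genotype_binding(cfg, af = 0, n_samples = 10)
  expect_true(all(all_ref$genotypes == 0))
})
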