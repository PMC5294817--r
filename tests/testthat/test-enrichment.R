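test_that("upper tail matches enumeration on small worked cases", {
  # k = 0 is the whole sample space
  expect_equal(hypergeom_upper_tail(100, 10, 20, 0), 1)
  # N=10, K=4, n=5, k=3: (C(4,3)C(6,2) + C(4,4)C(6,1)) / C(10,5) = 66/252
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3), 66 / 252,
               tolerance = 1e-14)
  # GWAS-scale marginals agree with the exact big-integer oracle
  got <- hypergeom_upper_tail(191482, 1874, 78, 4)
  expect_equal(got, hyper_upper_exact(191482, 1874, 78, 4),
               tolerance = 1e-12)
})

test_that("upper tail agrees with the exact rational oracle on a
          randomized grid (N <= 200)", {
  set.seed(2024)
  grid <- do.call(rbind, lapply(1:60, function(i) {
    N <- sample(5:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    data.frame(N = N, K = K, n = n, k = k)
  }))
  grid <- grid[grid$k >= 1, ]
  exact <- hyper_upper_exact(grid$N, grid$K, grid$n, grid$k)
  got <- mapply(hypergeom_upper_tail, grid$N, grid$K, grid$n, grid$k)
  expect_true(all(abs(got - exact) / exact < 1e-12))
  # and with base R's phyper as a second, independent cross-check
  ph <- phyper(grid$k - 1, grid$K, grid$N - grid$K, grid$n,
               lower.tail = FALSE)
  expect_equal(got, ph, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("upper tail is monotone in k and symmetric in (K, n)", {
  set.seed(31)
  for (rep in 1:20) {
    N <- sample(20:150, 1)
    K <- sample.int(N - 1, 1)
    n <- sample.int(N - 1, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    p <- vapply(ks, function(k) hypergeom_upper_tail(N, K, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    k <- sample(ks, 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 hypergeom_upper_tail(N, n, K, k), tolerance = 1e-12)
  }
})

test_that("inconsistent counts are rejected", {
  expect_error(hypergeom_upper_tail(10, 4, 5, 6), "inconsistent")
  expect_error(hypergeom_upper_tail(10, 2, 5, 3), "inconsistent")
  expect_error(hypergeom_upper_tail(10, 9, 9, 0), "inconsistent")
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(1e-4, 1), 1e-4)
  expect_equal(bonferroni(0.01, 211), 1)
  expect_equal(bonferroni(1e-6, 211), 2.11e-4)
})

test_that("one-tailed Fisher matches enumeration and fisher.test", {
  expect_equal(fisher_exact_one_tailed(1, 0, 0, 1), 0.5)
  # identical row proportions carry no enrichment signal
  expect_gte(fisher_exact_one_tailed(5, 5, 5, 5), 0.5)
  # 15/42 likely-affecting vs a 17% background of 1000
  got <- fisher_exact_one_tailed(15, 27, 170, 830)
  ft <- fisher.test(rbind(c(15, 27), c(170, 830)),
                    alternative = "greater")$p.value
  expect_equal(got, ft, tolerance = 1e-10)
  expect_lt(got, 0.05)  # the focal set is visibly enriched
  expect_error(fisher_exact_one_tailed(0, 0, 0, 0), "all-zero")
})

test_that("trait enrichment counts deduplicated sets and ranks a fully
          contained trait first", {
  # universe of 20 SNPs, trait T has 5, the peak holds 4 of them
  assocs <- data.frame(
    trait = c(rep("T", 5), rep("U", 15)),
    snp_id = paste0("rs", 1:20),
    lead_id = paste0("rs", 1:20))
  loci <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A")))
  snps <- data.frame(snp_id = paste0("rs", 1:20), chrom = "chr1",
                     pos = c(1:4, 200 + 1:16))
  ov <- overlap_snps(snps, loci)
  res <- trait_enrichment(assocs, ov)
  row_t <- res[res$trait == "T" & res$peak_set == "combined", ]
  expect_equal(row_t$N, 20)
  expect_equal(row_t$K, 5)
  expect_equal(row_t$n, 4)
  expect_equal(row_t$k, 4)
  expect_equal(row_t$p_raw, hyper_upper_exact(20, 5, 4, 4),
               tolerance = 1e-12)
  expect_equal(res$trait[1], "T")
  # trait with nothing under peaks reports p = 1
  row_u <- res[res$trait == "U" & res$peak_set == "combined", ]
  expect_equal(row_u$k, 0)
  expect_equal(row_u$p_raw, 1)
  expect_equal(row_u$p_corrected, 1)
})

test_that("duplicated trait associations do not change the result", {
  assocs <- data.frame(trait = c("T", "T", "U"),
                       snp_id = c("a", "a", "b"),
                       lead_id = c("a", "a", "b"))
  loci <- merge_consensus(list(peak_set("chr1", 0, 10, name = "A")))
  ov <- overlap_snps(data.frame(snp_id = c("a", "b"), chrom = "chr1",
                                pos = c(5, 50)), loci)
  res <- trait_enrichment(assocs, ov)
  expect_equal(res$K[res$trait == "T" & res$peak_set == "combined"], 1)
  expect_equal(res$N[1], 2)
})

test_that("per-peak-set counting uses the locus source lists", {
  sets <- list(peak_set("chr1", 0, 100, name = "A"),
               peak_set("chr1", 200, 300, name = "B"))
  loci <- merge_consensus(sets)
  assocs <- data.frame(trait = c("T", "T"), snp_id = c("x", "y"),
                       lead_id = c("x", "y"))
  ov <- overlap_snps(data.frame(snp_id = c("x", "y"), chrom = "chr1",
                                pos = c(50, 250)), loci)
  res <- trait_enrichment(assocs, ov, peak_sets = c("A", "B"))
  expect_equal(res$n[res$peak_set == "A"], 1)
  expect_equal(res$n[res$peak_set == "B"], 1)
  expect_equal(res$n[res$peak_set == "combined"], 2)
})

test_that("empty universe is rejected", {
  expect_error(trait_enrichment(
    data.frame(trait = character(0), snp_id = character(0)),
    list(assignments = data.frame(snp_id = character(0),
                                  sources = character(0)))),
    "empty")
})

test_that("null simulations keep the raw-p false-positive rate at or
          below nominal", {
  # uniform SNP placement, random trait labels; the hypergeometric test
  # is conservative through discreteness
  n_rep <- 200
  hits <- 0L
  total <- 0L
  cfg0 <- sim_config(seed = 1, genome_length_bp = 1e6, n_blocks = 20,
                     block_size_bp = 20000, sites_per_block = 10,
                     n_haplotypes = 20, n_peaks = 100, n_traits = 20,
                     snps_per_trait = 10, enrichment_factor = 1)
  panel <- sim_panel(cfg0)
  for (seed in seq_len(n_rep)) {
    cfg <- cfg0
    cfg$seed <- 50000 + seed
    cp <- sim_catalog_and_peaks(cfg, panel)
    loci <- merge_consensus(cp$peak_sets)
    ov <- overlap_snps(unique(cp$catalog[c("snp_id", "chrom", "pos")]),
                       loci)
    res <- trait_enrichment(cp$catalog, ov)
    res <- res[res$peak_set == "combined", ]
    hits <- hits + sum(res$p_raw < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(rate, 0.05 + 2 * se)
})
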