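test_that("consensus merge handles identity, union and half-open abutment", {
  # already-disjoint single set passes through with one source each
  a <- peak_set("chr1", c(0, 200), c(100, 300), name = "A")
  cons <- merge_consensus(list(a))
  expect_equal(bed0(cons)$start, c(0, 200))
  expect_equal(bed0(cons)$end, c(100, 300))
  expect_equal(S4Vectors::mcols(cons)$sources, c("A", "A"))

  # overlapping spans from two datasets fuse into one locus with both
  # sources
  b <- peak_set("chr1", 50, 150, name = "B")
  cons <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A"), b))
  expect_equal(length(cons), 1L)
  expect_equal(bed0(cons)[, c("start", "end")],
               data.frame(start = 0L, end = 150L))
  expect_equal(S4Vectors::mcols(cons)$sources, "A,B")

  # abutting half-open intervals share zero bp and must not merge
  cons <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A"),
                               peak_set("chr1", 100, 200, name = "B")))
  expect_equal(length(cons), 2L)
  expect_equal(S4Vectors::mcols(cons)$sources, c("A", "B"))
})

test_that("malformed intervals are rejected with the offending record", {
  expect_error(peak_set("chr1", c(0, 50), c(100, 50), name = "A"),
               "record\\(s\\) 2")
  expect_error(granges0("chr1", -5, 10), "record\\(s\\) 1")
})

test_that("consensus merge matches a naive pairwise-union oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n_sets <- sample(2:4, 1)
    sets <- lapply(seq_len(n_sets), function(i) {
      random_peak_set(sample(5:40, 1), name = paste0("S", i))
    })
    cons <- bed0(merge_consensus(sets))
    pooled <- do.call(rbind, lapply(sets, function(s) {
      bed0(s)[c("chrom", "start", "end")]
    }))
    oracle <- naive_union(pooled$chrom, pooled$start, pooled$end)
    expect_equal(cons$start, oracle$start)
    expect_equal(cons$end, oracle$end)
    # covered bp is preserved by merging
    expect_equal(sum(cons$end - cons$start),
                 naive_covered_bp(pooled$start, pooled$end))
    # output loci are pairwise non-overlapping
    expect_true(all(diff(cons$start) > 0))
    expect_true(all(cons$start[-1] >= cons$end[-length(cons$end)]))
  }
})

test_that("SNP assignment respects half-open boundaries and deduplicates", {
  loci <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A"),
                               peak_set("chr1", 50, 120, name = "B"),
                               peak_set("chr2", 0, 50, name = "A")))
  snps <- data.frame(snp_id = c("in", "at_end", "at_start", "off_chrom"),
                     chrom = c("chr1", "chr1", "chr1", "chr9"),
                     pos = c(50, 120, 0, 10))
  ov <- overlap_snps(snps, loci)
  expect_setequal(ov$assignments$snp_id, c("in", "at_start"))
  expect_equal(ov$n_snps_under_loci, 2L)

  # 3 SNPs, 2 under loci, one of them in a locus shared by two datasets:
  # deduplicated count stays 2
  snps2 <- data.frame(snp_id = c("a", "b", "c"),
                      chrom = "chr1", pos = c(60, 10, 500))
  ov2 <- overlap_snps(snps2, loci)
  expect_equal(ov2$n_snps_under_loci, 2L)
  expect_equal(sort(unique(ov2$assignments$snp_id)), c("a", "b"))
  expect_equal(ov2$assignments$sources[ov2$assignments$snp_id == "a"],
               "A,B")
})

test_that("SNP assignment agrees with an exhaustive linear scan", {
  set.seed(7)
  for (rep in 1:30) {
    sets <- list(random_peak_set(sample(5:25, 1), "A"),
                 random_peak_set(sample(5:25, 1), "B"))
    loci <- merge_consensus(sets)
    snps <- data.frame(snp_id = paste0("rs", 1:40), chrom = "chr1",
                       pos = sample.int(1000, 40) - 1L)
    ov <- overlap_snps(snps, loci)
    oracle <- naive_snp_scan(snps, bed0(loci))
    got <- ov$assignments[order(ov$assignments$snp_id,
                                ov$assignments$locus_index),
                          c("snp_id", "locus_index")]
    want <- oracle[order(oracle$snp_id, oracle$locus_index), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("fractional intersection is reflexive and boundary-inclusive", {
  a <- merge_consensus(list(peak_set("chr1", c(0, 500), c(100, 700),
                                     name = "A")))
  # A = B: everything shared at any threshold
  for (f in c(0.01, 0.25, 1)) {
    cb <- fractional_intersect(a, a, min_fraction = f)
    expect_equal(cb$n_shared, 2L)
    expect_equal(cb$n_only_a, 0L)
    expect_equal(cb$n_shared + cb$n_only_a, length(a))
  }
  # exactly 25% of a 100-bp locus overlapped passes at 0.25 (inclusive)
  b <- merge_consensus(list(peak_set("chr1", 75, 200, name = "B")))
  one <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A")))
  expect_equal(fractional_intersect(one, b, 0.25)$n_shared, 1L)
  # but fails at 0.26
  expect_equal(fractional_intersect(one, b, 0.26)$n_shared, 0L)
})

test_that("fractional intersection is monotone and matches any-overlap at
          tiny thresholds", {
  set.seed(13)
  for (rep in 1:20) {
    a <- merge_consensus(list(random_peak_set(sample(5:30, 1), "A")))
    b <- merge_consensus(list(random_peak_set(sample(5:30, 1), "B")))
    fr <- c(1e-9, 0.1, 0.25, 0.5, 0.75, 1)
    shared <- vapply(fr, function(f) {
      fractional_intersect(a, b, f)$n_shared
    }, numeric(1))
    expect_true(all(diff(shared) <= 0))
    any_overlap <- sum(IRanges::overlapsAny(
      GenomicRanges::ranges(a), GenomicRanges::ranges(b)))
    expect_equal(shared[1], any_overlap)
    cb <- fractional_intersect(a, b, 0.25)
    expect_equal(cb$n_shared + cb$n_only_a, length(a))
    expect_equal(cb$n_shared_b + cb$n_only_b, length(b))
  }
})

test_that("empty inputs yield zero counts without error", {
  a <- merge_consensus(list(peak_set("chr1", 0, 100, name = "A")))
  empty <- a[0]
  cb <- fractional_intersect(empty, a, 0.25)
  expect_equal(cb$n_shared, 0L)
  expect_equal(cb$n_only_a, 0L)
  cb2 <- fractional_intersect(a, empty, 0.25)
  expect_equal(cb2$n_shared, 0L)
  expect_equal(cb2$n_only_a, 1L)
})

test_that("reciprocal mode is at most as permissive as query mode", {
  set.seed(99)
  for (rep in 1:10) {
    a <- merge_consensus(list(random_peak_set(20, "A")))
    b <- merge_consensus(list(random_peak_set(20, "B")))
    q <- fractional_intersect(a, b, 0.25)
    r <- fractional_intersect(a, b, 0.25, reciprocal = TRUE)
    expect_lte(r$n_shared, q$n_shared)
  }
})
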