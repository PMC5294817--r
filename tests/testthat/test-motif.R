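test_that("model construction enforces PWM invariants and zero-weight
          spacer", {
  m <- motif_model()
  expect_equal(colSums(m$half_site_pwm), rep(1, 6), ignore_attr = TRUE)
  expect_equal(m$width, 15L)
  expect_equal(spacer_positions(m), 7:9)
  expect_equal(m$lods[, 7:9], matrix(0, 4, 3), ignore_attr = TRUE)
  expect_equal(consensus_sequence(m, full = FALSE), "AGGTCA")
  expect_error(motif_model(half_site_pwm = matrix(0.3, 4, 6)),
               "sum to 1")
})

test_that("a planted consensus motif is found exactly once under a
          strict threshold", {
  m <- motif_model()
  m$score_threshold <- m$max_score - 1e-9
  seq <- paste0(strrep("T", 10), "AGGTCAAAGAGGTCA", strrep("T", 10))
  hits <- scan_motifs(seq, m)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10)
  expect_equal(hits$end, 25)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, m$max_score, tolerance = 1e-9)

  # reverse complement of the same sequence: one minus-strand hit at the
  # mirrored coordinates with an identical score
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  hits_rc <- scan_motifs(rc, m)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  expect_equal(hits_rc$start, nchar(seq) - hits$end)
})

test_that("N-containing windows and too-short sequences produce no hits", {
  m <- motif_model()
  expect_equal(nrow(scan_motifs(strrep("N", 60), m)), 0L)
  expect_equal(nrow(scan_motifs("ACGT", m)), 0L)
})

test_that("window scores are additive over columns (brute-force
          rescoring)", {
  set.seed(8)
  m <- motif_model()
  m$score_threshold <- -Inf
  seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  hits <- scan_motifs(seq, m, both_strands = FALSE)
  brute <- brute_window_score(seq, m$lods)
  expect_equal(hits$score, brute[hits$start + 1], tolerance = 1e-12)
  expect_equal(nrow(hits), length(brute))
})

test_that("SNP-in-motif positions follow the hit orientation", {
  hits <- data.frame(chrom = "chr1", start = 100, end = 115,
                     strand = c("+", "-"), score = 10,
                     sequence = "AGGTCAAAGAGGTCA")
  snps <- data.frame(snp_id = c("first", "mid", "plus2"),
                     chrom = "chr1", pos = c(100, 110, 102))
  ann <- snp_in_motif(snps, hits)
  plus <- ann[ann$strand == "+", ]
  expect_equal(plus$position_in_motif[plus$snp_id == "first"], 1L)
  expect_equal(plus$position_in_motif[plus$snp_id == "mid"], 11L)
  minus <- ann[ann$strand == "-", ]
  expect_equal(minus$position_in_motif[minus$snp_id == "plus2"], 13L)
  expect_equal(minus$position_in_motif[minus$snp_id == "first"], 15L)
})

test_that("delta LOD equals the single-column closed form and is zero in
          the spacer", {
  m <- motif_model()
  ctx <- paste0(strrep("C", 5), "AGGTCAAAGAGGTCA", strrep("C", 5))
  hit <- data.frame(chrom = "chr1", start = 5, end = 20, strand = "+")
  # same allele: identity
  expect_equal(delta_lod(m, ctx, list(snp_id = "x", pos = 6, ref = "G",
                                      alt = "G"), hit), 0)
  # spacer SNP (in-motif positions 7-9): zero by construction
  for (pos in 11:13) {
    expect_equal(delta_lod(m, ctx, list(snp_id = "x", pos = pos,
                                        ref = substring(ctx, pos + 1,
                                                        pos + 1),
                                        alt = "C"), hit), 0)
  }
  # consensus base replaced by the lowest-probability base at a scored
  # column: delta equals the column log-odds difference
  col2 <- m$lods[, 2]
  want <- col2["A"] - col2["G"]
  got <- delta_lod(m, ctx, list(snp_id = "x", pos = 6, ref = "G",
                                alt = "A"), hit)
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_lt(got, 0)
  # rescoring both full windows must match for every scored column, on
  # both strands
  hit_m <- transform(hit, strand = "-")
  for (offset in c(0, 4, 10, 14)) {
    pos <- 5 + offset
    ref <- substring(ctx, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      dp <- delta_lod(m, ctx, list(snp_id = "x", pos = pos, ref = ref,
                                   alt = alt), hit)
      col <- offset + 1
      closed <- m$lods[alt, col] - m$lods[ref, col]
      expect_equal(dp, unname(closed), tolerance = 1e-12)
      dm <- delta_lod(m, ctx, list(snp_id = "x", pos = pos, ref = ref,
                                   alt = alt), hit_m)
      col_m <- 15 - offset
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      closed_m <- m$lods[comp[alt], col_m] - m$lods[comp[ref], col_m]
      expect_equal(dm, unname(closed_m), tolerance = 1e-12)
    }
  }
})

test_that("delta LOD rejects reference mismatches with the position", {
  m <- motif_model()
  ctx <- strrep("A", 30)
  hit <- data.frame(chrom = "chr1", start = 5, end = 20, strand = "+")
  expect_error(delta_lod(m, ctx, list(snp_id = "rsX", pos = 10, ref = "G",
                                      alt = "T"), hit),
               "mismatch.*rsX.*10")
})

test_that("planted near-consensus motifs are fully recovered at the 80%
          threshold with few background false hits", {
  set.seed(77)
  m <- motif_model()  # default threshold is 0.8 * max_score
  n_seq <- 100
  found <- logical(n_seq)
  bg_hits <- 0
  bg_bp <- 0
  for (i in seq_len(n_seq)) {
    bg <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    offset <- sample.int(200 - 15, 1)
    seq <- paste(c(bg[1:offset], strsplit("AGGTCAAAGAGGTCA", "")[[1]],
                   bg[(offset + 16):200]), collapse = "")
    hits <- scan_motifs(seq, m)
    found[i] <- any(hits$start == offset & hits$strand == "+")
    pure_bg <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                     collapse = "")
    bg_hits <- bg_hits + nrow(scan_motifs(pure_bg, m))
    bg_bp <- bg_bp + 500
  }
  expect_true(all(found))
  # false-hit rate per window stays below the exact i.i.d. expectation
  # (both strands => 2x the per-window tail), with Poisson slack
  p_win <- exact_score_tail(m$lods, m$background, m$score_threshold)
  expected <- 2 * p_win * bg_bp
  expect_lte(bg_hits, expected + 3 * sqrt(expected) + 3)
})

test_that("PWM files round-trip and normalize counts", {
  path <- tempfile(fileext = ".pwm")
  write_pwm(dr3_default_pwm(), path, name = "test_half")
  back <- read_pwm(path)
  expect_equal(unclass(back), dr3_default_pwm(),
               ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(attr(back, "name"), "test_half")
  writeLines(c("A [ 2 0 ]", "C [ 0 2 ]", "G [ 1 1 ]", "T [ 1 1 ]"),
             path)
  counts <- read_pwm(path)
  expect_equal(colSums(counts), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(counts["A", 1]), 0.5)
})

test_that("the shipped PWM file reproduces the default model", {
  pwm <- read_pwm(extdata("dr3_halfsite.pwm"))
  expect_equal(unclass(pwm), dr3_default_pwm(), ignore_attr = TRUE,
               tolerance = 1e-7)
})
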