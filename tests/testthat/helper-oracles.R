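# Independent oracles used across the suite. Each is deliberately naive
# and kept free of the package's own code paths.

# Exact rational upper-tail hypergeometric probability via python's
# big-integer Fraction arithmetic; float conversion is correctly rounded,
# so values are exact to ~1e-16 relative.
hyper_upper_exact <- function(N, K, n, k) {
  grid <- data.frame(N = N, K = K, n = n, k = k)
  script <- paste(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin:",
    "    parts = line.split()",
    "    if not parts: continue",
    "    N, K, n, k = map(int, parts)",
    "    num = sum(comb(K, j) * comb(N - K, n - j)",
    "              for j in range(k, min(K, n) + 1))",
    "    print(repr(float(Fraction(num, comb(N, n)))))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)),
                 input = apply(grid, 1, paste, collapse = " "),
                 stdout = TRUE)
  as.numeric(out)
}

# O(n^2) pairwise interval-union oracle on 0-based half-open intervals
naive_union <- function(chrom, start, end) {
  res <- list()
  for (ch in unique(chrom)) {
    s <- start[chrom == ch]
    e <- end[chrom == ch]
    merged <- list()
    for (i in seq_along(s)) {
      cur <- c(s[i], e[i])
      repeat {
        hit <- 0
        for (j in seq_along(merged)) {
          m <- merged[[j]]
          if (cur[1] < m[2] && m[1] < cur[2]) { hit <- j; break }
        }
        if (hit == 0) break
        m <- merged[[hit]]
        cur <- c(min(cur[1], m[1]), max(cur[2], m[2]))
        merged[[hit]] <- NULL
      }
      merged[[length(merged) + 1]] <- cur
    }
    ms <- vapply(merged, `[`, numeric(1), 1)
    me <- vapply(merged, `[`, numeric(1), 2)
    o <- order(ms)
    res[[ch]] <- data.frame(chrom = ch, start = ms[o], end = me[o])
  }
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

# per-bp covered length (coordinates must be small)
naive_covered_bp <- function(start, end, limit = 5000) {
  covered <- logical(limit)
  for (i in seq_along(start)) {
    covered[(start[i] + 1):end[i]] <- TRUE
  }
  sum(covered)
}

# exhaustive per-SNP linear scan against loci
naive_snp_scan <- function(snps, loci_df) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(loci_df))) {
      if (snps$chrom[i] == loci_df$chrom[j] &&
          snps$pos[i] >= loci_df$start[j] &&
          snps$pos[i] < loci_df$end[j]) {
        hits[[length(hits) + 1]] <- data.frame(snp_id = snps$snp_id[i],
                                               locus_index = j)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(snp_id = character(0), locus_index = integer(0)))
  }
  do.call(rbind, hits)
}

# brute-force per-window motif rescoring
brute_window_score <- function(sequence, lods) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(lods)
  vapply(seq_len(length(chars) - w + 1), function(i) {
    total <- 0
    for (cc in seq_len(w)) {
      b <- match(chars[i + cc - 1], bases)
      if (is.na(b)) return(NA_real_)
      total <- total + lods[b, cc]
    }
    total
  }, numeric(1))
}

# exact distribution of a scan score under i.i.d. background: returns
# P(score >= threshold) by discrete convolution over columns
exact_score_tail <- function(lods, background, threshold) {
  dist <- c(`0` = 1)
  for (cc in seq_len(ncol(lods))) {
    new <- list()
    for (s in names(dist)) {
      for (b in 1:4) {
        v <- round(as.numeric(s) + lods[b, cc], 9)
        key <- as.character(v)
        new[[key]] <- (new[[key]] %||% 0) + dist[[s]] * background[b]
      }
    }
    dist <- unlist(new)
  }
  sum(dist[as.numeric(names(dist)) >= threshold - 1e-9])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
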