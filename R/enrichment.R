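# Per-phenotype hypergeometric enrichment of trait SNPs under peaks, with
# Bonferroni correction, plus the one-tailed 2x2 Fisher comparison.

# log hypergeometric pmf: P(X = j) for population N with K successes and
# n draws
.lhyper_pmf <- function(j, N, K, n) {
  lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability that at least \code{k} of \code{n} SNPs drawn without
#' replacement from a universe of \code{N} (of which \code{K} belong to the
#' trait) belong to the trait. Computed by summing the pmf in log space
#' (numerically safe for N up to 1e7); the tail is inclusive of \code{k}.
#'
#' @param N universe size; @param K trait SNPs in the universe;
#' @param n SNPs drawn (under peaks); @param k observed trait SNPs drawn.
#' @return probability in (0, 1]; \code{k = 0} returns exactly 1.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  .check_hyper(N, K, n, k)
  if (k <= 0) return(1)
  js <- k:min(K, n)
  if (length(js) == 0 || k > min(K, n)) {
    stop("inconsistent counts: k=", k, " exceeds min(K, n)=", min(K, n),
         call. = FALSE)
  }
  lp <- .lhyper_pmf(js, N, K, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Lower-tail hypergeometric probability P(X <= k)
#' @inheritParams hypergeom_upper_tail
#' @return probability in (0, 1].
#' @export
hypergeom_lower_tail <- function(N, K, n, k) {
  .check_hyper(N, K, n, k)
  js <- max(0, n - (N - K)):k
  lp <- .lhyper_pmf(js, N, K, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

.check_hyper <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (!(k >= 0 && n >= k && N >= n && K >= k && N >= K)) {
    stop("inconsistent counts: need 0 <= k <= n <= N and k <= K <= N (got N=",
         N, ", K=", K, ", n=", n, ", k=", k, ")", call. = FALSE)
  }
  if (n - k > N - K) {
    stop("inconsistent counts: n - k = ", n - k,
         " non-trait draws exceed N - K = ", N - K, call. = FALSE)
  }
  invisible(TRUE)
}

#' Bonferroni correction
#' @param p_raw raw p-value(s).
#' @param m number of tests (>= 1).
#' @return \code{min(1, m * p_raw)}, vectorized over \code{p_raw}.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

#' One-tailed Fisher's exact test for enrichment
#'
#' For the 2x2 table \code{rbind(c(a, b), c(c, d))} with row 1 the focal
#' set and column 1 the property of interest, returns the exact one-tailed
#' (enrichment-direction) probability of observing at least \code{a}
#' property-positive members at fixed margins, i.e. the upper hypergeometric
#' tail at population \code{a+b+c+d}, successes \code{a+c}, draws
#' \code{a+b}.
#'
#' @param a,b,c_,d_ non-negative cell counts.
#' @return one-tailed probability.
#' @export
fisher_exact_one_tailed <- function(a, b, c_, d_) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d_ >= 0)
  if (a + b + c_ + d_ == 0) stop("all-zero 2x2 table", call. = FALSE)
  hypergeom_upper_tail(N = a + b + c_ + d_, K = a + c_, n = a + b, k = a)
}

#' Per-phenotype enrichment of trait SNPs under peak-set loci
#'
#' For each (trait, peak set) pair, counts the deduplicated SNP universe
#' \code{N}, trait SNPs \code{K}, SNPs under the peak set's loci \code{n}
#' and trait SNPs under them \code{k}, and computes the upper-tail
#' hypergeometric probability (and the lower tail, for
#' under-representation) with Bonferroni correction across phenotypes.
#' A SNP counts once toward N and n however many leads or traits it
#' relates to, and once per trait toward K.
#'
#' @param assocs data.frame of trait associations: \code{trait},
#'   \code{snp_id}, \code{lead_id}; the deduplicated snp_id set is the
#'   universe N.
#' @param overlap output of [overlap_snps()] against consensus loci (its
#'   \code{assignments} carry the loci's \code{sources}).
#' @param peak_sets character vector of peak-set labels to test
#'   individually; \code{"combined"} (always included first) uses every
#'   locus.
#' @param m_policy \code{"tested"} corrects across phenotypes with at least
#'   one SNP under the peak set's loci; \code{"all"} across every phenotype
#'   in \code{assocs}.
#' @return data.frame sorted by \code{p_corrected}: trait, peak_set, N, K,
#'   n, k, p_raw, p_under, m, p_corrected, snps_under_peaks (comma-joined
#'   "snp/lead" pairs, Table-1 style).
#' @export
trait_enrichment <- function(assocs, overlap, peak_sets = "combined",
                             m_policy = c("tested", "all")) {
  m_policy <- match.arg(m_policy)
  stopifnot(all(c("trait", "snp_id") %in% names(assocs)))
  if (!"lead_id" %in% names(assocs)) assocs$lead_id <- assocs$snp_id
  assocs <- assocs[!duplicated(assocs[c("trait", "snp_id")]), , drop = FALSE]
  universe <- unique(assocs$snp_id)
  N <- length(universe)
  if (N == 0) stop("empty SNP universe", call. = FALSE)
  asg <- overlap$assignments
  peak_sets <- unique(c("combined", peak_sets))
  traits <- unique(assocs$trait)
  res <- list()
  for (ps in peak_sets) {
    if (ps == "combined") {
      under <- unique(asg$snp_id)
    } else {
      in_set <- vapply(strsplit(asg$sources, ",", fixed = TRUE),
                       function(s) ps %in% s, logical(1))
      under <- unique(asg$snp_id[in_set])
    }
    under <- intersect(under, universe)
    n <- length(under)
    snps_by_trait <- split(assocs$snp_id, assocs$trait)
    leads_by_trait <- split(assocs$lead_id, assocs$trait)
    trait_rows <- lapply(traits, function(tr) {
      tsnps <- snps_by_trait[[tr]]
      K <- length(tsnps)
      hit <- intersect(tsnps, under)
      k <- length(hit)
      p_raw <- if (k == 0) 1 else hypergeom_upper_tail(N, K, n, k)
      p_under <- hypergeom_lower_tail(N, K, n, k)
      leads <- leads_by_trait[[tr]][match(hit, tsnps)]
      data.frame(trait = tr, peak_set = ps, N = N, K = K, n = n, k = k,
                 p_raw = p_raw, p_under = p_under,
                 snps_under_peaks = paste(paste0(hit, "/", leads),
                                          collapse = ","),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, trait_rows)
    m <- if (m_policy == "tested") max(1L, sum(tab$k >= 1)) else
      length(traits)
    tab$m <- m
    tab$p_corrected <- bonferroni(tab$p_raw, m)
    res[[ps]] <- tab
  }
  out <- do.call(rbind, res)
  out <- out[order(out$p_corrected, out$p_raw, out$trait), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[c("trait", "peak_set", "N", "K", "n", "k", "p_raw", "p_under", "m",
        "p_corrected", "snps_under_peaks")]
}
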