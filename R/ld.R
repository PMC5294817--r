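# Phased-haplotype allele frequencies, pairwise r2 and lead-SNP proxy
# expansion.

#' Construct a phased haplotype panel
#'
#' @param sites data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (0-based bp), \code{ref}, \code{alt}; one row per biallelic
#'   site.
#' @param haplotypes integer/logical matrix of allele codes in \{0,1\}; one
#'   row per haplotype, one column per site.
#' @return object of class \code{HaplotypePanel}.
#' @export
haplotype_panel <- function(sites, haplotypes) {
  stopifnot(is.data.frame(sites),
            all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(sites)))
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (ncol(haplotypes) != nrow(sites)) {
    stop("haplotype matrix has ", ncol(haplotypes),
         " columns but sites table has ", nrow(sites), " rows", call. = FALSE)
  }
  if (nrow(haplotypes) < 2) stop("need >= 2 haplotypes", call. = FALSE)
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype codes must be 0/1 (biallelic)", call. = FALSE)
  }
  sites$chrom <- normalize_chrom(sites$chrom)
  structure(list(sites = sites, haplotypes = haplotypes),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat("HaplotypePanel:", nrow(x$haplotypes), "haplotypes x",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Alternate-allele frequency at panel sites
#' @param panel a [haplotype_panel()].
#' @param site_index site index (vectorized).
#' @return alt-allele fraction in [0, 1].
#' @export
alt_freq <- function(panel, site_index = seq_len(nrow(panel$sites))) {
  stopifnot(all(site_index >= 1), all(site_index <= nrow(panel$sites)))
  colMeans(panel$haplotypes[, site_index, drop = FALSE])
}

#' Minor allele frequency at panel sites
#'
#' \code{maf = min(f, 1 - f)} with f the alt-allele fraction; monomorphic
#' sites return 0.
#'
#' @inheritParams alt_freq
#' @return MAF in [0, 0.5].
#' @export
allele_freq <- function(panel, site_index = seq_len(nrow(panel$sites))) {
  f <- alt_freq(panel, site_index)
  pmin(f, 1 - f)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Gametic (haplotype) r2: \eqn{r^2 = D^2 / (p_i q_i p_j q_j)} with
#' \eqn{D = f_{11} - p_i p_j}, where \eqn{f_{11}} is the frequency of
#' haplotypes carrying the alt allele at both sites. If either site is
#' monomorphic the quantity is undefined and \code{NA} is returned
#' (distinct from 0). The \code{"dosage"} method instead pairs consecutive
#' haplotype rows into diploid individuals and returns the squared Pearson
#' correlation of alt-allele dosages (fallback for effectively unphased
#' data).
#'
#' @param panel a [haplotype_panel()].
#' @param i,j site indices.
#' @param method "haplotype" (default) or "dosage".
#' @return r2 in [0, 1], or NA if undefined.
#' @export
r2 <- function(panel, i, j, method = c("haplotype", "dosage")) {
  method <- match.arg(method)
  h <- panel$haplotypes
  if (method == "dosage") {
    if (nrow(h) %% 2 != 0) stop("dosage r2 needs an even number of haplotypes",
                                call. = FALSE)
    idx <- seq(1, nrow(h), by = 2)
    di <- h[idx, i] + h[idx + 1, i]
    dj <- h[idx, j] + h[idx + 1, j]
    if (stats::sd(di) == 0 || stats::sd(dj) == 0) return(NA_real_)
    return(stats::cor(di, dj)^2)
  }
  pi_ <- mean(h[, i])
  pj_ <- mean(h[, j])
  if (pi_ %in% c(0, 1) || pj_ %in% c(0, 1)) return(NA_real_)
  f11 <- mean(h[, i] == 1L & h[, j] == 1L)
  d <- f11 - pi_ * pj_
  min(1, d^2 / (pi_ * (1 - pi_) * pj_ * (1 - pj_)))
}

# r2 of one site against many, vectorized (haplotype method)
.r2_vec <- function(panel, i, js) {
  h <- panel$haplotypes
  pi_ <- mean(h[, i])
  if (pi_ %in% c(0, 1)) return(rep(NA_real_, length(js)))
  pj_ <- colMeans(h[, js, drop = FALSE])
  f11 <- colMeans(h[, i] * h[, js, drop = FALSE])
  d <- f11 - pi_ * pj_
  out <- d^2 / (pi_ * (1 - pi_) * pj_ * (1 - pj_))
  out[pj_ %in% c(0, 1)] <- NA_real_
  pmin(1, out)
}

#' Thresholds for LD proxy expansion
#'
#' @param r2_min minimum r2 with the lead (inclusive), default 0.8.
#' @param maf_min minimum proxy MAF, default 0.05 (leads are exempt).
#' @param window_bp half-window around the lead, default 500,000 (i.e.
#'   proxies are sought within +/- 500 kb).
#' @return list of class \code{LdConfig}.
#' @export
ld_config <- function(r2_min = 0.8, maf_min = 0.05, window_bp = 500000) {
  stopifnot(r2_min > 0, r2_min <= 1, maf_min >= 0, maf_min < 0.5,
            window_bp > 0)
  structure(list(r2_min = r2_min, maf_min = maf_min, window_bp = window_bp),
            class = "LdConfig")
}

#' Expand GWAS lead SNPs with LD proxies from a haplotype panel
#'
#' For every lead found in the panel, all panel sites within
#' \code{+/- window_bp} on the same chromosome with \code{r2 >= r2_min}
#' against the lead and \code{maf >= maf_min} are returned as proxies
#' carrying (lead_id, r2) provenance. Leads are retained regardless of
#' their own MAF; leads absent from the panel are retained with no proxies
#' and collected in the \code{unmatched} attribute (with a warning).
#'
#' @param leads data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (0-based); extra columns are ignored.
#' @param panel a [haplotype_panel()].
#' @param cfg an [ld_config()].
#' @param method r2 estimator passed to [r2()].
#' @return data.frame of SNP records: snp_id, chrom, pos, ref, alt, maf,
#'   provenance ("LEAD"/"PROXY"), lead_id (self for leads), r2 (1 for
#'   leads, NA for unmatched leads). One row per (snp, lead) relationship;
#'   deduplicate on snp_id for the SNP universe.
#' @export
expand_leads <- function(leads, panel, cfg = ld_config(),
                         method = c("haplotype", "dosage")) {
  method <- match.arg(method)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(leads)))
  leads <- leads[!duplicated(leads$snp_id), , drop = FALSE]
  leads$chrom <- normalize_chrom(leads$chrom)
  sites <- panel$sites
  maf <- allele_freq(panel)
  out <- vector("list", nrow(leads))
  unmatched <- character(0)
  for (li in seq_len(nrow(leads))) {
    lead <- leads[li, ]
    idx <- match(lead$snp_id, sites$snp_id)
    if (is.na(idx)) {
      idx <- which(sites$chrom == lead$chrom & sites$pos == lead$pos)[1]
    }
    if (is.na(idx)) {
      unmatched <- c(unmatched, lead$snp_id)
      out[[li]] <- data.frame(
        snp_id = lead$snp_id, chrom = lead$chrom, pos = lead$pos,
        ref = NA_character_, alt = NA_character_, maf = NA_real_,
        provenance = "LEAD", lead_id = lead$snp_id, r2 = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    lead_row <- data.frame(
      snp_id = sites$snp_id[idx], chrom = sites$chrom[idx],
      pos = sites$pos[idx], ref = sites$ref[idx], alt = sites$alt[idx],
      maf = maf[idx], provenance = "LEAD", lead_id = sites$snp_id[idx],
      r2 = 1, stringsAsFactors = FALSE)
    cand <- which(sites$chrom == sites$chrom[idx] &
                    abs(sites$pos - sites$pos[idx]) <= cfg$window_bp)
    cand <- setdiff(cand, idx)
    cand <- cand[maf[cand] >= cfg$maf_min]
    if (length(cand) > 0) {
      rr <- if (method == "haplotype") .r2_vec(panel, idx, cand) else
        vapply(cand, function(j) r2(panel, idx, j, method = "dosage"),
               numeric(1))
      keep <- which(!is.na(rr) & rr >= cfg$r2_min)
      cand <- cand[keep]
      rr <- rr[keep]
    } else rr <- numeric(0)
    proxies <- if (length(cand) > 0) data.frame(
      snp_id = sites$snp_id[cand], chrom = sites$chrom[cand],
      pos = sites$pos[cand], ref = sites$ref[cand], alt = sites$alt[cand],
      maf = maf[cand], provenance = "PROXY", lead_id = sites$snp_id[idx],
      r2 = rr, stringsAsFactors = FALSE) else NULL
    out[[li]] <- rbind(lead_row, proxies)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(unmatched) > 0) {
    warning(length(unmatched), " lead SNP(s) not found in panel: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "", call. = FALSE)
  }
  attr(res, "unmatched") <- unmatched
  res
}
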