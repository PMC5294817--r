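# Regulatory-score classification, score distributions, co-binding TF
# frequencies and genotype-stratified binding-signal summaries.

#' Closed vocabulary of regulatory-score categories
#'
#' Ordinal evidence categories in the RegulomeDB style: 1a-1f (likely to
#' affect binding and linked to expression of a gene target), 2a-2c
#' (likely to affect binding), then 3a-6 (weaker or minimal evidence).
#' @export
REG_SCORE_CATEGORIES <- c("1a", "1b", "1c", "1d", "1e", "1f",
                          "2a", "2b", "2c", "3a", "3b", "4", "5", "6")

#' Categories classed as "likely to affect transcription factor binding"
#' @export
LIKELY_AFFECTING_CATEGORIES <- c("1a", "1b", "1c", "1d", "1e", "1f",
                                 "2a", "2b", "2c")

#' Partition regulatory-score records into likely-affecting vs other
#'
#' A record is "likely to affect transcription factor binding" iff its
#' category is one of 1a-1f, 2a, 2b, 2c (i.e. score <= 2, implemented as
#' the explicit category set, not numeric parsing). Records with unknown
#' categories are rejected from the partition and reported with a warning.
#'
#' @param records data.frame with columns \code{snp_id}, \code{category}.
#' @return list: \code{likely} and \code{other} (row subsets),
#'   \code{n_likely}, \code{n_other}, \code{fraction_likely} (of valid
#'   records), \code{rejected} (rows with unknown categories).
#' @export
classify_likely_affecting <- function(records) {
  stopifnot(all(c("snp_id", "category") %in% names(records)))
  bad <- !(records$category %in% REG_SCORE_CATEGORIES)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown category rejected: ",
            paste(utils::head(unique(records$category[bad]), 5),
                  collapse = ", "), call. = FALSE)
  }
  valid <- records[!bad, , drop = FALSE]
  is_likely <- valid$category %in% LIKELY_AFFECTING_CATEGORIES
  list(likely = valid[is_likely, , drop = FALSE],
       other = valid[!is_likely, , drop = FALSE],
       n_likely = sum(is_likely),
       n_other = sum(!is_likely),
       fraction_likely = if (nrow(valid) == 0) NA_real_ else
         mean(is_likely),
       rejected = records[bad, , drop = FALSE])
}

#' Distribution of regulatory-score categories across SNP sets
#'
#' One column per labelled SNP set, one row per category, cells counting
#' the set's SNPs carrying that category; a \code{Total} row sums each
#' column.
#'
#' @param snp_sets named list of SNP id vectors.
#' @param records data.frame with \code{snp_id}, \code{category}.
#' @param categories category rows to tabulate (default the full closed
#'   vocabulary).
#' @return data.frame with a \code{category} column, one count column per
#'   set label, and a final \code{Total} row.
#' @export
score_distribution <- function(snp_sets, records,
                               categories = REG_SCORE_CATEGORIES) {
  stopifnot(is.list(snp_sets), length(names(snp_sets)) == length(snp_sets),
            !anyDuplicated(names(snp_sets)))
  records <- records[records$category %in% categories, , drop = FALSE]
  records <- records[!duplicated(records$snp_id), , drop = FALSE]
  counts <- vapply(snp_sets, function(ids) {
    sub <- records[records$snp_id %in% unique(ids), , drop = FALSE]
    tab <- table(factor(sub$category, levels = categories))
    as.integer(tab)
  }, integer(length(categories)))
  counts <- matrix(counts, nrow = length(categories),
                   dimnames = list(NULL, names(snp_sets)))
  out <- data.frame(category = categories, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  total <- data.frame(category = "Total",
                      t(colSums(counts)), check.names = FALSE,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Frequency of co-binding transcription factors over a SNP set
#'
#' Counts, for each transcription factor, the number of SNPs at whose site
#' that factor binds (set semantics: a factor listed twice for one SNP
#' counts once). Sorted by descending count, ties broken lexicographically;
#' suitable as wordcloud input.
#'
#' @param snp_ids SNP id vector.
#' @param records data.frame with \code{snp_id} and \code{bound_tfs}
#'   (semicolon-joined TF names, or a list column of character vectors).
#' @return data.frame: tf, n_snps.
#' @export
tf_cooccurrence <- function(snp_ids, records) {
  empty <- data.frame(tf = character(0), n_snps = integer(0),
                      stringsAsFactors = FALSE)
  if (length(snp_ids) == 0 || nrow(records) == 0) return(empty)
  sub <- records[records$snp_id %in% unique(snp_ids), , drop = FALSE]
  if (nrow(sub) == 0) return(empty)
  tfs <- sub$bound_tfs
  if (!is.list(tfs)) tfs <- strsplit(as.character(tfs), ";", fixed = TRUE)
  pairs <- unique(data.frame(
    snp_id = rep(sub$snp_id, lengths(tfs)),
    tf = trimws(unlist(tfs)),
    stringsAsFactors = FALSE))
  pairs <- pairs[nzchar(pairs$tf) & !is.na(pairs$tf), , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  tab <- table(pairs$tf)
  out <- data.frame(tf = names(tab), n_snps = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_snps, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize binding signal by genotype class
#'
#' Groups samples into reference-homozygote, heterozygote and
#' alternate-homozygote classes by alt-allele dosage and reports per-class
#' sample counts, mean signal and standard deviation, plus whether the
#' class means are ordered with allele dosage (the Fig.-3c-style
#' allele-sensitive binding pattern where alt homozygotes lose binding).
#'
#' @param genotypes named numeric vector: sample -> alt-allele count
#'   (0, 1 or 2).
#' @param signals named numeric vector: sample -> binding signal at the
#'   site; every signal sample must have a genotype.
#' @return object of class \code{GenotypeBindingSummary}: list with
#'   \code{classes} (data.frame: class, dosage, n, mean, sd) and
#'   \code{monotonicity} ("decreasing", "increasing", "flat", or
#'   \code{NA} when fewer than two classes are populated).
#' @export
binding_by_genotype <- function(genotypes, signals) {
  if (!all(names(signals) %in% names(genotypes))) {
    stop("samples with signal but no genotype: ",
         paste(setdiff(names(signals), names(genotypes)), collapse = ", "),
         call. = FALSE)
  }
  g <- genotypes[names(signals)]
  if (!all(g %in% c(0, 1, 2))) {
    stop("genotype outside {0, 1, 2} for sample(s): ",
         paste(names(g)[!g %in% c(0, 1, 2)], collapse = ", "),
         call. = FALSE)
  }
  dosages <- c(`ref-hom` = 0, het = 1, `alt-hom` = 2)
  classes <- data.frame(
    class = names(dosages), dosage = unname(dosages),
    n = vapply(dosages, function(d) sum(g == d), integer(1)),
    mean = vapply(dosages, function(d) {
      if (any(g == d)) mean(signals[g == d]) else NA_real_
    }, numeric(1)),
    sd = vapply(dosages, function(d) {
      if (sum(g == d) > 1) stats::sd(signals[g == d]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  means <- classes$mean[classes$n > 0]
  monotonicity <- if (length(means) < 2) NA_character_
  else if (all(diff(means) < 0)) "decreasing"
  else if (all(diff(means) > 0)) "increasing"
  else if (all(diff(means) == 0)) "flat"
  else "non-monotone"
  structure(list(classes = classes, monotonicity = monotonicity),
            class = "GenotypeBindingSummary")
}

#' @export
print.GenotypeBindingSummary <- function(x, ...) {
  print(x$classes)
  cat("monotonicity with dosage:", x$monotonicity, "\n")
  invisible(x)
}
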