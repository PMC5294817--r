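#' @importFrom methods is
NULL

# All coordinates handled by this package are 0-based half-open (BED-native).
# GRanges (1-based closed) is used internally for the interval index; the
# conversion happens only inside granges0()/bed0().

#' Normalize chromosome names to the "chr"-prefixed dialect
#'
#' @param x character vector of chromosome names ("1" or "chr1").
#' @return character vector with a "chr" prefix on every name.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom chromosome names (normalized to "chr" form).
#' @param start 0-based inclusive start (bp).
#' @param end exclusive end (bp); must satisfy end > start.
#' @param strand "+", "-" or "*" (unstranded).
#' @return a \code{GRanges}; widths equal \code{end - start}.
#' @export
granges0 <- function(chrom, start, end, strand = "*") {
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start |
                 is.na(chrom) | !nzchar(chrom))
  if (length(bad) > 0) {
    stop("malformed interval(s) at record(s) ", paste(bad, collapse = ", "),
         ": require chrom non-empty, start >= 0, end > start", call. = FALSE)
  }
  GenomicRanges::GRanges(
    seqnames = normalize_chrom(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand
  )
}

#' Extract 0-based half-open coordinates from a GRanges
#'
#' @param gr a \code{GRanges}.
#' @return data.frame with columns chrom, start (0-based), end (exclusive),
#'   strand, plus any metadata columns.
#' @export
bed0 <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc) > 0) df <- cbind(df, mc)
  df
}

#' Construct a named ChIP-seq peak set
#'
#' A peak set is a \code{GRanges} (0-based half-open on construction), sorted
#' by (chrom, start), with duplicates removed and the dataset label stored in
#' \code{metadata(x)$name}.
#'
#' @param chrom,start,end,strand vectors as in [granges0()].
#' @param name dataset label (e.g. cell line + treatment).
#' @return a sorted, deduplicated \code{GRanges} carrying the label.
#' @export
peak_set <- function(chrom, start, end, name, strand = "*") {
  gr <- granges0(chrom, start, end, strand)
  gr <- unique(GenomicRanges::sort(gr, ignore.strand = TRUE))
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Dataset label of a peak set
#' @param x a peak set created by [peak_set()] or [read_bed()].
#' @return the label, or NA if unset.
#' @export
peak_set_name <- function(x) {
  nm <- S4Vectors::metadata(x)$name
  if (is.null(nm)) NA_character_ else nm
}

#' Merge peak sets into a consensus cistrome
#'
#' Overlapping peaks from any number of datasets are merged into
#' non-overlapping consensus loci. Abutting half-open intervals
#' ([0,100) and [100,200)) share zero base pairs and are not merged.
#' Each consensus locus records every dataset contributing at least 1 bp
#' of overlap in the \code{sources} metadata column (comma-joined, sorted).
#'
#' @param peak_sets list of peak sets ([peak_set()] / [read_bed()] output).
#' @return \code{GRanges} of pairwise non-overlapping consensus loci with a
#'   \code{sources} metadata column.
#' @export
merge_consensus <- function(peak_sets) {
  if (!is.list(peak_sets)) peak_sets <- list(peak_sets)
  if (length(peak_sets) == 0) stop("no peak sets supplied", call. = FALSE)
  labs <- vapply(seq_along(peak_sets), function(i) {
    nm <- peak_set_name(peak_sets[[i]])
    if (is.na(nm)) paste0("set", i) else nm
  }, character(1))
  for (i in seq_along(peak_sets)) {
    gr <- peak_sets[[i]]
    if (any(GenomicRanges::width(gr) < 1)) {
      stop("peak set '", labs[i], "' contains malformed interval(s) at record(s) ",
           paste(which(GenomicRanges::width(gr) < 1), collapse = ", "),
           call. = FALSE)
    }
  }
  all_gr <- suppressWarnings(do.call(c, lapply(peak_sets, function(g) {
    GenomicRanges::granges(g)
  })))
  src <- rep(labs, times = vapply(peak_sets, length, integer(1)))
  # min.gapwidth = 0L: merge only intervals that truly share bp, never
  # abutting ones.
  loci <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(loci, all_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  srcs <- vapply(split(src[S4Vectors::subjectHits(hits)],
                       factor(S4Vectors::queryHits(hits),
                              levels = seq_along(loci))),
                 function(v) paste(sort(unique(v)), collapse = ","),
                 character(1))
  S4Vectors::mcols(loci)$sources <- unname(srcs)
  loci
}

#' Split the comma-joined sources column of consensus loci
#' @param loci consensus loci from [merge_consensus()].
#' @return list of character vectors, one per locus.
#' @export
consensus_sources <- function(loci) {
  strsplit(S4Vectors::mcols(loci)$sources, ",", fixed = TRUE)
}

#' Assign SNPs to consensus loci
#'
#' A SNP is a 1-bp interval at its (0-based) position; it is assigned to a
#' locus [s, e) iff s <= pos < e. SNPs on chromosomes absent from the loci
#' are simply unassigned.
#'
#' @param snps data.frame with at least \code{snp_id}, \code{chrom},
#'   \code{pos} (0-based bp).
#' @param loci consensus loci (\code{GRanges}), e.g. from [merge_consensus()].
#' @return list with \code{assignments} (data.frame: snp_id, locus_index,
#'   locus_chrom, locus_start, locus_end, sources; one row per (snp, locus)
#'   pair, each snp at most once per locus) and \code{n_snps_under_loci}
#'   (deduplicated count of distinct SNP ids under any locus).
#' @export
overlap_snps <- function(snps, loci) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (nrow(snps) == 0 || length(loci) == 0) {
    return(list(assignments = data.frame(
      snp_id = character(0), locus_index = integer(0),
      locus_chrom = character(0), locus_start = integer(0),
      locus_end = integer(0), sources = character(0),
      stringsAsFactors = FALSE), n_snps_under_loci = 0L))
  }
  snps <- snps[!duplicated(snps$snp_id), , drop = FALSE]
  sgr <- granges0(snps$chrom, snps$pos, snps$pos + 1)
  # harmonize seqlevels so findOverlaps tolerates chromosomes private to
  # one side
  lev <- union(GenomeInfoDb::seqlevels(sgr), GenomeInfoDb::seqlevels(loci))
  GenomeInfoDb::seqlevels(sgr) <- lev
  lgr <- loci
  GenomeInfoDb::seqlevels(lgr) <- lev
  hits <- GenomicRanges::findOverlaps(sgr, lgr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  srcs <- S4Vectors::mcols(loci)$sources
  if (is.null(srcs)) srcs <- rep(NA_character_, length(loci))
  assignments <- data.frame(
    snp_id = snps$snp_id[qi],
    locus_index = si,
    locus_chrom = as.character(GenomicRanges::seqnames(loci))[si],
    locus_start = GenomicRanges::start(loci)[si] - 1L,
    locus_end = GenomicRanges::end(loci)[si],
    sources = srcs[si],
    stringsAsFactors = FALSE
  )
  assignments <- assignments[!duplicated(assignments[c("snp_id", "locus_index")]), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       n_snps_under_loci = length(unique(assignments$snp_id)))
}

#' Intersect two cistromes with a fractional-overlap criterion
#'
#' A locus of \code{a} counts as shared iff the total number of its base
#' pairs overlapped by loci of \code{b} is at least
#' \code{min_fraction * width}. The threshold is inclusive, so a 100-bp
#' locus with exactly 25 bp overlapped passes at \code{min_fraction = 0.25}.
#' With \code{reciprocal = TRUE}, the matching \code{b} loci must also have
#' at least \code{min_fraction} of their own length overlapped by \code{a}.
#'
#' @param a,b \code{GRanges} of non-overlapping loci (query is \code{a}).
#' @param min_fraction overlap fraction threshold in (0, 1].
#' @param reciprocal require the criterion in both directions.
#' @return object of class \code{CobindingSummary}: list with
#'   \code{n_shared}, \code{n_only_a}, \code{n_only_b}, \code{shared_loci}
#'   (the shared subset of \code{a}), \code{min_fraction}, \code{reciprocal}.
#' @export
fractional_intersect <- function(a, b, min_fraction = 0.25,
                                 reciprocal = FALSE) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1,
            min_fraction > 0, min_fraction <= 1)
  shared_a <- .frac_covered(a, b, min_fraction)
  shared_b <- .frac_covered(b, a, min_fraction)
  if (reciprocal) {
    # a query locus stays shared only if some b locus it overlaps also
    # passes in the other direction
    hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L,
                                        ignore.strand = TRUE)
    ok_pair <- shared_a[S4Vectors::queryHits(hits)] &
      shared_b[S4Vectors::subjectHits(hits)]
    shared_a <- as.logical(tapply(ok_pair,
                                  factor(S4Vectors::queryHits(hits),
                                         levels = seq_along(a)),
                                  any))
    shared_a[is.na(shared_a)] <- FALSE
    shared_b2 <- as.logical(tapply(ok_pair,
                                   factor(S4Vectors::subjectHits(hits),
                                          levels = seq_along(b)),
                                   any))
    shared_b2[is.na(shared_b2)] <- FALSE
    shared_b <- shared_b2
  }
  out <- list(
    n_shared = sum(shared_a),
    n_only_a = sum(!shared_a),
    n_only_b = sum(!shared_b),
    n_shared_b = sum(shared_b),
    shared_loci = a[shared_a],
    min_fraction = min_fraction,
    reciprocal = reciprocal
  )
  class(out) <- "CobindingSummary"
  out
}

# fraction of each query locus covered by the subject set, compared
# inclusively against min_fraction
.frac_covered <- function(query, subject, min_fraction) {
  if (length(query) == 0) return(logical(0))
  if (length(subject) == 0) return(rep(FALSE, length(query)))
  lev <- union(GenomeInfoDb::seqlevels(query),
               GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lev
  GenomeInfoDb::seqlevels(subject) <- lev
  subj <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, subj, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(query)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(subj)[S4Vectors::subjectHits(hits)]))
  cov_bp <- rep(0, length(query))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  cov_bp[as.integer(names(agg))] <- agg
  # require some overlap, with tiny slack so exact-fraction boundaries
  # are inclusive despite floating-point products
  cov_bp > 0 & cov_bp >= min_fraction * GenomicRanges::width(query) - 1e-9
}

#' @export
print.CobindingSummary <- function(x, ...) {
  cat("Cobinding summary (min_fraction=", x$min_fraction,
      if (x$reciprocal) ", reciprocal" else "", ")\n", sep = "")
  cat("  shared (A):", x$n_shared, "  A-only:", x$n_only_a,
      "  B-only:", x$n_only_b, "\n")
  invisible(x)
}
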