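# DR3 direct-repeat motif model, bidirectional PWM scanning, SNP-in-motif
# annotation and allele-aware delta-LOD scoring.

.BASES <- c("A", "C", "G", "T")

#' Default DR3 half-site position weight matrix
#'
#' Built from the degenerate nuclear-receptor half-site consensus RGKTSA
#' (AGGTCA-like): each column puts 0.85 total weight on the consensus
#' base(s) and spreads the remainder uniformly over the other bases.
#'
#' @return 4 x 6 probability matrix with rows A, C, G, T.
#' @export
dr3_default_pwm <- function() {
  cons <- list(c("A", "G"), "G", c("G", "T"), "T", c("C", "G"), "A")
  pwm <- vapply(cons, function(b) {
    col <- rep(0.15 / (4 - length(b)), 4)
    names(col) <- .BASES
    col[b] <- 0.85 / length(b)
    col
  }, numeric(4))
  rownames(pwm) <- .BASES
  colnames(pwm) <- paste0("p", seq_len(ncol(pwm)))
  pwm
}

#' DR3 motif model
#'
#' A direct repeat of two 6-bp half sites separated by a \code{spacer_len}
#' unscored spacer (3 bp for the canonical DR3). Log-odds are base 2
#' (bits); a pseudocount is added to the PWM cells, which are renormalized,
#' before taking log odds, so no cell maps to -Inf. Spacer columns carry
#' uniform weights and contribute exactly 0 to every score.
#'
#' @param half_site_pwm 4 x 6 probability matrix (rows A, C, G, T); columns
#'   must each sum to 1 within 1e-9. Default [dr3_default_pwm()].
#' @param spacer_len bases between the half sites (default 3).
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param score_threshold minimum summed log-odds for a scan hit, in bits;
#'   default 80\% of the maximum attainable (consensus) score.
#' @param pseudocount added to each PWM cell before log-odds (default 0.01).
#' @return object of class \code{MotifModel} with elements
#'   \code{half_site_pwm}, \code{spacer_len}, \code{background},
#'   \code{lods} (4 x width log-odds matrix, spacer columns zero),
#'   \code{width}, \code{max_score}, \code{score_threshold}.
#' @export
motif_model <- function(half_site_pwm = dr3_default_pwm(), spacer_len = 3,
                        background = rep(0.25, 4), score_threshold = NULL,
                        pseudocount = 0.01) {
  stopifnot(nrow(half_site_pwm) == 4, ncol(half_site_pwm) == 6,
            spacer_len >= 0, length(background) == 4,
            abs(sum(background) - 1) < 1e-9)
  if (any(abs(colSums(half_site_pwm) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1", call. = FALSE)
  }
  rownames(half_site_pwm) <- .BASES
  w <- sweep(half_site_pwm + pseudocount, 2,
             colSums(half_site_pwm + pseudocount), "/")
  half_lods <- log2(w / background)
  width <- 2L * 6L + as.integer(spacer_len)
  lods <- cbind(half_lods, matrix(0, 4, spacer_len), half_lods)
  colnames(lods) <- paste0("c", seq_len(width))
  max_score <- sum(apply(lods, 2, max))
  if (is.null(score_threshold)) score_threshold <- 0.8 * max_score
  structure(list(half_site_pwm = half_site_pwm, spacer_len = spacer_len,
                 background = background, lods = lods, width = width,
                 max_score = max_score, score_threshold = score_threshold,
                 pseudocount = pseudocount),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("DR", x$spacer_len, " motif model: width ", x$width,
      ", max score ", round(x$max_score, 3), " bits, threshold ",
      round(x$score_threshold, 3), " bits\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a motif model
#'
#' Per-column maximum-probability base (ties broken in A < C < G < T
#' order); spacer positions are reported as "A" placeholders only in the
#' full-width form.
#'
#' @param model a [motif_model()].
#' @param full return the full 15-mer (half sites + spacer placeholder)
#'   instead of the 6-bp half site.
#' @return character scalar.
#' @export
consensus_sequence <- function(model, full = TRUE) {
  half <- paste(.BASES[apply(model$half_site_pwm, 2, which.max)],
                collapse = "")
  if (!full) return(half)
  paste0(half, strrep("A", model$spacer_len), half)
}

#' In-motif positions belonging to the unscored spacer
#' @param model a [motif_model()].
#' @return integer vector of 1-based in-motif positions.
#' @export
spacer_positions <- function(model) {
  if (model$spacer_len == 0) return(integer(0))
  seq(7L, length.out = model$spacer_len)
}

# score every window of an encoded sequence (integer codes 1..4, NA for N);
# returns numeric vector of window scores (NA where the window contains N)
.window_scores <- function(codes, lods) {
  w <- ncol(lods)
  L <- length(codes)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  sc <- numeric(nwin)
  for (cc in seq_len(w)) {
    b <- codes[cc:(cc + nwin - 1L)]
    sc <- sc + lods[cbind(b, cc)]
  }
  sc
}

.encode_seq <- function(sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]], .BASES)
  codes
}

#' Scan a sequence for motif hits on one or both strands
#'
#' Every window whose summed two-hexamer log-odds meets the model threshold
#' is reported. Coordinates are 0-based half-open on the + strand genome;
#' windows containing N are skipped. Overlapping hits are allowed. The
#' reported \code{sequence} is the window read in the hit's orientation.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param model a [motif_model()].
#' @param both_strands also scan the reverse complement (default TRUE).
#' @param chrom,origin chromosome name and 0-based genomic offset of the
#'   first base of \code{sequence}.
#' @return data.frame: chrom, start, end, strand, score, sequence.
#' @export
scan_motifs <- function(sequence, model, both_strands = TRUE,
                        chrom = "chr1", origin = 0) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  }
  w <- model$width
  L <- nchar(sequence)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)
  out <- list()
  scan_one <- function(seqstr, strand) {
    codes <- .encode_seq(seqstr)
    sc <- .window_scores(codes, model$lods)
    keep <- which(!is.na(sc) & sc >= model$score_threshold)
    if (length(keep) == 0) return(NULL)
    if (strand == "+") {
      start0 <- origin + keep - 1L
    } else {
      # window j (1-based) on the reverse complement maps to + strand
      # 0-based start L - j - w + 1
      start0 <- origin + L - keep - w + 1L
    }
    data.frame(chrom = chrom, start = start0, end = start0 + w,
               strand = strand, score = sc[keep],
               sequence = substring(seqstr, keep, keep + w - 1L),
               stringsAsFactors = FALSE)
  }
  out$plus <- scan_one(sequence, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    out$minus <- scan_one(rc, "-")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a set of loci against a genome for motif hits
#'
#' @param genome named \code{DNAStringSet} (names = chromosome names) or a
#'   named character vector of sequences.
#' @param loci \code{GRanges} of regions to scan (e.g. consensus loci).
#' @param model a [motif_model()].
#' @param flank_from_midpoint if not NULL, scan only +/- this many bp
#'   around each locus midpoint (default 100, mirroring summit-centred
#'   annotation); NULL scans whole loci.
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame of hits as in [scan_motifs()], genomic coordinates.
#' @export
scan_loci <- function(genome, loci, model, flank_from_midpoint = 100,
                      both_strands = TRUE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  df <- bed0(loci)
  hits <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    chrom <- df$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("chromosome ", chrom, " missing from genome", call. = FALSE)
    }
    s0 <- df$start[i]; e0 <- df$end[i]
    if (!is.null(flank_from_midpoint)) {
      mid <- floor((s0 + e0) / 2)
      s0 <- max(0, mid - flank_from_midpoint)
      e0 <- min(length(genome[[chrom]]), mid + flank_from_midpoint)
    }
    if (e0 - s0 < model$width) next
    subseq <- as.character(Biostrings::subseq(genome[[chrom]], s0 + 1, e0))
    hits[[i]] <- scan_motifs(subseq, model, both_strands = both_strands,
                             chrom = chrom, origin = s0)
  }
  res <- do.call(rbind, hits)
  if (is.null(res)) {
    return(scan_motifs(strrep("N", model$width), model))
  }
  res <- res[!duplicated(res[c("chrom", "start", "strand")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate SNPs falling inside motif hits
#'
#' One annotation per (SNP, overlapping hit). \code{position_in_motif} is
#' the 1-based offset of the SNP within the motif read in the hit's
#' orientation: for - strand hits position 1 is the hit's end-most genomic
#' base, so a SNP at genomic offset o into a width-w hit has position
#' w - o.
#'
#' @param snps data.frame with \code{snp_id}, \code{chrom}, \code{pos}
#'   (0-based).
#' @param hits data.frame of hits from [scan_motifs()]/[scan_loci()].
#' @return data.frame: snp_id, chrom, start, end, strand, score, sequence,
#'   position_in_motif.
#' @export
snp_in_motif <- function(snps, hits) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    sel <- which(normalize_chrom(snps$chrom) == normalize_chrom(h$chrom) &
                   snps$pos >= h$start & snps$pos < h$end)
    if (length(sel) == 0) next
    offset <- snps$pos[sel] - h$start
    position <- if (h$strand == "-") (h$end - h$start) - offset else
      offset + 1L
    out[[length(out) + 1L]] <- data.frame(
      snp_id = snps$snp_id[sel], chrom = h$chrom, start = h$start,
      end = h$end, strand = h$strand, score = h$score,
      sequence = h$sequence, position_in_motif = as.integer(position),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      sequence = character(0),
                      position_in_motif = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.complement <- function(base) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[toupper(base)]
}

#' Allele-aware change in motif log-odds score (delta LOD)
#'
#' Rescoring of the full motif window with the alternate allele substituted
#' for the reference: \code{delta_lod = score(alt) - score(ref)}. Negative
#' values mean the predicted relative affinity is higher for the reference
#' sequence; positive values favour the alternate allele. SNPs in spacer
#' positions return exactly 0 (spacer columns carry no weight).
#'
#' @param model a [motif_model()].
#' @param context_sequence + strand nucleotide string covering the hit.
#' @param context_origin 0-based genomic position of the first base of
#'   \code{context_sequence}.
#' @param snp one-row data.frame (or list) with \code{snp_id}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}; \code{ref} is the + strand
#'   reference base and must match the supplied sequence.
#' @param hit one-row data.frame with \code{start}, \code{end},
#'   \code{strand} (a motif hit containing the SNP).
#' @return delta LOD in bits.
#' @export
delta_lod <- function(model, context_sequence, snp, hit,
                      context_origin = 0) {
  pos <- snp$pos
  if (pos < hit$start || pos >= hit$end) {
    stop("SNP ", snp$snp_id, " at ", pos, " lies outside hit [",
         hit$start, ",", hit$end, ")", call. = FALSE)
  }
  win_start <- hit$start - context_origin  # 0-based into context
  if (win_start < 0 ||
      win_start + model$width > nchar(context_sequence)) {
    stop("context sequence does not cover the hit", call. = FALSE)
  }
  window <- toupper(substring(context_sequence, win_start + 1,
                              win_start + model$width))
  offset <- pos - hit$start  # 0-based offset on + strand window
  genome_base <- substring(window, offset + 1, offset + 1)
  if (genome_base != toupper(snp$ref)) {
    stop("reference allele mismatch for ", snp$snp_id, " at position ",
         pos, ": genome has ", genome_base, ", record says ", snp$ref,
         call. = FALSE)
  }
  orient <- function(s) {
    if (hit$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    } else s
  }
  score_window <- function(win) {
    codes <- .encode_seq(orient(win))
    sum(model$lods[cbind(codes, seq_len(model$width))])
  }
  alt_window <- window
  substring(alt_window, offset + 1, offset + 1) <- toupper(snp$alt)
  score_window(alt_window) - score_window(window)
}

#' Write a motif half-site PWM as a JASPAR-like text file
#' @param pwm 4 x w probability (or count) matrix, rows A, C, G, T.
#' @param path output path.
#' @param name motif name written on the header line.
#' @export
write_pwm <- function(pwm, path, name = "DR3_half_site") {
  lines <- c(paste0(">", name),
             vapply(seq_len(4), function(i) {
               paste0(.BASES[i], " [ ",
                      paste(formatC(pwm[i, ], format = "fg", digits = 8),
                            collapse = " "), " ]")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JASPAR-like PWM text file
#'
#' Accepts 4 base rows of the form \code{"A [ 1 2 ... ]"} (brackets
#' optional), with an optional \code{">name"} header. Counts are
#' normalized to column probabilities.
#'
#' @param path input path.
#' @return 4 x w probability matrix with rows A, C, G, T; the motif name
#'   (if any) is kept in the \code{"name"} attribute.
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- NULL
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4) {
    stop("expected 4 base rows in PWM file ", path, call. = FALSE)
  }
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  base_order <- toupper(substring(lines, 1, 1))
  if (!setequal(base_order, .BASES)) {
    stop("PWM rows must be labelled A, C, G, T", call. = FALSE)
  }
  w <- unique(vapply(rows, length, integer(1)))
  if (length(w) != 1) stop("ragged PWM rows in ", path, call. = FALSE)
  pwm <- do.call(rbind, rows)[match(.BASES, base_order), , drop = FALSE]
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  rownames(pwm) <- .BASES
  attr(pwm, "name") <- name
  pwm
}
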