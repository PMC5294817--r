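# Readers and writers for the external formats the pipeline exchanges:
# BED3/BED6 peak files, GWAS-catalog TSVs, phased panels (VCF or plain
# haplotype matrix), FASTA, regulatory-score TSVs and plain TSV tables.

#' Write a TSV table
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV table
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a BED3/BED6 peak file
#'
#' Tab-separated, 0-based half-open. Chromosome names are normalized to
#' the "chr"-prefixed dialect. Malformed lines (non-numeric coordinates,
#' end <= start) are rejected with their line number.
#'
#' @param path BED file path.
#' @param name dataset label to attach (default: file name without
#'   extension).
#' @return a [peak_set()] \code{GRanges}; a \code{name} column, if
#'   present, is kept in \code{mcols()}.
#' @export
read_bed <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(raw) < 3) stop("BED file ", path, " has fewer than 3 columns",
                          call. = FALSE)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("non-numeric coordinates in ", path, " at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    stop("invalid interval (end <= start or negative start) in ", path,
         " at line(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  strand <- if (ncol(raw) >= 6) ifelse(raw[[6]] %in% c("+", "-"),
                                       raw[[6]], "*") else "*"
  gr <- granges0(raw[[1]], start, end, strand)
  if (ncol(raw) >= 4) S4Vectors::mcols(gr)$name <- raw[[4]]
  if (ncol(raw) >= 5) {
    S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(raw[[5]]))
  }
  ord <- GenomicRanges::order(gr)
  gr <- gr[ord]
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write intervals as BED6
#'
#' Consensus loci serialize their comma-joined \code{sources} in the name
#' column; otherwise a \code{name} metadata column (or ".") is used.
#'
#' @param gr \code{GRanges} (0-based half-open on output).
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- bed0(gr)
  nm <- if ("sources" %in% names(df)) df$sources
  else if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df) && !all(is.na(df$score))) df$score
  else 0
  out <- data.frame(df$chrom, df$start, df$end, nm, score,
                    ifelse(df$strand == "*", ".", df$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GWAS catalog flat file
#'
#' Expects a header row; the mapping from the required logical columns to
#' file columns is configurable. Positions in the file are 1-based and are
#' converted to the package's 0-based convention. Rows lacking a numeric
#' chromosomal position are dropped (their count is reported in the
#' \code{"n_dropped"} attribute and a message). (trait, SNP) duplicates
#' are collapsed.
#'
#' @param path TSV path.
#' @param column_map named character vector mapping logical names
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{trait}, \code{study},
#'   \code{pvalue} to file column names (study/pvalue optional).
#' @return data.frame: trait, snp_id, lead_id (= snp_id), chrom
#'   (normalized), pos (0-based), study, pvalue.
#' @export
read_gwas_catalog <- function(path,
                              column_map = c(snp_id = "snp_id",
                                             chrom = "chrom", pos = "pos",
                                             trait = "trait",
                                             study = "study",
                                             pvalue = "pvalue")) {
  df <- read_tsv_table(path)
  required <- c("snp_id", "chrom", "pos", "trait")
  missing_cols <- setdiff(column_map[required], names(df))
  if (length(missing_cols) > 0) {
    stop("GWAS catalog ", path, " lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get <- function(logical_name, default = NA) {
    col <- column_map[logical_name]
    if (!is.na(col) && col %in% names(df)) df[[col]] else
      rep(default, nrow(df))
  }
  pos <- suppressWarnings(as.numeric(get("pos")))
  keep <- !is.na(pos)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " catalog row(s) without numeric position dropped")
  }
  out <- data.frame(
    trait = as.character(get("trait"))[keep],
    snp_id = as.character(get("snp_id"))[keep],
    chrom = normalize_chrom(get("chrom")[keep]),
    pos = as.integer(pos[keep]) - 1L,
    study = as.character(get("study", ""))[keep],
    pvalue = suppressWarnings(as.numeric(get("pvalue", NA)))[keep],
    stringsAsFactors = FALSE)
  out$lead_id <- out$snp_id
  out <- out[!duplicated(out[c("trait", "snp_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[c("trait", "snp_id", "lead_id", "chrom", "pos", "study",
               "pvalue")]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a catalog data.frame back to the flat-file layout (1-based pos)
#' @param catalog data.frame from [read_gwas_catalog()] or the simulator.
#' @param path output path.
#' @export
write_gwas_catalog <- function(catalog, path) {
  out <- data.frame(snp_id = catalog$snp_id, chrom = catalog$chrom,
                    pos = catalog$pos + 1L, trait = catalog$trait,
                    study = if ("study" %in% names(catalog)) catalog$study
                    else "", pvalue = if ("pvalue" %in% names(catalog))
                      catalog$pvalue else NA,
                    stringsAsFactors = FALSE)
  write_tsv_table(out, path)
}

#' Read a phased haplotype panel from VCF
#'
#' Biallelic sites load as one panel column; multi-allelic sites are split
#' into one biallelic column per alternate allele (their count is
#' reported via message). Unphased genotypes are rejected unless
#' \code{allow_unphased = TRUE} (in which case the "|"/"/" distinction is
#' ignored and downstream r2 should use the dosage method). VCF positions
#' (1-based) are converted to 0-based.
#'
#' @param path VCF path (plain text).
#' @param allow_unphased accept "/"-separated genotypes.
#' @return a [haplotype_panel()] with 2 haplotype rows per sample.
#' @export
read_panel_vcf <- function(path, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) {
    stop("VCF ", path, " has no genotype columns", call. = FALSE)
  }
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased) && !allow_unphased) {
    stop("unphased genotype(s) in ", path, " (first at record ",
         which(rowSums(matrix(unphased, nrow = nrow(gt))) > 0)[1],
         "); use allow_unphased = TRUE to accept", call. = FALSE)
  }
  gt <- gsub("/", "|", gt, fixed = TRUE)
  sites <- list()
  cols <- list()
  n_split <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1) n_split <- n_split + 1L
    parts <- strsplit(gt[i, ], "|", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("malformed GT at record ", i, " (", fix$CHROM[i], ":",
           fix$POS[i], ")", call. = FALSE)
    }
    al <- suppressWarnings(as.integer(unlist(parts)))
    if (any(is.na(al))) {
      stop("missing or malformed allele at record ", i, " (", fix$CHROM[i],
           ":", fix$POS[i], ")", call. = FALSE)
    }
    for (k in seq_along(alts)) {
      id <- fix$ID[i]
      if (is.na(id) || id == ".") id <- paste0(fix$CHROM[i], ":", fix$POS[i])
      if (length(alts) > 1) id <- paste0(id, "_alt", k)
      sites[[length(sites) + 1L]] <- data.frame(
        snp_id = id, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]) - 1L, ref = fix$REF[i],
        alt = alts[k], stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- as.integer(al == k)
    }
  }
  if (n_split > 0) {
    message(n_split, " multi-allelic site(s) split into biallelic records")
  }
  # unlist(parts) interleaves the two alleles per sample in sample order:
  # haplotype rows are (sample1.a, sample1.b, sample2.a, ...)
  haplotype_panel(do.call(rbind, sites), do.call(cbind, cols))
}

#' Write a haplotype panel as a minimal phased VCF (plain text)
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param sample_prefix sample name prefix.
#' @export
write_panel_vcf <- function(panel, path, sample_prefix = "SAMPLE") {
  h <- panel$haplotypes
  if (nrow(h) %% 2 != 0) {
    stop("panel must have an even number of haplotypes to pair into samples",
         call. = FALSE)
  }
  n_samp <- nrow(h) / 2
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n_samp))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gts <- vapply(seq_len(nrow(panel$sites)), function(i) {
    a <- h[seq(1, nrow(h), by = 2), i]
    b <- h[seq(2, nrow(h), by = 2), i]
    paste(paste0(a, "|", b), collapse = "\t")
  }, character(1))
  body <- paste(panel$sites$chrom, panel$sites$pos + 1L,
                panel$sites$snp_id, panel$sites$ref, panel$sites$alt,
                ".", "PASS", ".", "GT", gts, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a plain haplotype-matrix TSV panel
#'
#' Layout: a site table header of the form
#' \code{snp_id  chrom  pos  ref  alt} transposed is impractical, so the
#' format is: first four rows give \code{chrom}, \code{pos} (1-based),
#' \code{ref}, \code{alt} per site under a header row of site ids; every
#' following row is one haplotype of 0/1 codes.
#'
#' @param path TSV path.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_rows <- c("chrom", "pos", "ref", "alt")
  rn <- raw[[1]]
  if (!all(meta_rows %in% rn[1:4])) {
    stop("haplotype TSV ", path,
         " must start with chrom/pos/ref/alt rows", call. = FALSE)
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  sites <- data.frame(
    snp_id = colnames(mat),
    chrom = mat[match("chrom", rn), ],
    pos = as.integer(mat[match("pos", rn), ]) - 1L,
    ref = mat[match("ref", rn), ],
    alt = mat[match("alt", rn), ],
    stringsAsFactors = FALSE)
  hap <- mat[-(1:4), , drop = FALSE]
  storage.mode(hap) <- "integer"
  rownames(sites) <- NULL
  haplotype_panel(sites, hap)
}

#' Write a haplotype panel as a plain TSV matrix
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_haplotype_tsv <- function(panel, path) {
  mat <- rbind(chrom = panel$sites$chrom, pos = panel$sites$pos + 1L,
               ref = panel$sites$ref, alt = panel$sites$alt,
               panel$haplotypes)
  out <- data.frame(row = c("chrom", "pos", "ref", "alt",
                            sprintf("hap%04d", seq_len(nrow(panel$haplotypes)))),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("row", panel$sites$snp_id)
  write_tsv_table(out, path)
}

#' Read a regulatory-score TSV
#' @param path TSV with columns snp_id, category, bound_tfs
#'   (semicolon-joined), eqtl_genes (semicolon-joined).
#' @return data.frame with those columns.
#' @export
read_reg_scores <- function(path) {
  df <- read_tsv_table(path)
  needed <- c("snp_id", "category")
  if (!all(needed %in% names(df))) {
    stop("regulatory-score table ", path, " needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"bound_tfs" %in% names(df)) df$bound_tfs <- ""
  if (!"eqtl_genes" %in% names(df)) df$eqtl_genes <- ""
  df$bound_tfs[is.na(df$bound_tfs)] <- ""
  df$eqtl_genes[is.na(df$eqtl_genes)] <- ""
  df
}

#' Write genome sequences as FASTA
#' @param genome named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA path.
#' @return named \code{DNAStringSet}.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
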