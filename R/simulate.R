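# Deterministic, seeded generators for every input the pipeline consumes:
# haplotype panels with block LD, GWAS-style catalogs with a planted
# enriched trait, peak sets, sequences with planted DR3 motifs, and
# genotype-dependent binding signal.

#' Derive a named RNG substream seed
#'
#' Each generator draws from its own substream derived from (seed, name)
#' with a small polynomial string hash, so adding a generator never
#' perturbs the output of existing ones. The result is < 2^31.
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @return integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1014283
  as.integer(((as.numeric(seed) %% 1014283) * 1014283 + h) %% 2147483647)
}

.set_stream <- function(seed, name) {
  set.seed(substream_seed(seed, name), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Defaults give a compact but fully structured study: a 10-Mb genome, a
#' 200-haplotype panel organised in 20 independent LD blocks (10 sites
#' each, per-site mutation probability 0.02 off a block founder, so
#' within-block r2 is high and cross-block r2 is null), 50 traits of 10
#' SNPs, 500 background peaks of mean width 500 bp split over 2 datasets,
#' and one planted trait whose SNPs are covered by peaks at
#' \code{enrichment_factor} times the background coverage probability.
#'
#' @param seed master integer seed driving every substream.
#' @param n_haplotypes haplotypes in the panel.
#' @param n_blocks,block_size_bp,sites_per_block LD block structure.
#' @param mutation_rate per-site probability of flipping the founder
#'   allele within a block.
#' @param n_peaks background peak count (across all peak sets).
#' @param peak_width_mean,peak_width_sd peak width distribution (bp).
#' @param n_peak_sets number of ChIP-seq datasets (>= 2).
#' @param n_traits,snps_per_trait catalog shape; trait SNP sets partition
#'   the panel sites, so the deduplicated universe is exactly
#'   \code{n_traits * snps_per_trait}.
#' @param planted_trait label of the enriched trait.
#' @param enrichment_factor coverage multiplier (>= 1) for the planted
#'   trait's SNPs.
#' @param genome_length_bp genome size.
#' @param motif_plant_count number of consensus DR3 15-mers planted.
#' @param plant_ld_neighborhood when TRUE, the coverage planting extends
#'   to every panel site in the LD blocks containing a planted-trait SNP
#'   (so the trait's signal survives proxy expansion); the default FALSE
#'   covers only the trait's own SNPs, which keeps the planted coverage
#'   probability exactly \code{enrichment_factor} times background for
#'   calibration studies.
#' @return list of class \code{SimConfig}.
#' @export
sim_config <- function(seed = 1, n_haplotypes = 200, n_blocks = 20,
                       block_size_bp = 50000, sites_per_block = 10,
                       mutation_rate = 0.02, n_peaks = 500,
                       peak_width_mean = 500, peak_width_sd = 100,
                       n_peak_sets = 2, n_traits = 50, snps_per_trait = 10,
                       planted_trait = "planted_trait",
                       enrichment_factor = 10, genome_length_bp = 1e7,
                       motif_plant_count = 20,
                       plant_ld_neighborhood = FALSE) {
  cfg <- list(seed = seed, n_haplotypes = n_haplotypes, n_blocks = n_blocks,
              block_size_bp = block_size_bp,
              sites_per_block = sites_per_block,
              mutation_rate = mutation_rate, n_peaks = n_peaks,
              peak_width_mean = peak_width_mean,
              peak_width_sd = peak_width_sd, n_peak_sets = n_peak_sets,
              n_traits = n_traits, snps_per_trait = snps_per_trait,
              planted_trait = planted_trait,
              enrichment_factor = enrichment_factor,
              genome_length_bp = genome_length_bp,
              motif_plant_count = motif_plant_count,
              plant_ld_neighborhood = plant_ld_neighborhood)
  stopifnot(all(vapply(cfg[c("n_haplotypes", "n_blocks", "block_size_bp",
                             "sites_per_block", "n_peaks", "n_peak_sets",
                             "n_traits", "snps_per_trait",
                             "genome_length_bp")],
                       function(x) x > 0, logical(1))),
            enrichment_factor >= 1, mutation_rate >= 0, mutation_rate < 0.5,
            n_blocks * block_size_bp <= genome_length_bp)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Haplotypes are organised in independent blocks laid end to end along
#' one chromosome. Within a block every site is a copy of a founder
#' column (alt-allele frequency drawn uniformly on (0.02, 0.5), so site
#' MAFs straddle the 0.05 filter) with per-site mutation probability
#' \code{cfg$mutation_rate}; across blocks columns are independent.
#'
#' @param cfg a [sim_config()].
#' @return a [haplotype_panel()]; sites carry ids \code{"rsim<block>_<site>"}
#'   and a \code{block} column.
#' @export
sim_panel <- function(cfg) {
  .set_stream(cfg$seed, "panel")
  nh <- cfg$n_haplotypes
  cols <- list()
  sites <- list()
  for (b in seq_len(cfg$n_blocks)) {
    founder_f <- stats::runif(1, 0.02, 0.5)
    founder <- stats::rbinom(nh, 1, founder_f)
    block_start <- (b - 1) * cfg$block_size_bp
    pos <- sort(sample.int(cfg$block_size_bp, cfg$sites_per_block)) - 1L +
      block_start
    for (s in seq_len(cfg$sites_per_block)) {
      flip <- stats::rbinom(nh, 1, cfg$mutation_rate)
      cols[[length(cols) + 1L]] <- as.integer(xor(founder, flip))
    }
    alleles <- vapply(seq_len(cfg$sites_per_block), function(s) {
      paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
    }, character(1))
    sites[[b]] <- data.frame(
      snp_id = sprintf("rsim%d_%d", b, seq_len(cfg$sites_per_block)),
      chrom = "chr1", pos = pos,
      ref = substring(alleles, 1, 1), alt = substring(alleles, 2, 2),
      block = b, stringsAsFactors = FALSE)
  }
  haplotype_panel(do.call(rbind, sites),
                  do.call(cbind, cols))
}

# independent linear-scan coverage check used for ground truth (kept free
# of the package's interval index on purpose)
.covered_by <- function(pos, starts, ends) {
  vapply(pos, function(p) any(starts <= p & p < ends), logical(1))
}

#' Simulate a GWAS-style catalog and ChIP-seq peak sets with a planted
#' enriched trait
#'
#' Trait SNP sets partition the panel sites (each SNP belongs to exactly
#' one trait, so the deduplicated universe is exact). Background peaks are
#' placed uniformly on the genome but rejection-sampled away from the
#' planted trait's SNPs; each planted-trait SNP instead receives a
#' covering peak independently with probability
#' \code{min(1, enrichment_factor * p_cov)}, where
#' \code{p_cov = n_peaks * peak_width_mean / genome_length_bp} is the
#' background coverage probability. At \code{enrichment_factor = 1} the
#' planted trait is therefore covered at exactly the background rate.
#'
#' @param cfg a [sim_config()].
#' @param panel panel from [sim_panel()] (trait SNPs are drawn from its
#'   sites).
#' @return list: \code{catalog} (data.frame: trait, snp_id, lead_id,
#'   chrom, pos, study, pvalue), \code{peak_sets} (list of [peak_set()]
#'   GRanges, one per dataset), \code{truth} (data.frame: snp_id, trait,
#'   covered, planted) computed by an independent linear scan.
#' @export
sim_catalog_and_peaks <- function(cfg, panel) {
  .set_stream(cfg$seed, "catalog_peaks")
  sites <- panel$sites
  need <- cfg$n_traits * cfg$snps_per_trait
  if (need > nrow(sites)) {
    stop("need ", need, " sites for ", cfg$n_traits, " traits but panel has ",
         nrow(sites), call. = FALSE)
  }
  p_cov <- cfg$n_peaks * cfg$peak_width_mean / cfg$genome_length_bp
  p_plant <- cfg$enrichment_factor * p_cov
  if (p_plant > 1) {
    stop("enrichment_factor ", cfg$enrichment_factor,
         " requires coverage probability ", round(p_plant, 3),
         " > 1; reduce it or the background coverage", call. = FALSE)
  }
  traits <- c(cfg$planted_trait,
              sprintf("trait_%03d", seq_len(cfg$n_traits - 1)))
  picked <- sample.int(nrow(sites), need)
  catalog <- data.frame(
    trait = rep(traits, each = cfg$snps_per_trait),
    snp_id = sites$snp_id[picked],
    lead_id = sites$snp_id[picked],
    chrom = sites$chrom[picked],
    pos = sites$pos[picked],
    study = "SIM0001",
    pvalue = 1e-8,
    stringsAsFactors = FALSE)
  planted_pos <- catalog$pos[catalog$trait == cfg$planted_trait]
  if (isTRUE(cfg$plant_ld_neighborhood) && "block" %in% names(sites)) {
    planted_blocks <- unique(sites$block[match(
      catalog$snp_id[catalog$trait == cfg$planted_trait],
      sites$snp_id)])
    planted_pos <- sites$pos[sites$block %in% planted_blocks]
  }

  draw_width <- function(n) {
    pmax(50L, as.integer(round(stats::rnorm(n, cfg$peak_width_mean,
                                            cfg$peak_width_sd))))
  }
  # background peaks, rejection-sampled off the planted trait's SNPs
  widths <- draw_width(cfg$n_peaks)
  starts <- integer(cfg$n_peaks)
  for (i in seq_len(cfg$n_peaks)) {
    repeat {
      s <- sample.int(cfg$genome_length_bp - widths[i], 1) - 1L
      if (!any(planted_pos >= s & planted_pos < s + widths[i])) break
    }
    starts[i] <- s
  }
  # forced peaks covering planted SNPs at enrichment_factor x background
  forced <- which(stats::runif(length(planted_pos)) < p_plant)
  f_widths <- draw_width(length(forced))
  f_offsets <- vapply(f_widths, function(w) sample.int(w, 1) - 1L,
                      integer(1))
  f_starts <- pmax(0L, planted_pos[forced] - f_offsets)
  all_starts <- c(starts, f_starts)
  all_widths <- c(widths, f_widths)
  set_of <- sample.int(cfg$n_peak_sets, length(all_starts), replace = TRUE)
  peak_sets <- lapply(seq_len(cfg$n_peak_sets), function(ps) {
    sel <- set_of == ps
    peak_set(chrom = rep("chr1", sum(sel)), start = all_starts[sel],
             end = all_starts[sel] + all_widths[sel],
             name = sprintf("set%s", LETTERS[ps]))
  })
  truth <- data.frame(
    snp_id = catalog$snp_id, trait = catalog$trait,
    covered = .covered_by(catalog$pos, all_starts,
                          all_starts + all_widths),
    planted = catalog$trait == cfg$planted_trait,
    stringsAsFactors = FALSE)
  list(catalog = catalog, peak_sets = peak_sets, truth = truth)
}

#' Simulate locus sequences with planted DR3 motifs
#'
#' Generates an i.i.d. uniform-background sequence for each locus and
#' plants exact consensus DR3 15-mers at recorded positions and strands.
#' If \code{snps} is given, plants are preferentially placed so that a SNP
#' inside a locus falls at a recorded in-motif position (to exercise
#' SNP-in-motif annotation and delta-LOD scoring).
#'
#' @param cfg a [sim_config()].
#' @param loci \code{GRanges} of loci to sequence.
#' @param model a [motif_model()]; the planted 15-mer is its consensus.
#' @param snps optional data.frame (\code{snp_id}, \code{chrom},
#'   \code{pos}) of SNPs that plants should overlap when possible.
#' @return list: \code{sequences} (named character vector, one chromosome
#'   per locus-bearing chromosome, assembled to genome coordinates is NOT
#'   done -- sequences are per locus, named "chrom:start-end"),
#'   \code{genome} (named character vector of full-length per-chromosome
#'   sequences with loci embedded), \code{truth} (data.frame: chrom,
#'   start, end, strand, locus_index, snp_id, position_in_motif).
#' @export
sim_sequences_with_motifs <- function(cfg, loci, model, snps = NULL) {
  .set_stream(cfg$seed, "sequences")
  df <- bed0(loci)
  chroms <- unique(df$chrom)
  glen <- max(cfg$genome_length_bp, max(df$end))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
          collapse = "")
  }, character(1))
  cons <- consensus_sequence(model, full = FALSE)
  spacer <- paste(sample(c("A", "C", "G", "T"), model$spacer_len,
                         replace = TRUE), collapse = "")
  motif_seq <- paste0(cons, spacer, cons)
  w <- model$width
  truth <- list()
  n_plant <- min(cfg$motif_plant_count, nrow(df))
  if (n_plant == 0) {
    return(list(genome = genome,
                truth = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   locus_index = integer(0),
                                   snp_id = character(0),
                                   position_in_motif = integer(0))))
  }
  target_loci <- sample.int(nrow(df), n_plant)
  for (li in target_loci) {
    ch <- df$chrom[li]
    strand <- sample(c("+", "-"), 1)
    snp_id <- NA_character_
    posm <- NA_integer_
    snp_here <- if (!is.null(snps)) {
      which(normalize_chrom(snps$chrom) == ch & snps$pos >= df$start[li] &
              snps$pos < df$end[li])
    } else integer(0)
    if (length(snp_here) > 0) {
      sidx <- snp_here[1]
      # choose an in-motif offset (avoiding edges) and place the plant so
      # the SNP falls inside it
      offset <- sample.int(w, 1) - 1L
      start0 <- snps$pos[sidx] - offset
      if (start0 < df$start[li] || start0 + w > df$end[li]) {
        start0 <- df$start[li] +
          sample.int(df$end[li] - df$start[li] - w + 1L, 1) - 1L
      } else {
        snp_id <- snps$snp_id[sidx]
        o <- snps$pos[sidx] - start0
        posm <- if (strand == "-") w - o else o + 1L
      }
    } else {
      if (df$end[li] - df$start[li] < w) next
      start0 <- df$start[li] +
        sample.int(df$end[li] - df$start[li] - w + 1L, 1) - 1L
    }
    planted <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif_seq)))
    } else motif_seq
    substring(genome[ch], start0 + 1, start0 + w) <- planted
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = ch, start = start0, end = start0 + w, strand = strand,
      locus_index = li, snp_id = snp_id, position_in_motif = posm,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), locus_index = integer(0),
               snp_id = character(0), position_in_motif = integer(0))
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Simulate genotype-dependent binding signal
#'
#' Hardy-Weinberg genotypes at allele frequency \code{af}; the binding
#' signal is \code{base_signal * (2 - dosage) / 2} plus Gaussian noise, so
#' alternate-allele homozygotes lose binding entirely at zero noise (the
#' Fig.-3c-style allele-sensitive pattern).
#'
#' @param cfg a [sim_config()] (provides the seed).
#' @param af alt-allele frequency.
#' @param n_samples number of samples.
#' @param base_signal mean signal of reference homozygotes.
#' @param noise_sd Gaussian noise standard deviation.
#' @return list: \code{genotypes} (named vector sample -> dosage),
#'   \code{signals} (named vector sample -> signal).
#' @export
sim_genotype_binding <- function(cfg, af = 0.3, n_samples = 20,
                                 base_signal = 10, noise_sd = 1) {
  .set_stream(cfg$seed, "genotype_binding")
  samples <- sprintf("S%03d", seq_len(n_samples))
  dosage <- stats::rbinom(n_samples, 1, af) + stats::rbinom(n_samples, 1, af)
  signal <- base_signal * (2 - dosage) / 2 +
    stats::rnorm(n_samples, 0, noise_sd)
  list(genotypes = stats::setNames(dosage, samples),
       signals = stats::setNames(signal, samples))
}

#' Simulate a regulatory-score table for a SNP universe
#'
#' Assigns each SNP a category drawn from the closed vocabulary with
#' probabilities shaped like a real export (most SNPs in the weak
#' categories), a set of bound TFs for likely-affecting SNPs, and
#' occasional eQTL gene symbols.
#'
#' @param cfg a [sim_config()] (provides the seed).
#' @param snp_ids SNP id vector.
#' @param p_likely total probability mass on the likely-affecting
#'   categories (default 0.04, near the 3.8\% seen genome-wide).
#' @return data.frame: snp_id, category, bound_tfs (semicolon-joined),
#'   eqtl_genes (semicolon-joined).
#' @export
sim_reg_scores <- function(cfg, snp_ids, p_likely = 0.04) {
  .set_stream(cfg$seed, "reg_scores")
  snp_ids <- unique(snp_ids)
  likely <- LIKELY_AFFECTING_CATEGORIES
  weak <- setdiff(REG_SCORE_CATEGORIES, likely)
  probs <- c(stats::setNames(rep(p_likely / length(likely), length(likely)),
                             likely),
             stats::setNames(rep((1 - p_likely) / length(weak),
                                 length(weak)), weak))
  category <- sample(names(probs), length(snp_ids), replace = TRUE,
                     prob = probs)
  tf_pool <- c("NFKB1", "POLR2A", "EBF1", "PAX5", "RUNX3", "BATF", "IRF4",
               "STAT3", "SP1", "CTCF", "GATA4", "FOXO4")
  bound_tfs <- vapply(category, function(cat) {
    if (cat %in% likely) {
      # NFKB1 deliberately over-represented among likely-affecting SNPs
      n <- sample.int(4, 1)
      tfs <- unique(c(if (stats::runif(1) < 0.6) "NFKB1",
                      sample(tf_pool, n)))
      paste(sort(tfs), collapse = ";")
    } else ""
  }, character(1))
  gene_pool <- c("TLR1", "TLR6", "TLR10", "RPS26", "CCDC88", "LINC00299")
  eqtl_genes <- vapply(category, function(cat) {
    if (cat %in% c("1a", "1b", "1c", "1d", "1e", "1f") &&
        stats::runif(1) < 0.5) {
      paste(sample(gene_pool, sample.int(2, 1)), collapse = ";")
    } else ""
  }, character(1))
  data.frame(snp_id = snp_ids, category = category,
             bound_tfs = unname(bound_tfs), eqtl_genes = unname(eqtl_genes),
             stringsAsFactors = FALSE)
}

#' Harmonize panel alleles to a simulated genome
#'
#' Sets each panel site's ref allele to the genome base at its position
#' (and, when that collides with the recorded alt, swaps the alt to a
#' different base) so that allele-aware rescoring against the simulated
#' genome passes its reference check.
#'
#' @param panel a [haplotype_panel()].
#' @param genome named character vector (or \code{DNAStringSet}) of
#'   chromosome sequences.
#' @return the panel with updated site ref/alt columns.
#' @export
harmonize_panel_to_genome <- function(panel, genome) {
  if (!is.character(genome)) genome <- as.character(genome)
  sites <- panel$sites
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    if (!ch %in% names(genome)) next
    base <- toupper(substring(genome[[ch]], sites$pos[i] + 1,
                              sites$pos[i] + 1))
    if (base %in% c("A", "C", "G", "T")) {
      if (sites$alt[i] == base || sites$ref[i] != base) {
        if (sites$alt[i] == base) {
          sites$alt[i] <- setdiff(c("A", "C", "G", "T"), base)[1]
        }
        sites$ref[i] <- base
      }
    }
  }
  panel$sites <- sites
  panel
}
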