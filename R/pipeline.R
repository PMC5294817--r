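# Pipeline driver: merge -> ld-expand -> overlap -> enrich -> motif-scan
# -> annotate -> intersect -> report, on files, with a run manifest.

#' Default pipeline configuration
#'
#' @param beds named character vector of BED paths (one per ChIP-seq
#'   dataset; names are the dataset labels).
#' @param catalog GWAS catalog TSV path.
#' @param panel_vcf phased panel VCF path (or NULL with
#'   \code{panel_tsv}).
#' @param panel_tsv plain haplotype-matrix TSV path (used when
#'   \code{panel_vcf} is NULL).
#' @param genome_fasta genome FASTA path (NULL disables the motif and
#'   delta-LOD stages).
#' @param reg_scores regulatory-score TSV path (NULL disables the
#'   annotation stage).
#' @param cobinding_bed BED path of a second cistrome to intersect (NULL
#'   disables the intersection stage).
#' @param r2_min,maf_min,window_bp LD thresholds (see [ld_config()]).
#' @param min_fraction,reciprocal fractional-intersection criterion (see
#'   [fractional_intersect()]).
#' @param motif_threshold_frac scan threshold as a fraction of the
#'   consensus score.
#' @param scan_flank bp scanned around each locus midpoint (NULL = whole
#'   locus).
#' @param m_policy,alpha Bonferroni policy and significance level (see
#'   [trait_enrichment()]).
#' @param seed integer seed recorded in the manifest (the pipeline's own
#'   stages are deterministic; the seed drives any simulation used to
#'   produce the inputs).
#' @return list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(beds, catalog, panel_vcf = NULL,
                            panel_tsv = NULL, genome_fasta = NULL,
                            reg_scores = NULL, cobinding_bed = NULL,
                            r2_min = 0.8, maf_min = 0.05,
                            window_bp = 500000, min_fraction = 0.25,
                            reciprocal = FALSE,
                            motif_threshold_frac = 0.8, scan_flank = 100,
                            m_policy = "tested", alpha = 0.05, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... overrides applied after reading (override wins).
#' @return list of class \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  if (!is.null(y$beds)) y$beds <- unlist(y$beds)
  do.call(pipeline_config, y)
}

.stage_outputs <- list(
  merge = "consensus.bed",
  ld_expand = c("snps.tsv", "associations.tsv"),
  overlap = "assignments.tsv",
  enrich = "enrichment.tsv",
  motif_scan = c("motif_hits.tsv", "snp_motif.tsv"),
  annotate = c("score_distribution.tsv", "tf_frequency.tsv",
               "eqtl_table.tsv"),
  intersect = "cobinding.tsv",
  report = "manifest.json"
)

#' Run the full integration pipeline
#'
#' Executes merge, LD expansion, SNP-to-peak overlap, per-phenotype
#' enrichment, motif scanning with delta-LOD annotation, regulatory-score
#' annotation, fractional cistrome intersection and the run manifest, in
#' order, writing plain TSV/BED/JSON outputs under \code{out_dir}. A
#' stage whose outputs already exist is skipped (so deleting a stage's
#' outputs and rerunning regenerates it and everything downstream
#' identically); \code{force = TRUE} reruns everything. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param out_dir output directory (created if missing).
#' @param force rerun stages whose outputs already exist.
#' @return (invisibly) \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  outp <- function(f) file.path(out_dir, f)
  done <- function(stage) {
    all(file.exists(outp(.stage_outputs[[stage]])))
  }
  run_stage <- function(stage, fn) {
    if (!force && done(stage)) {
      log_msg("stage ", stage, ": outputs present, skipped")
      return(invisible(NULL))
    }
    log_msg("stage ", stage, ": running")
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- c(config$beds, config$catalog, config$panel_vcf,
              config$panel_tsv, config$genome_fasta, config$reg_scores,
              config$cobinding_bed)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    stop("missing input file(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }

  run_stage("merge", function() {
    labels <- names(config$beds)
    if (is.null(labels)) labels <- sub("\\.bed$", "", basename(config$beds))
    sets <- lapply(seq_along(config$beds), function(i) {
      read_bed(config$beds[[i]], name = labels[i])
    })
    consensus <- merge_consensus(sets)
    write_bed(consensus, outp("consensus.bed"))
    log_msg("merged ", length(sets), " peak sets into ",
            length(consensus), " consensus loci")
  })
  consensus <- read_bed(outp("consensus.bed"), name = "consensus")
  names(S4Vectors::mcols(consensus))[
    names(S4Vectors::mcols(consensus)) == "name"] <- "sources"

  run_stage("ld_expand", function() {
    catalog <- read_gwas_catalog(config$catalog)
    panel <- if (!is.null(config$panel_vcf)) {
      read_panel_vcf(config$panel_vcf)
    } else read_haplotype_tsv(config$panel_tsv)
    leads <- catalog[!duplicated(catalog$snp_id),
                     c("snp_id", "chrom", "pos")]
    cfg_ld <- ld_config(r2_min = config$r2_min, maf_min = config$maf_min,
                        window_bp = config$window_bp)
    snps <- expand_leads(leads, panel, cfg_ld)
    write_tsv_table(snps, outp("snps.tsv"))
    # proxies inherit every trait of their lead
    assoc <- merge(catalog[c("trait", "snp_id")],
                   snps[c("snp_id", "lead_id")],
                   by.x = "snp_id", by.y = "lead_id")
    assoc <- data.frame(trait = assoc$trait, snp_id = assoc$snp_id.y,
                        lead_id = assoc$snp_id, stringsAsFactors = FALSE)
    assoc <- assoc[!duplicated(assoc[c("trait", "snp_id")]), , drop = FALSE]
    assoc <- assoc[order(assoc$trait, assoc$snp_id), , drop = FALSE]
    write_tsv_table(assoc, outp("associations.tsv"))
    log_msg(nrow(leads), " leads expanded to ",
            length(unique(assoc$snp_id)), " universe SNPs")
  })
  snps <- read_tsv_table(outp("snps.tsv"))
  assocs <- read_tsv_table(outp("associations.tsv"))

  run_stage("overlap", function() {
    ov <- overlap_snps(snps[!duplicated(snps$snp_id), ], consensus)
    write_tsv_table(ov$assignments, outp("assignments.tsv"))
    log_msg(ov$n_snps_under_loci, " distinct SNPs under consensus loci")
  })
  assignments <- read_tsv_table(outp("assignments.tsv"))
  assignments$snp_id <- as.character(assignments$snp_id)
  assignments$sources <- as.character(assignments$sources)
  overlap_res <- list(assignments = assignments,
                      n_snps_under_loci =
                        length(unique(assignments$snp_id)))

  run_stage("enrich", function() {
    labels <- names(config$beds)
    if (is.null(labels)) labels <- sub("\\.bed$", "", basename(config$beds))
    enr <- trait_enrichment(assocs, overlap_res, peak_sets = labels,
                            m_policy = config$m_policy)
    write_tsv_table(enr, outp("enrichment.tsv"))
    log_msg(sum(enr$p_corrected < config$alpha & enr$peak_set ==
                  "combined"), " traits significant at alpha = ",
            config$alpha, " (combined set)")
  })
  enr <- read_tsv_table(outp("enrichment.tsv"))

  if (!is.null(config$genome_fasta)) {
    run_stage("motif_scan", function() {
      genome <- read_genome_fasta(config$genome_fasta)
      model <- motif_model()
      model$score_threshold <- config$motif_threshold_frac * model$max_score
      hits <- scan_loci(genome, consensus, model,
                        flank_from_midpoint = config$scan_flank)
      write_tsv_table(hits, outp("motif_hits.tsv"))
      under <- snps[snps$snp_id %in% assignments$snp_id, , drop = FALSE]
      under <- under[!duplicated(under$snp_id), , drop = FALSE]
      ann <- snp_in_motif(under, hits)
      if (nrow(ann) > 0) {
        ann$delta_lod <- NA_real_
        for (i in seq_len(nrow(ann))) {
          rec <- under[under$snp_id == ann$snp_id[i], ][1, ]
          if (is.na(rec$ref) || is.na(rec$alt)) next
          chrom_seq <- as.character(genome[[ann$chrom[i]]])
          ann$delta_lod[i] <- tryCatch(
            delta_lod(model, chrom_seq,
                      list(snp_id = rec$snp_id, pos = rec$pos,
                           ref = rec$ref, alt = rec$alt),
                      ann[i, ], context_origin = 0),
            error = function(e) {
              log_msg("delta_lod skipped for ", rec$snp_id, ": ",
                      conditionMessage(e))
              NA_real_
            })
        }
      } else ann$delta_lod <- numeric(0)
      write_tsv_table(ann, outp("snp_motif.tsv"))
      log_msg(nrow(hits), " motif hits; ", nrow(ann),
              " SNP-in-motif annotations")
    })
  }

  if (!is.null(config$reg_scores)) {
    run_stage("annotate", function() {
      reg <- read_reg_scores(config$reg_scores)
      universe_ids <- unique(assocs$snp_id)
      under_ids <- unique(assignments$snp_id)
      sig_traits <- unique(enr$trait[enr$p_corrected < config$alpha &
                                       enr$peak_set == "combined"])
      sig_rows <- enr[enr$peak_set == "combined" &
                        enr$trait %in% sig_traits, , drop = FALSE]
      sig_ids <- unique(unlist(lapply(
        strsplit(sig_rows$snps_under_peaks[
          nzchar(sig_rows$snps_under_peaks)], ",", fixed = TRUE),
        function(p) sub("/.*$", "", p))))
      dist <- score_distribution(
        list(universe = universe_ids, under_peaks = under_ids,
             significant = sig_ids), reg)
      write_tsv_table(dist, outp("score_distribution.tsv"))
      likely <- classify_likely_affecting(
        reg[reg$snp_id %in% sig_ids, , drop = FALSE])
      tf <- tf_cooccurrence(likely$likely$snp_id, reg)
      write_tsv_table(tf, outp("tf_frequency.tsv"))
      eqtl <- reg[reg$snp_id %in% sig_ids & nzchar(reg$eqtl_genes),
                  c("snp_id", "category", "eqtl_genes"), drop = FALSE]
      write_tsv_table(eqtl, outp("eqtl_table.tsv"))
      log_msg(likely$n_likely, "/", length(sig_ids),
              " significant SNPs likely to affect TF binding")
    })
  }

  if (!is.null(config$cobinding_bed)) {
    run_stage("intersect", function() {
      other <- read_bed(config$cobinding_bed)
      cb <- fractional_intersect(consensus, other,
                                 min_fraction = config$min_fraction,
                                 reciprocal = config$reciprocal)
      write_tsv_table(data.frame(
        n_shared = cb$n_shared, n_only_a = cb$n_only_a,
        n_only_b = cb$n_only_b, min_fraction = cb$min_fraction,
        reciprocal = cb$reciprocal), outp("cobinding.tsv"))
      write_bed(cb$shared_loci, outp("shared_loci.bed"))
      log_msg(cb$n_shared, " consensus loci shared with the second cistrome")
    })
  }

  run_stage("report", function() {
    write_manifest(config, out_dir)
    log_msg("manifest written")
  })
  invisible(out_dir)
}

#' Write the run manifest
#'
#' Records the package version, timestamp, seed, every threshold actually
#' used and md5 checksums of all input files, as JSON, alongside the
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) the manifest path.
#' @export
write_manifest <- function(config, out_dir) {
  inputs <- c(config$beds, catalog = config$catalog,
              panel_vcf = config$panel_vcf, panel_tsv = config$panel_tsv,
              genome_fasta = config$genome_fasta,
              reg_scores = config$reg_scores,
              cobinding_bed = config$cobinding_bed)
  manifest <- list(
    tool = "cistrovar",
    version = as.character(utils::packageVersion("cistrovar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    thresholds = list(r2_min = config$r2_min, maf_min = config$maf_min,
                      window_bp = config$window_bp,
                      min_fraction = config$min_fraction,
                      reciprocal = config$reciprocal,
                      motif_threshold_frac = config$motif_threshold_frac,
                      scan_flank = config$scan_flank,
                      m_policy = config$m_policy, alpha = config$alpha),
    input_md5 = as.list(tools::md5sum(unlist(inputs)))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
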