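## End-to-end orchestration: run the stages in dependency order from a
## validated configuration, writing stage TSVs, a JSON summary with full
## threshold provenance, and a log.

.default_thresholds <- function() {
  list(
    merge_slack = 0L, count_mode = "max",
    min_total_reads = 5L, min_samples = 2L, min_detectors = 2L,
    lfc_threshold = 2, padj_threshold = 0.05, base_mean_threshold = 10,
    fold_margin_log2 = 1,
    motif_p_threshold = 0.001, bin_width = 100L,
    alu_min_fraction = 0.5,
    seed_span = c(2L, 8L), allowed_mismatches = 0L
  )
}

.known_config_keys <- c("inputs", "outdir", "stages", "thresholds", "seed")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from JSON via
#' [read_pipeline_config()]) with `inputs` (named file paths), `outdir`,
#' optional `stages` (subset of catalog, concordance, burden, motifs,
#' introns, axes), optional `thresholds` overriding the defaults, and
#' `seed`. Unknown top-level or threshold keys are rejected; referenced
#' input files must exist.
#'
#' @param config Named list.
#' @return The completed configuration (defaults filled in).
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$outdir)) stop("configuration requires 'outdir'")
  defaults <- .default_thresholds()
  th <- config$thresholds
  bad <- setdiff(names(th), names(defaults))
  if (length(bad)) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  }
  config$thresholds <- utils::modifyList(defaults, as.list(th))
  if (is.null(config$stages)) {
    config$stages <- c("catalog", "concordance", "burden", "motifs",
                       "introns", "axes")
  }
  if (is.null(config$seed)) config$seed <- 1L
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("configuration input does not exist: ", p)
  }
  config
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the structure described in
#'   [validate_pipeline_config()].
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(
    jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full downstream pipeline
#'
#' Stages run in dependency order (catalog, concordance, burden,
#' motifs, introns, axes); each enabled stage writes its tables under
#' `outdir` and contributes to `summary.json`, which echoes every
#' threshold used. A stage failure aborts with the stage name and
#' cause. Reruns on identical inputs and configuration are
#' bit-identical (the log, which carries timestamps, is written
#' separately as `pipeline.log`).
#'
#' @param config Configuration list ([validate_pipeline_config()] is
#'   applied) whose `inputs` name the files written by
#'   [write_synthetic_inputs()] or equivalent real data: `gtf`,
#'   `bsj_*` (one per detector), `de_circ`, `de_linear`, `pairing`,
#'   `variants`, `alu`, `genome`, `mirna_circ_sites`,
#'   `mirna_utr_sites`, `motifs_tsv` (consensus motif TSV).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  th <- config$thresholds
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(thresholds = th, stages = config$stages,
                 seed = config$seed)
  inp <- config$inputs
  enabled <- function(s) s %in% config$stages

  exons <- if (!is.null(inp$gtf)) read_gtf(inp$gtf) else NULL
  catalog <- NULL

  if (enabled("catalog")) {
    catalog <- stage("catalog", {
      det_paths <- inp[grep("^bsj_", names(inp))]
      calls <- rbindlist(lapply(names(det_paths), function(nm) {
        read_bsj_calls(det_paths[[nm]], detector = sub("^bsj_", "", nm))
      }))
      merged <- merge_bsj_calls(calls, slack = th$merge_slack,
                                count_mode = th$count_mode)
      n_total <- nrow(merged)
      expr_f <- filter_expression(merged, th$min_total_reads,
                                  th$min_samples)
      det_f <- filter_detector_support(expr_f, th$min_detectors)
      ann <- annotate_splice_status(det_f, exons)
      write_tsv_table(ann, file.path(outdir, "catalog.tsv"))
      summ <- host_gene_summary(ann, n_total = n_total,
                                n_expression_filtered = nrow(expr_f))
      report$catalog <- unclass(summ)
      ann
    })
  }

  if (enabled("concordance")) {
    stage("concordance", {
      circ_de <- read_de_table(inp$de_circ)
      lin_de <- read_de_table(inp$de_linear)
      pairing <- read_tsv_table(inp$pairing)
      corr <- lfc_correlation(circ_de, lin_de, pairing)
      pairs_lfc <- merge(
        merge(pairing,
              circ_de[, .(circ_id = feature_id, lfc_circ = lfc)],
              by = "circ_id"),
        lin_de[, .(gene_id = feature_id, lfc_linear = lfc)],
        by = "gene_id")
      fr <- fold_ratio_stats(pairs_lfc, margin_log2 = th$fold_margin_log2)
      labels <- classify_de(circ_de, th$lfc_threshold, th$padj_threshold)
      report$concordance <- list(
        r = corr$r, p = corr$p, n_pairs = corr$n_pairs,
        fraction_exceeding = fr$fraction_exceeding,
        mean_excess = fr$mean_excess_top_n,
        n_up = sum(labels == "up"), n_down = sum(labels == "down"))
      write_tsv_table(data.table(feature_id = circ_de$feature_id,
                                 label = as.character(labels)),
                      file.path(outdir, "de_labels.tsv"))
    })
  }

  exon_classes <- NULL
  if (enabled("burden")) {
    stage("burden", {
      variants <- read_variants(inp$variants)
      exon_classes <- classify_catalog_exons(catalog, exons)
      res_circ <- burden_compare(exon_classes, variants, grouping = "circ")
      res_bsj <- burden_compare(exon_classes, variants, grouping = "bsj")
      bed <- copy(exon_classes)[, name := fifelse(circ_class == "circ",
                                  paste0("circ/", bsj_class), "nonCirc")]
      write_bed(bed[, .(chrom, start, end, name, score = 0L, strand)],
                file.path(outdir, "exon_classes.bed"))
      keep <- c("group_a", "group_b", "n_variants_a", "n_variants_b",
                "total_kb_a", "total_kb_b", "freq_per_kb_a",
                "freq_per_kb_b", "rate_ratio", "z", "p_z", "p_wilcoxon")
      report$burden <- list(circ = unclass(res_circ)[keep],
                              bsj = unclass(res_bsj)[keep])
    })
  }

  pairs <- NULL
  if (enabled("motifs") || enabled("introns")) {
    pairs <- catalog_flanking_introns(catalog, exons)
  }

  if (enabled("motifs")) {
    stage("motifs", {
      genome <- read_genome_fasta(inp$genome)
      motifs <- read_consensus_motifs(inp$motifs_tsv)
      ann <- catalog[annotation == "annotated"]
      seqs <- setNames(vapply(seq_len(nrow(ann)), function(r) {
        extract_circ_sequence(ann[r], exons, genome)
      }, character(1)), ann$circ_id)
      hits <- scan_sequences(seqs, motifs,
                             p_threshold = th$motif_p_threshold)
      write_tsv_table(hits, file.path(outdir, "motif_hits.tsv"))
      report$motifs <- list(n_sequences = length(seqs),
                              n_hits = nrow(hits))
    })
  }

  if (enabled("introns")) {
    stage("introns", {
      alus <- read_alu_elements(inp$alu)
      kept <- filter_alu_overlap(alus, pairs, th$alu_min_fraction)
      iae <- rbindlist(lapply(seq_len(nrow(pairs)), function(r) {
        closest_alu_pair(pairs[r], kept)
      }))
      classified <- classify_circ_introns(pairs, iae)
      write_tsv_table(classified, file.path(outdir, "intron_classes.tsv"))
      report$introns <- list(
        n_circ = nrow(classified),
        median_length = attr(classified, "median_length"),
        median_alu_distance = attr(classified, "median_alu_distance"),
        class_counts = as.list(table(classified$intron_class)))
    })
  }

  if (enabled("axes")) {
    stage("axes", {
      circ_sites <- read_tsv_table(inp$mirna_circ_sites)
      utr_sites <- read_tsv_table(inp$mirna_utr_sites)
      circ_de <- read_de_table(inp$de_circ)
      lin_de <- read_de_table(inp$de_linear)
      ax <- build_axes(circ_sites, utr_sites, circ_de, lin_de,
                       th$lfc_threshold, th$padj_threshold)
      write_tsv_table(ax$axes, file.path(outdir, "axes.tsv"))
      report$axes <- list(n_axes = nrow(ax$axes),
                            max_sites_per_circ = ax$max_sites_per_circ)
    })
  }

  jsonlite::write_json(report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  logmsg("pipeline finished")
  invisible(report)
}
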