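## circRNA catalogue construction: merge per-detector BSJ call tables,
## apply expression and detector-support filters, annotate splice status
## against gene models, and summarise host genes.

#' Read a per-detector BSJ call table
#'
#' Input is tab-separated with header columns `chrom`, `start`, `end`,
#' `strand` followed by one numeric read-count column per sample.
#' Detector coordinate dialects are normalised here: CIRI-style output is
#' 1-based inclusive, BED-style output already 0-based half-open.
#'
#' @param path TSV path.
#' @param detector Detector label attached to every call.
#' @param coords `"zero_half_open"` (BED dialect, default) or
#'   `"one_based"` (CIRI dialect, converted on read).
#' @return `data.table` of BSJ calls in internal coordinates with a
#'   `detector` column and per-sample count columns.
#' @export
read_bsj_calls <- function(path, detector,
                           coords = c("zero_half_open", "one_based")) {
  coords <- match.arg(coords)
  dt <- read_tsv_table(path)
  required <- c("chrom", "start", "end", "strand")
  if (!all(required %in% names(dt))) {
    stop("BSJ table ", path, " must have columns chrom, start, end, strand")
  }
  if (coords == "one_based") dt <- from_one_based(dt)
  validate_intervals(dt)
  count_cols <- setdiff(names(dt), c(required, "detector"))
  if (!length(count_cols)) stop("BSJ table ", path, " has no count columns")
  if (any(vapply(dt[, ..count_cols], function(x) any(x < 0), logical(1)))) {
    stop("negative read counts in ", path)
  }
  dt[, detector := detector]
  setcolorder(dt, c(required, "detector", count_cols))
  dt[]
}

## internal: names of per-sample count columns on a call/catalog table
.count_cols <- function(dt) {
  setdiff(names(dt), c("chrom", "start", "end", "strand", "detector",
                       "detectors", "n_detectors", "circ_id", "host_gene",
                       "annotation", "known_id", "bs_exon_from", "bs_exon_to",
                       "transcript_id", "strand_conflict"))
}

#' Merge BSJ calls from multiple detectors into one catalogue
#'
#' Calls whose BSJ coordinates agree within `slack` bases on both ends
#' and share chromosome and strand collapse into a single circRNA record.
#' Detector sets are unioned; per-sample counts are combined with
#' `count_mode` (default maximum across detectors, avoiding
#' double-counting of the same junction reads); output coordinates are
#' those of the first detector in `detector_priority` present in the
#' group. Records sharing exact coordinates but disagreeing on strand are
#' never merged and carry `strand_conflict = TRUE`.
#'
#' Merging is idempotent: re-merging a merged catalogue is a no-op.
#'
#' @param calls BSJ call table ([read_bsj_calls()] output, possibly
#'   several detectors row-bound, or a previously merged catalogue).
#' @param slack Non-negative coordinate slack in bases (default 0: exact
#'   match). Clustering with positive slack is greedy on sorted starts.
#' @param detector_priority Character vector ordering detectors for
#'   coordinate choice; defaults to sorted detector labels.
#' @param count_mode `"max"` (default) or `"mean"`.
#' @return Catalogue `data.table` with interim `circ_id`
#'   (`circ_<chrom>:<start1>-<end>`), `detectors` (comma-joined),
#'   `n_detectors`, merged counts and `strand_conflict`.
#' @export
merge_bsj_calls <- function(calls, slack = 0L, detector_priority = NULL,
                            count_mode = c("max", "mean")) {
  count_mode <- match.arg(count_mode)
  stopifnot(slack >= 0L)
  calls <- as.data.table(calls)
  if ("detectors" %in% names(calls) && !"detector" %in% names(calls)) {
    setnames(calls, "detectors", "detector")  # accept merged catalogues
  }
  validate_intervals(calls)
  count_cols <- .count_cols(calls)
  if (is.null(detector_priority)) {
    detector_priority <- sort(unique(unlist(strsplit(calls$detector, ","))))
  }

  calls <- copy(calls)
  if (slack == 0L) {
    calls[, cluster := .GRP, by = .(chrom, strand, start, end)]
  } else {
    setorder(calls, chrom, strand, start, end)
    calls[, cluster := {
      cl <- integer(.N); cur <- 1L; s0 <- start[1L]; e0 <- end[1L]
      for (k in seq_len(.N)) {
        if (k > 1L && (abs(start[k] - s0) > slack || abs(end[k] - e0) > slack)) {
          cur <- cur + 1L; s0 <- start[k]; e0 <- end[k]
        }
        cl[k] <- cur
      }
      cl
    }, by = .(chrom, strand)]
    calls[, cluster := .GRP, by = .(chrom, strand, cluster)]
  }

  agg <- calls[, {
    dets <- sort(unique(unlist(strsplit(detector, ","))))
    pri <- detector_priority[detector_priority %in% detector]
    rep_row <- if (length(pri)) which(detector == pri[1L])[1L] else 1L
    cnt <- lapply(.SD, function(x) {
      if (count_mode == "max") max(x) else mean(x)
    })
    c(list(chrom = chrom[rep_row], start = start[rep_row],
           end = end[rep_row], strand = strand[rep_row],
           detectors = paste(dets, collapse = ","),
           n_detectors = length(dets)),
      cnt)
  }, by = cluster, .SDcols = count_cols]
  agg[, cluster := NULL]

  # same exact coordinates on opposite strands: flag, never merge
  agg[, strand_conflict := .N > 1L, by = .(chrom, start, end)]
  agg[, circ_id := sprintf("circ_%s:%d-%d", chrom, start + 1L, end)]
  setcolorder(agg, c("circ_id", "chrom", "start", "end", "strand",
                     "detectors", "n_detectors", count_cols,
                     "strand_conflict"))
  setorder(agg, chrom, start, end, strand)
  agg[]
}

#' Filter a catalogue on minimum expression
#'
#' Keeps circRNAs with total merged reads of at least `min_total_reads`
#' and at least `min_samples` samples with one or more reads. The source
#' study does not print its expression thresholds; the defaults here are
#' deliberately conservative and configurable.
#'
#' @param circs Merged catalogue.
#' @param min_total_reads,min_samples Non-negative thresholds.
#' @return Filtered catalogue.
#' @export
filter_expression <- function(circs, min_total_reads = 5L, min_samples = 2L) {
  stopifnot(min_total_reads >= 0L, min_samples >= 0L)
  count_cols <- .count_cols(circs)
  m <- as.matrix(circs[, ..count_cols])
  keep <- rowSums(m) >= min_total_reads & rowSums(m >= 1) >= min_samples
  circs[keep]
}

#' Filter a catalogue on detector support
#'
#' @param circs Merged catalogue.
#' @param min_detectors Minimum number of distinct detectors (default 2,
#'   the "detected by at least two programmes" rule).
#' @return Filtered catalogue.
#' @export
filter_detector_support <- function(circs, min_detectors = 2L) {
  stopifnot(min_detectors >= 1L)
  circs[n_detectors >= min_detectors]
}

#' Annotate catalogue splice status against gene models
#'
#' A circRNA is `annotated` when both BSJ coordinates coincide exactly
#' with exon boundaries (the BSJ start with an exon start, the BSJ end
#' with an exon end) of one transcript on the same chromosome and
#' strand; its host gene and back-spliced exon indices are then recorded
#' and the identifier is rewritten as `HOSTGENE_chrom:start-end` (1-based
#' inclusive). When transcripts of more than one gene match, the gene of
#' the longest matching transcript wins and a warning is logged.
#' All other circRNAs are `de_novo` with `host_gene = "intergenic"`.
#' When a known-circRNA lookup is supplied, matching records get its id.
#'
#' @param circs Merged catalogue.
#' @param exons Transcript models ([read_gtf()]).
#' @param known Optional lookup table with `chrom`, `start`, `end`,
#'   `strand`, `known_id` in internal coordinates.
#' @return Catalogue with `host_gene`, `annotation`, `transcript_id`,
#'   `bs_exon_from`, `bs_exon_to`, `known_id` columns.
#' @export
annotate_splice_status <- function(circs, exons, known = NULL) {
  circs <- copy(as.data.table(circs))
  tl <- transcript_lengths(exons)
  circs[, `:=`(host_gene = "intergenic", annotation = "de_novo",
               transcript_id = NA_character_,
               bs_exon_from = NA_integer_, bs_exon_to = NA_integer_,
               known_id = NA_character_)]
  for (r in seq_len(nrow(circs))) {
    cc <- circs[r]
    cand <- exons[chrom == cc$chrom & strand == cc$strand &
                    transcript_id %in%
                    intersect(exons[chrom == cc$chrom & start == cc$start,
                                    transcript_id],
                              exons[chrom == cc$chrom & end == cc$end,
                                    transcript_id])]
    if (nrow(cand) == 0L) next
    txs <- unique(cand$transcript_id)
    genes <- unique(cand$gene_id)
    pick <- tl[transcript_id %in% txs][order(-tx_len, transcript_id)][1L]
    if (length(genes) > 1L) {
      warning("BSJ ", cc$circ_id, " matches exon boundaries of ",
              length(genes), " genes; resolved to longest transcript ",
              pick$transcript_id)
    }
    tx_ex <- exons[transcript_id == pick$transcript_id]
    i <- tx_ex[start == cc$start, exon_index]
    j <- tx_ex[end == cc$end, exon_index]
    if (!length(i) || !length(j)) next  # boundary split across transcripts
    gene_nm <- tx_ex$gene_name[1L]
    circs[r, `:=`(host_gene = gene_nm, annotation = "annotated",
                  transcript_id = pick$transcript_id,
                  bs_exon_from = i[1L], bs_exon_to = j[1L])]
  }
  circs[annotation == "annotated",
        circ_id := sprintf("%s_%s:%d-%d", host_gene, chrom, start + 1L, end)]
  if (!is.null(known)) {
    known <- as.data.table(known)
    circs[known, known_id := i.known_id,
          on = c("chrom", "start", "end", "strand")]
  }
  circs[]
}

#' Summarise a catalogue by host gene
#'
#' Hotspot genes are hosts generating more than ten circRNAs (eleven or
#' more); multi-isoform genes host two or more.
#'
#' @param circs Annotated catalogue (the final, multi-detector-filtered
#'   set).
#' @param n_total Raw call count before any filtering (optional
#'   provenance; defaults to `nrow(circs)`).
#' @param n_expression_filtered Count after the expression filter
#'   (optional; defaults to `nrow(circs)`).
#' @return List of class `catalog_summary` with counts and
#'   `hotspot_genes`.
#' @export
host_gene_summary <- function(circs, n_total = nrow(circs),
                              n_expression_filtered = nrow(circs)) {
  stopifnot(nrow(circs) <= n_expression_filtered,
            n_expression_filtered <= n_total)
  hosts <- circs[annotation == "annotated", .N, by = host_gene]
  out <- list(
    n_total = as.integer(n_total),
    n_expression_filtered = as.integer(n_expression_filtered),
    n_multi_detector = nrow(circs),
    n_known = sum(!is.na(circs$known_id)),
    n_novel = sum(circs$annotation == "annotated" & is.na(circs$known_id)),
    n_de_novo = sum(circs$annotation == "de_novo"),
    n_host_genes = nrow(hosts),
    n_multi_isoform_genes = sum(hosts$N >= 2L),
    hotspot_genes = sort(hosts[N >= 11L, host_gene])
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("circRNA catalogue summary\n")
  cat(sprintf("  raw calls:              %d\n", x$n_total))
  cat(sprintf("  expression-filtered:    %d (%.1f%%)\n",
              x$n_expression_filtered,
              100 * x$n_expression_filtered / max(x$n_total, 1L)))
  cat(sprintf("  multi-detector:         %d (%.1f%%)\n", x$n_multi_detector,
              100 * x$n_multi_detector / max(x$n_expression_filtered, 1L)))
  cat(sprintf("  known / novel / de novo: %d / %d / %d\n",
              x$n_known, x$n_novel, x$n_de_novo))
  cat(sprintf("  host genes:             %d (%d multi-isoform, %d hotspot)\n",
              x$n_host_genes, x$n_multi_isoform_genes,
              length(x$hotspot_genes)))
  invisible(x)
}

#' Percentage of records surviving a filtering step
#'
#' Convenience for reporting filter survival from printed or computed
#' counts, e.g. raw calls versus the expression-filtered set.
#'
#' @param n_before,n_after Counts before and after the filter.
#' @return Percentage (0-100).
#' @examples
#' filter_survival_pct(60531, 6540) # ~10.8
#' @export
filter_survival_pct <- function(n_before, n_after) {
  stopifnot(n_before > 0, n_after >= 0, n_after <= n_before)
  100 * n_after / n_before
}
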