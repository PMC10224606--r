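## Post-model statistics on differential-expression and exon-usage
## tables: circ/linear LFC concordance, exon-bin aggregation,
## differential-splicing classification, hypergeometric splicing-rate /
## gene-set tests, and the shared two-sample Z-test.

#' Classify differential-expression records as up / down / ns
#'
#' A record is `up` when `lfc >= lfc_threshold` and
#' `padj < padj_threshold`, `down` when `lfc <= -lfc_threshold` with the
#' same padj condition (both LFC comparisons inclusive), otherwise `ns`.
#' Missing `padj` is never significant.
#'
#' @param records Table with `lfc` and `padj` columns (the standard
#'   DESeq2-style export: `feature_id`, `baseMean`, `log2FoldChange`,
#'   `padj` is accepted via [read_de_table()]).
#' @param lfc_threshold,padj_threshold Positive thresholds; defaults are
#'   the |LFC| >= 2, padj < 0.05 rule.
#' @return Factor vector over `up`, `down`, `ns` (one label per record;
#'   the three classes partition the input).
#' @export
classify_de <- function(records, lfc_threshold = 2, padj_threshold = 0.05) {
  stopifnot(lfc_threshold > 0, padj_threshold > 0)
  sig <- !is.na(records$padj) & records$padj < padj_threshold
  lab <- rep("ns", nrow(records))
  lab[sig & records$lfc >= lfc_threshold] <- "up"
  lab[sig & records$lfc <= -lfc_threshold] <- "down"
  factor(lab, levels = c("up", "down", "ns"))
}

#' Read a DESeq2-style differential-expression table
#'
#' @param path TSV with header `feature_id`, `baseMean`,
#'   `log2FoldChange`, `padj` (or already-internal `lfc`/`base_mean`
#'   names).
#' @return `data.table` with `feature_id`, `base_mean`, `lfc`, `padj`.
#' @export
read_de_table <- function(path) {
  dt <- read_tsv_table(path)
  map <- c(baseMean = "base_mean", log2FoldChange = "lfc")
  for (nm in names(map)) {
    if (nm %in% names(dt)) setnames(dt, nm, map[[nm]])
  }
  required <- c("feature_id", "base_mean", "lfc", "padj")
  if (!all(required %in% names(dt))) {
    stop("DE table ", path, " must have columns ",
         paste(required, collapse = ", "))
  }
  if (any(dt$base_mean < 0, na.rm = TRUE)) stop("negative base_mean in ", path)
  if (any(dt$padj < 0 | dt$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0,1] in ", path)
  }
  dt[]
}

#' Pearson correlation of paired circular and linear LFCs
#'
#' Pairs each circRNA with its host-gene linear record through `pairing`
#' and computes the Pearson correlation with a t-distribution p-value.
#' Unpaired records are dropped and counted.
#'
#' @param circ,linear DE tables ([read_de_table()] shape).
#' @param pairing Table with `circ_id`, `gene_id` mapping circRNA ids to
#'   host linear feature ids.
#' @return List with `r`, `p`, `conf_int` (95% CI for r), `n_pairs`,
#'   `n_dropped`.
#' @export
lfc_correlation <- function(circ, linear, pairing) {
  pairing <- as.data.table(pairing)
  m <- merge(pairing, as.data.table(circ)[, .(circ_id = feature_id, lfc_circ = lfc)],
             by = "circ_id")
  m <- merge(m, as.data.table(linear)[, .(gene_id = feature_id, lfc_linear = lfc)],
             by = "gene_id")
  m <- m[!is.na(lfc_circ) & !is.na(lfc_linear)]
  n_dropped <- nrow(pairing) - nrow(m)
  if (nrow(m) < 3L) stop("insufficient data: fewer than 3 matched LFC pairs")
  ct <- cor.test(m$lfc_circ, m$lfc_linear, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       conf_int = as.numeric(ct$conf.int),
       n_pairs = nrow(m), n_dropped = n_dropped)
}

#' Circ-over-linear fold-ratio statistics
#'
#' Reports the fraction of pairs whose circRNA LFC exceeds its linear
#' counterpart by more than `margin_log2` (default one log2 unit, i.e.
#' "over two-fold higher"), and the mean linear-scale excess
#' `2^(lfc_circ - lfc_linear)` over the `top_n` pairs ranked by circRNA
#' LFC.
#'
#' @param pairs Table with `lfc_circ` and `lfc_linear` columns.
#' @param margin_log2 Log2 margin defining "exceeding" (strict `>`).
#' @param top_n Number of top circRNAs for the mean-excess summary
#'   (default all pairs).
#' @return List with `fraction_exceeding` and `mean_excess_top_n`.
#' @export
fold_ratio_stats <- function(pairs, margin_log2 = 1, top_n = nrow(pairs)) {
  stopifnot(nrow(pairs) > 0L)
  excess <- pairs$lfc_circ - pairs$lfc_linear
  topi <- order(-pairs$lfc_circ)[seq_len(min(top_n, nrow(pairs)))]
  list(
    fraction_exceeding = mean(excess > margin_log2),
    mean_excess_top_n = mean(2^excess[topi])
  )
}

#' Aggregate exon bins to annotated exons
#'
#' DEXSeq-style exon bins mapping to one annotated exon are collapsed:
#' LFC and base mean as arithmetic means over bins, padj as the minimum
#' bin padj (consistent with the "at least one differentially used bin"
#' gene rule).
#'
#' @param bins Table with `gene_id`, `exon_id`, `bin_id`, `lfc`, `padj`,
#'   `base_mean`.
#' @return One row per `(gene_id, exon_id)`.
#' @export
aggregate_exon_bins <- function(bins) {
  as.data.table(bins)[, .(
    lfc = mean(lfc),
    padj = if (all(is.na(padj))) NA_real_ else min(padj, na.rm = TRUE),
    base_mean = mean(base_mean),
    n_bins = .N
  ), by = .(gene_id, exon_id)]
}

#' Classify differentially used exon bins and differentially spliced genes
#'
#' A bin is differentially used when |LFC| >= `lfc_threshold`,
#' `padj < padj_threshold` and `base_mean > base_mean_threshold`; a gene
#' is differentially spliced when at least one of its bins qualifies.
#'
#' @param bins Exon-bin table (`gene_id`, `lfc`, `padj`, `base_mean`).
#' @param lfc_threshold,padj_threshold,base_mean_threshold The |LFC| >= 2,
#'   padj < 0.05, base mean > 10 defaults.
#' @return List with `bins` (input plus logical `diff_used`) and
#'   `spliced_genes` (character vector).
#' @export
classify_spliced_genes <- function(bins, lfc_threshold = 2,
                                   padj_threshold = 0.05,
                                   base_mean_threshold = 10) {
  bins <- copy(as.data.table(bins))
  bins[, diff_used := !is.na(padj) & padj < padj_threshold &
         abs(lfc) >= lfc_threshold & base_mean > base_mean_threshold]
  list(bins = bins[],
       spliced_genes = sort(unique(bins[diff_used == TRUE, gene_id])))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of drawing `k` or more spliced
#' genes in a subset of size `n` from a universe of `N` genes of which
#' `K` are spliced. Shared engine of [splicing_rate_test()] and
#' [gene_set_ora()].
#'
#' @param k,K,n,N Overlap, set size, selection size, universe size.
#' @return Upper-tail p-value.
#' @keywords internal
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k <= min(K, n), K <= N, n <= N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Splicing-rate comparison between gene sets
#'
#' Tests whether a subset of genes (e.g. circRNA hosts) is enriched for
#' differentially spliced genes relative to the universe, via the
#' one-tailed (upper) hypergeometric test. Also reports the rate ratio
#' `(k/n) / (K/N)`.
#'
#' @param universe Character vector of all genes.
#' @param spliced Differentially spliced genes (subset of universe).
#' @param subset Genes to test (subset of universe; must be non-empty).
#' @param set_name Label carried into the result.
#' @return List of class `ora_result`: `set_name`, `k`, `K`, `n`, `N`,
#'   `p`, `rate_ratio`.
#' @export
splicing_rate_test <- function(universe, spliced, subset,
                               set_name = "subset") {
  universe <- unique(universe)
  spliced <- intersect(unique(spliced), universe)
  subset <- intersect(unique(subset), universe)
  if (length(subset) == 0L) stop("empty subset for splicing-rate test")
  k <- length(intersect(subset, spliced))
  K <- length(spliced); n <- length(subset); N <- length(universe)
  out <- list(set_name = set_name, k = k, K = K, n = n, N = N,
              p = hypergeom_upper(k, K, n, N),
              rate_ratio = if (K > 0) (k / n) / (K / N) else NA_real_)
  class(out) <- "ora_result"
  out
}

#' Gene-set over-representation analysis
#'
#' One-tailed hypergeometric test of each supplied gene set against the
#' selected genes, with Benjamini-Hochberg adjustment across sets. Gene
#' sets disjoint from the universe give p = 1 with a warning.
#'
#' @param universe All genes.
#' @param selected Selected genes (e.g. hosts of increased circRNAs).
#' @param gene_sets Named list of character vectors.
#' @return `data.table` with one row per set: `set_name`, `k`, `K`, `n`,
#'   `N`, `p`, `padj_bh`.
#' @export
gene_set_ora <- function(universe, selected, gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) > 0L)
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    if (length(gs) == 0L) {
      warning("gene set '", nm, "' is disjoint from the universe; p = 1")
      return(data.table(set_name = nm, k = 0L, K = 0L,
                        n = length(selected), N = length(universe), p = 1))
    }
    res <- splicing_rate_test(universe, gs, selected, set_name = nm)
    data.table(set_name = nm, k = res$k, K = res$K, n = res$n, N = res$N,
               p = res$p)
  })
  out <- rbindlist(rows)
  out[, padj_bh := p.adjust(p, method = "BH")]
  out[]
}

#' Two-sample Z-test on group means
#'
#' `z = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)` with standard errors
#' `sd / sqrt(n)` using the unbiased (n-1) standard deviation; two-sided
#' normal p-value. Degenerate zero-variance groups with equal means give
#' z = 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List of class `z_test_result`: `mean_a`, `mean_b`, `se_a`,
#'   `se_b`, `z`, `p`.
#' @export
two_sample_z_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  ma <- mean(values_a); mb <- mean(values_b)
  sea <- sd(values_a) / sqrt(length(values_a))
  seb <- sd(values_b) / sqrt(length(values_b))
  denom <- sqrt(sea^2 + seb^2)
  z <- if (denom == 0) {
    if (ma == mb) 0 else sign(ma - mb) * Inf
  } else (ma - mb) / denom
  out <- list(mean_a = ma, mean_b = mb, se_a = sea, se_b = seb,
              z = z, p = 2 * pnorm(-abs(z)))
  class(out) <- "z_test_result"
  out
}

#' @export
print.z_test_result <- function(x, ...) {
  cat(sprintf("two-sample Z-test: mean_a=%.4g mean_b=%.4g z=%.4g p=%.4g\n",
              x$mean_a, x$mean_b, x$z, x$p))
  invisible(x)
}

#' Wilcoxon rank-sum test companion
#'
#' Offered alongside the Z-test wherever the per-Kb frequency figures
#' quote "Z-test/Wilcox test". Exact when both groups have fewer than 25
#' values and no ties, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values_a,values_b Numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  exact <- length(values_a) < 25L && length(values_b) < 25L &&
    !anyDuplicated(c(values_a, values_b))
  suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)$p.value
  )
}

#' Resolve duplicate host-gene LFC entries for ranked gene-list use
#'
#' Hosts with several circRNAs appear multiple times in a circRNA LFC
#' table. For ranked (GSEA-style) input, positively regulated tables
#' keep the maximum LFC per gene and negatively regulated tables the
#' minimum. Table preparation only; enrichment itself is out of scope.
#'
#' @param records Table with `gene_id` and `lfc`.
#' @param direction `"positive"` (keep max) or `"negative"` (keep min).
#' @return One row per gene.
#' @export
dedupe_host_lfc <- function(records, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  f <- if (direction == "positive") max else min
  as.data.table(records)[, .(lfc = f(lfc)), by = gene_id]
}
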