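## Exon-level genetic variant burden: classify exons of circRNA host
## transcripts into circ/nonCirc and BSJ/nonBSJ groups, tally variants
## per group normalised per Kb, and compare groups statistically.

#' Select the longest transcript containing both back-spliced exons
#'
#' Among transcripts whose exon boundaries contain both BSJ ends of a
#' circRNA (start coinciding with an exon start and end with an exon
#' end, same chromosome and strand), returns the one with the maximum
#' summed exon length; ties break lexicographically on `transcript_id`.
#' The containment constraint dominates length: a shorter transcript
#' that contains both back-spliced exons beats a longer one that does
#' not.
#'
#' @param exons Transcript models ([read_gtf()]).
#' @param circ One catalogue row (internal coordinates).
#' @return `transcript_id`, or `NULL` (with a message) when no
#'   transcript contains both BSJ exons — the circRNA is then excluded
#'   from exon analysis.
#' @export
select_longest_transcript <- function(exons, circ) {
  cand <- intersect(
    exons[chrom == circ$chrom & strand == circ$strand & start == circ$start,
          transcript_id],
    exons[chrom == circ$chrom & strand == circ$strand & end == circ$end,
          transcript_id]
  )
  if (!length(cand)) {
    message("no transcript contains both BSJ exons of ", circ$circ_id,
            "; excluded from exon analysis")
    return(NULL)
  }
  tl <- transcript_lengths(exons[transcript_id %in% cand])
  tl[order(-tx_len, transcript_id)]$transcript_id[1L]
}

#' Classify exons of one transcript relative to one circRNA
#'
#' Exons between the back-spliced boundaries inclusive are `circ`
#' (assuming no exon is spliced out of the circRNA); of those, the two
#' boundary exons are `BSJ` and strictly internal exons `nonBSJ`. All
#' remaining exons are `nonCirc` with `bsj_class` NA. A single-exon
#' circRNA has that exon `circ`/`BSJ`.
#'
#' @param exons Transcript models.
#' @param tx_id Transcript to classify.
#' @param circ Catalogue row whose BSJ boundaries lie on this
#'   transcript's exons.
#' @return `data.table` of exon-class records: interval columns plus
#'   `transcript_id`, `gene_id`, `exon_index`, `circ_class`,
#'   `bsj_class`, `length_kb`, `circ_id`.
#' @export
classify_exons <- function(exons, tx_id, circ) {
  tx <- exons[transcript_id == tx_id]
  setorder(tx, start)
  i <- tx[start == circ$start, exon_index]
  j <- tx[end == circ$end, exon_index]
  if (!length(i) || !length(j)) {
    stop("internal error: BSJ boundaries of ", circ$circ_id,
         " not on exon boundaries of ", tx_id)
  }
  i <- i[1L]; j <- j[1L]
  stopifnot(i <= j)
  out <- tx[, .(chrom, start, end, strand, transcript_id, gene_id,
                exon_index)]
  out[, circ_class := ifelse(exon_index >= i & exon_index <= j,
                             "circ", "nonCirc")]
  out[, bsj_class := NA_character_]
  out[circ_class == "circ",
      bsj_class := ifelse(exon_index == i | exon_index == j, "BSJ", "nonBSJ")]
  out[, length_kb := (end - start) / 1000]
  out[, circ_id := circ$circ_id]
  out[]
}

#' Classify exons for every annotated circRNA of a catalogue
#'
#' Applies [select_longest_transcript()] and [classify_exons()] per
#' circRNA, then de-duplicates exon records shared between circRNAs of
#' one gene by `(transcript_id, exon)` keeping the most circular label
#' (BSJ > nonBSJ > nonCirc), so no exon is double-counted within a
#' grouping.
#'
#' @param circs Annotated catalogue (only `annotation == "annotated"`
#'   rows are used).
#' @param exons Transcript models.
#' @param dedupe De-duplicate shared exons (default TRUE).
#' @return Exon-class `data.table`.
#' @export
classify_catalog_exons <- function(circs, exons, dedupe = TRUE) {
  ann <- as.data.table(circs)[annotation == "annotated"]
  recs <- vector("list", nrow(ann))
  for (r in seq_len(nrow(ann))) {
    cc <- ann[r]
    tx <- select_longest_transcript(exons, cc)
    if (is.null(tx)) next
    recs[[r]] <- classify_exons(exons, tx, cc)
  }
  out <- rbindlist(recs)
  if (nrow(out) == 0L) return(out)
  if (dedupe) {
    out[, class_rank := fifelse(circ_class == "nonCirc", 3L,
                                fifelse(bsj_class == "BSJ", 1L, 2L))]
    setorder(out, class_rank)
    out <- unique(out, by = c("transcript_id", "start", "end"))
    out[, class_rank := NULL]
    setorder(out, chrom, start, end)
  }
  out[]
}

#' Read a variant table
#'
#' BED-derived TSV with header `chrom`, `pos` (0-based), `ref`, `alt`,
#' `impact` (`low`/`medium`/`high`/`none`), `flags` (comma-separated
#' subset of `missense`, `splice_region`, `deleterious`; empty allowed)
#' and `cohort`.
#'
#' @param path TSV path.
#' @return Variant `data.table`.
#' @export
read_variants <- function(path) {
  dt <- read_tsv_table(path)
  required <- c("chrom", "pos", "ref", "alt", "impact", "flags", "cohort")
  if (!all(required %in% names(dt))) {
    stop("variant table ", path, " must have columns ",
         paste(required, collapse = ", "))
  }
  if (any(dt$pos < 0)) stop("coordinate error: negative variant position")
  dt[is.na(flags), flags := ""]
  dt[]
}

## internal: does a variant carry a flag
.has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE),
         function(f) flag %in% trimws(f), logical(1))
}

#' Tally variants per classified exon
#'
#' A variant belongs to an exon when its (start) position falls inside
#' the half-open exon interval; indels are assigned by start position.
#' Densities are counts per Kb of exon length.
#'
#' @param exon_classes Exon-class table ([classify_catalog_exons()]).
#' @param variants Variant table ([read_variants()]).
#' @return `exon_classes` plus `n_var` and `density` columns.
#' @export
tally_variants <- function(exon_classes, variants) {
  out <- copy(as.data.table(exon_classes))
  if (nrow(variants) == 0L) {
    out[, n_var := 0L]
  } else {
    v <- as.data.table(variants)[, .(chrom, pos)]
    hit_rows <- out[v, on = .(chrom, start <= pos, end > pos),
                    nomatch = NULL, which = TRUE]
    out[, n_var := tabulate(hit_rows, nbins = nrow(out))]
  }
  out[, density := n_var / length_kb]
  out[]
}

#' Filter variants by cohort, flag or impact subset
#'
#' @param variants Variant table.
#' @param cohort Optional cohort label to retain.
#' @param flag Optional flag name (`"splice_region"`, `"missense"`,
#'   `"deleterious"`) to retain.
#' @param impact Optional character vector of impact levels to retain.
#' @return Filtered variant table.
#' @export
filter_variants <- function(variants, cohort = NULL, flag = NULL,
                            impact = NULL) {
  v <- as.data.table(variants)
  keep <- rep(TRUE, nrow(v))
  if (!is.null(cohort)) keep <- keep & v[["cohort"]] == cohort
  if (!is.null(flag)) keep <- keep & .has_flag(v[["flags"]], flag)
  if (!is.null(impact)) keep <- keep & v[["impact"]] %in% impact
  v[which(keep)]
}

#' Compare variant burden between exon groups
#'
#' Forms the two per-exon density vectors of a grouping — `circ` vs
#' `nonCirc` over all exons, or `BSJ` vs `nonBSJ` within circ exons —
#' after optional variant filtering, and compares them with the
#' two-sample Z-test and the Wilcoxon rank-sum test. Per-exon density
#' vectors (not pooled counts) feed the tests; the pooled per-Kb
#' frequencies and their ratio are reported alongside.
#'
#' @param exon_classes Exon-class table.
#' @param variants Variant table.
#' @param grouping `"circ"` or `"bsj"`.
#' @param cohort,flag,impact Passed to [filter_variants()].
#' @return List of class `burden_result`: group labels and sizes,
#'   variant counts, Kb totals, pooled `freq_per_kb_a`/`_b` and
#'   `rate_ratio`, per-exon `densities_a`/`_b`, `z`, `p_z`,
#'   `p_wilcoxon`.
#' @export
burden_compare <- function(exon_classes, variants,
                           grouping = c("circ", "bsj"),
                           cohort = NULL, flag = NULL, impact = NULL) {
  grouping <- match.arg(grouping)
  v <- filter_variants(variants, cohort = cohort, flag = flag,
                       impact = impact)
  tallied <- tally_variants(exon_classes, v)
  if (grouping == "circ") {
    a <- tallied[circ_class == "circ"]; b <- tallied[circ_class == "nonCirc"]
    labels <- c("circ", "nonCirc")
  } else {
    a <- tallied[circ_class == "circ" & bsj_class == "BSJ"]
    b <- tallied[circ_class == "circ" & bsj_class == "nonBSJ"]
    labels <- c("BSJ", "nonBSJ")
  }
  for (g in list(list(a, labels[1]), list(b, labels[2]))) {
    if (nrow(g[[1]]) == 0L) stop("empty exon group after filtering: ", g[[2]])
  }
  zt <- two_sample_z_test(a$density, b$density)
  kb_a <- sum(a$length_kb); kb_b <- sum(b$length_kb)
  fa <- sum(a$n_var) / kb_a; fb <- sum(b$n_var) / kb_b
  out <- list(
    group_a = labels[1], group_b = labels[2],
    n_exons_a = nrow(a), n_exons_b = nrow(b),
    n_variants_a = sum(a$n_var), n_variants_b = sum(b$n_var),
    total_kb_a = kb_a, total_kb_b = kb_b,
    freq_per_kb_a = fa, freq_per_kb_b = fb,
    rate_ratio = fa / fb,
    densities_a = a$density, densities_b = b$density,
    z = zt$z, p_z = zt$p,
    p_wilcoxon = wilcoxon_rank_sum(a$density, b$density)
  )
  class(out) <- "burden_result"
  out
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("variant burden %s vs %s\n", x$group_a, x$group_b))
  cat(sprintf("  %s: %d variants / %.2f Kb = %.3f per Kb (%d exons)\n",
              x$group_a, x$n_variants_a, x$total_kb_a, x$freq_per_kb_a,
              x$n_exons_a))
  cat(sprintf("  %s: %d variants / %.2f Kb = %.3f per Kb (%d exons)\n",
              x$group_b, x$n_variants_b, x$total_kb_b, x$freq_per_kb_b,
              x$n_exons_b))
  cat(sprintf("  rate ratio %.3f; z = %.3f, p_z = %.3g, p_wilcoxon = %.3g\n",
              x$rate_ratio, x$z, x$p_z, x$p_wilcoxon))
  invisible(x)
}

#' Assign variants to exon groups
#'
#' Tags each variant falling inside a classified exon with that exon's
#' `circ_class`/`bsj_class` (after exon de-duplication, each position
#' maps to at most one class per transcript).
#'
#' @param exon_classes Exon-class table.
#' @param variants Variant table.
#' @return Variants inside classified exons, with class columns added.
#' @export
assign_variant_groups <- function(exon_classes, variants) {
  v <- as.data.table(variants)
  e <- as.data.table(exon_classes)
  hit <- e[v, on = .(chrom, start <= pos, end > pos), nomatch = NULL,
           .(chrom, pos = i.pos, ref = i.ref, alt = i.alt,
             impact = i.impact, flags = i.flags, cohort = i.cohort,
             circ_class = x.circ_class, bsj_class = x.bsj_class)]
  unique(hit)
}

#' Impact-category proportions per exon group
#'
#' Proportions over `low`/`medium`/`high` per group; variants with
#' impact `none` are excluded (and counted).
#'
#' @param tagged_variants Output of [assign_variant_groups()].
#' @param by Grouping column, `"circ_class"` or `"bsj_class"`.
#' @return List with `proportions` (data.table group x impact) and
#'   `n_excluded_none`.
#' @export
impact_proportions <- function(tagged_variants, by = "circ_class") {
  v <- as.data.table(tagged_variants)
  v <- v[!is.na(v[[by]])]
  n_none <- sum(v$impact == "none")
  v <- v[impact != "none"]
  if (nrow(v) == 0L) stop("empty group: no variants with impact annotation")
  groups <- split(v$impact, v[[by]])
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (!length(x)) stop("empty group: ", g)
    data.table(group = g,
               low = mean(x == "low"),
               medium = mean(x == "medium"),
               high = mean(x == "high"))
  })
  list(proportions = rbindlist(rows), n_excluded_none = n_none)
}

#' Missense and deleterious-missense fractions per group
#'
#' @param tagged_variants Output of [assign_variant_groups()].
#' @param by Grouping column.
#' @return `data.table` per group: `fraction_missense` and
#'   `fraction_missense_deleterious` (conditional on missense; `NA` when
#'   the group has no missense variants).
#' @export
missense_deleterious_fractions <- function(tagged_variants,
                                           by = "circ_class") {
  v <- as.data.table(tagged_variants)
  v <- v[!is.na(v[[by]])]
  v[, grp := v[[by]]]
  v[, .(
    n = .N,
    fraction_missense = mean(.has_flag(flags, "missense")),
    fraction_missense_deleterious = {
      mis <- .has_flag(flags, "missense")
      if (!any(mis)) NA_real_
      else mean(.has_flag(flags[mis], "deleterious"))
    }
  ), by = grp]
}
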