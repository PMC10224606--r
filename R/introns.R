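## Flanking-intron extraction, Alu element processing and the
## intron-length / inverted-Alu-proximity classification of circRNAs.

#' Extract the flanking introns of an annotated circRNA
#'
#' The upstream intron is the intron 5' of the back-spliced acceptor
#' exon in transcription orientation (genomically left of the first
#' back-spliced exon on the plus strand, right of the last on the
#' minus strand); the downstream intron is 3' of the donor exon.
#' circRNAs whose back-spliced exons are the transcript's first or last
#' exon on the relevant side lack a flanking intron and are excluded
#' with a message.
#'
#' @param circ Annotated catalogue row.
#' @param exons Transcript models.
#' @return One-row `data.table` (`circ_id`, `chrom`, `strand`,
#'   `up_start`, `up_end`, `down_start`, `down_end`, `up_len`,
#'   `down_len`, `total_length`), or `NULL` when a flanking intron is
#'   missing.
#' @export
extract_flanking_introns <- function(circ, exons) {
  if (is.na(circ$transcript_id)) {
    stop("circRNA ", circ$circ_id, " is not annotated")
  }
  tx <- exons[transcript_id == circ$transcript_id]
  setorder(tx, start)
  i <- circ$bs_exon_from; j <- circ$bs_exon_to
  n <- nrow(tx)
  if (i <= 1L || j >= n) {
    message("circRNA ", circ$circ_id,
            " lacks a flanking intron (first/last exon); excluded")
    return(NULL)
  }
  left <- c(tx$end[i - 1L], tx$start[i])    # intron genomically left of exon i
  right <- c(tx$end[j], tx$start[j + 1L])   # intron genomically right of exon j
  if (circ$strand == "-") {
    up <- right; down <- left   # transcription order flips on minus strand
  } else {
    up <- left; down <- right
  }
  data.table(
    circ_id = circ$circ_id, chrom = circ$chrom, strand = circ$strand,
    up_start = up[1L], up_end = up[2L],
    down_start = down[1L], down_end = down[2L],
    up_len = up[2L] - up[1L], down_len = down[2L] - down[1L],
    total_length = (up[2L] - up[1L]) + (down[2L] - down[1L])
  )
}

#' Flanking-intron pairs for a whole catalogue
#'
#' @param circs Annotated catalogue (`annotation == "annotated"` rows
#'   with flanking introns on both sides are returned).
#' @param exons Transcript models.
#' @return Row-bound pair table; one row per eligible circRNA.
#' @export
catalog_flanking_introns <- function(circs, exons) {
  ann <- as.data.table(circs)[annotation == "annotated"]
  rbindlist(lapply(seq_len(nrow(ann)), function(r) {
    extract_flanking_introns(ann[r], exons)
  }))
}

#' Read a RepeatMasker-derived repeat annotation and keep Alu elements
#'
#' Accepts BED6 (name column = repeat family); Alu elements are
#' selected by the family-name prefix `"Alu"`.
#'
#' @param path BED6/TSV path.
#' @param family_prefix Repeat family prefix to retain (default
#'   `"Alu"`).
#' @return Interval table with `family` and `strand`.
#' @export
read_alu_elements <- function(path, family_prefix = "Alu") {
  bed <- read_bed(path)
  if (!"name" %in% names(bed)) stop("repeat annotation needs a name column")
  out <- bed[startsWith(bed$name, family_prefix)]
  setnames(out, "name", "family")
  out[]
}

#' Retain Alu elements overlapping flanking introns
#'
#' Keeps elements whose overlap with any flanking intron is at least
#' `min_fraction` of the element's own length (default the 50% rule,
#' inclusive).
#'
#' @param alus Alu interval table.
#' @param pairs Flanking-intron pair table
#'   ([catalog_flanking_introns()]).
#' @param min_fraction Minimum overlap fraction in (0, 1].
#' @return Filtered Alu table.
#' @export
filter_alu_overlap <- function(alus, pairs, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (nrow(alus) == 0L) return(alus)
  introns <- rbind(
    data.table(chrom = pairs$chrom, start = pairs$up_start,
               end = pairs$up_end),
    data.table(chrom = pairs$chrom, start = pairs$down_start,
               end = pairs$down_end)
  )
  hits <- intervals_intersect(alus, introns)
  if (nrow(hits) == 0L) return(alus[0L])
  hits[, grp := query]
  frac <- hits[, .(best = max(overlap)), by = grp]
  keep <- frac[best / (alus$end[grp] - alus$start[grp]) >= min_fraction, grp]
  alus[sort(unique(keep))]
}

#' Closest retained Alu in each flanking intron and inversion status
#'
#' For each intron the BSJ anchor is the splice-site coordinate on that
#' intron's BSJ side (the boundary shared with the back-spliced exon);
#' distance is measured to the Alu's nearest edge (0 when the element
#' overlaps the anchor). The circRNA has inverted Alu elements (IAE)
#' when the two closest Alus lie on opposite annotation strands; with
#' no retained Alu in either intron the inversion status is undefined
#' (no IAE).
#'
#' @param pair One flanking-intron pair row.
#' @param alus Overlap-filtered Alu table ([filter_alu_overlap()]).
#' @return One-row `data.table`: `circ_id`, `dist_up`, `dist_down`,
#'   `strand_up`, `strand_down`, `inverted`, `total_alu_distance`
#'   (NA when either side lacks an Alu).
#' @export
closest_alu_pair <- function(pair, alus) {
  side <- function(s, e, anchor) {
    within <- alus[chrom == pair$chrom & start < e & end > s]
    cf <- closest_feature(anchor, within, chrom = pair$chrom)
    if (is.null(cf)) list(dist = NA_integer_, strand = NA_character_)
    else list(dist = cf$distance, strand = within$strand[cf$index])
  }
  # BSJ-side boundary: upstream intron meets the acceptor exon, downstream
  # intron meets the donor exon
  up_anchor <- if (pair$strand == "-") pair$up_start else pair$up_end
  down_anchor <- if (pair$strand == "-") pair$down_end else pair$down_start
  up <- side(pair$up_start, pair$up_end, up_anchor)
  down <- side(pair$down_start, pair$down_end, down_anchor)
  inverted <- if (is.na(up$dist) || is.na(down$dist)) NA else
    up$strand != down$strand
  data.table(
    circ_id = pair$circ_id,
    dist_up = up$dist, dist_down = down$dist,
    strand_up = up$strand, strand_down = down$strand,
    inverted = inverted,
    total_alu_distance = if (isTRUE(!is.na(up$dist) && !is.na(down$dist)))
      up$dist + down$dist else NA_integer_
  )
}

#' Classify circRNAs by flanking-intron length and proximal IAE
#'
#' The length median is computed over all circRNAs' total flanking
#' intron length; the distance median over IAE-containing circRNAs'
#' total Alu distance. A circRNA is `Short`/`Long` by strict comparison
#' of its total intron length against the length median (values equal
#' to the median fall on the `Long` side), and gains the `pIAE-` prefix
#' when it has inverted Alus with total distance strictly below the
#' distance median.
#'
#' @param pairs Flanking-intron pair table.
#' @param iae Row-bound [closest_alu_pair()] results.
#' @return `data.table` with pair columns plus `dist_up`, `dist_down`,
#'   `inverted`, `total_alu_distance`, `intron_class` in
#'   `{Short, Long, pIAE-short, pIAE-long}`, and attributes
#'   `median_length` / `median_alu_distance`.
#' @export
classify_circ_introns <- function(pairs, iae) {
  stopifnot(nrow(pairs) >= 1L)
  x <- merge(as.data.table(pairs),
             as.data.table(iae)[, .(circ_id, dist_up, dist_down, inverted,
                                    total_alu_distance)],
             by = "circ_id", all.x = TRUE)
  med_len <- median(x$total_length)
  med_dist <- median(x[inverted == TRUE, total_alu_distance])
  short <- x$total_length < med_len
  piae <- !is.na(x$inverted) & x$inverted &
    !is.na(med_dist) & x$total_alu_distance < med_dist
  x[, intron_class := fifelse(piae & short, "pIAE-short",
                       fifelse(piae & !short, "pIAE-long",
                        fifelse(short, "Short", "Long")))]
  setattr(x, "median_length", med_len)
  setattr(x, "median_alu_distance", med_dist)
  x[]
}

#' Compare flanking-intron length and IAE distance between circRNA sets
#'
#' Two-sample Z-tests of mean total flanking-intron length (all
#' circRNAs) and of mean total Alu distance (IAE circRNAs only) for a
#' subset against the full set, plus the proportions of the four
#' intron classes in each set.
#'
#' @param subset_ids circRNA ids of the subset (e.g. increased
#'   circRNAs); must be non-empty and present in `classified`.
#' @param classified Output of [classify_circ_introns()] on all
#'   circRNAs.
#' @return List: `length_test` (`z_test_result`), `distance_test`
#'   (`z_test_result` or NULL when either side has <2 IAE circRNAs),
#'   `medians`, `class_proportions` (`data.table` set x class,
#'   proportions summing to 1 per set).
#' @export
intron_length_compare <- function(subset_ids, classified) {
  stopifnot(length(subset_ids) > 0L)
  sub <- classified[circ_id %in% subset_ids]
  if (nrow(sub) == 0L) stop("empty subset in intron_length_compare")
  length_test <- two_sample_z_test(sub$total_length,
                                   classified$total_length)
  sub_iae <- sub[inverted == TRUE]
  all_iae <- classified[inverted == TRUE]
  distance_test <- if (nrow(sub_iae) >= 2L && nrow(all_iae) >= 2L) {
    two_sample_z_test(sub_iae$total_alu_distance,
                      all_iae$total_alu_distance)
  } else NULL
  lv <- c("Short", "Long", "pIAE-short", "pIAE-long")
  prop_row <- function(x, label) {
    tb <- as.numeric(prop.table(table(factor(x, levels = lv))))
    dt <- as.data.table(as.list(tb))
    setnames(dt, lv)
    cbind(data.table(set = label), dt)
  }
  props <- rbind(prop_row(classified$intron_class, "all"),
                 prop_row(sub$intron_class, "subset"))
  list(
    length_test = length_test,
    distance_test = distance_test,
    medians = c(length_all = median(classified$total_length),
                length_subset = median(sub$total_length)),
    class_proportions = props
  )
}
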