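## circRNA:miRNA:mRNA axis construction from miRNA site tables, with a
## documented seed-match stand-in for external site prediction.

#' Count miRNA seed-match sites in a target sequence
#'
#' Simplified, explicitly labelled stand-in for external energy-model
#' site prediction: counts occurrences of the reverse complement of the
#' miRNA seed (positions `seed_span[1]..seed_span[2]` of the mature
#' miRNA, default 2-8) in the target, allowing up to
#' `allowed_mismatches` mismatches. Output rows carry
#' `method = "seed_match"`.
#'
#' @param target_seq RNA sequence of the target (circRNA or 3'UTR).
#' @param mirna_seq Mature miRNA RNA sequence (5'->3').
#' @param target_id,mirna Labels for the output.
#' @param target_type `"circ"` or `"utr3"`.
#' @param seed_span Integer pair, 1-based inclusive positions of the
#'   seed within the miRNA.
#' @param allowed_mismatches Maximum mismatches per site (default 0).
#' @return `data.table` with one row per site: `mirna`, `target_id`,
#'   `target_type`, `position` (0-based), `n_sites` (total per target),
#'   `method`; zero rows when no site.
#' @export
seed_match_sites <- function(target_seq, mirna_seq, target_id = "target",
                             mirna = "miRNA", target_type = "circ",
                             seed_span = c(2L, 8L),
                             allowed_mismatches = 0L) {
  mir <- .rna_chars(mirna_seq)
  if (seed_span[1L] < 1L || seed_span[2L] > length(mir)) {
    stop("seed span outside miRNA length")
  }
  seed <- paste(mir[seed_span[1L]:seed_span[2L]], collapse = "")
  site <- .rna_chars(reverse_complement_rna(seed))
  tg <- .rna_chars(target_seq)
  W <- length(site)
  n_off <- length(tg) - W + 1L
  if (n_off < 1L) pos <- integer() else {
    mm <- vapply(seq_len(n_off), function(o) {
      sum(tg[o:(o + W - 1L)] != site)
    }, integer(1))
    pos <- which(mm <= allowed_mismatches) - 1L
  }
  if (!length(pos)) {
    return(data.table(mirna = character(), target_id = character(),
                      target_type = character(), position = integer(),
                      n_sites = integer(), method = character()))
  }
  data.table(mirna = mirna, target_id = target_id,
             target_type = target_type, position = pos,
             n_sites = length(pos), method = "seed_match")
}

#' Build circRNA:miRNA:mRNA axes under the same-direction rule
#'
#' Emits a triple `(circ, miRNA, mRNA)` when the circRNA and the mRNA
#' both carry at least one site for the same miRNA and share a
#' differential-expression direction (both up or both down, per
#' [classify_de()]); non-significant features are never matched. Also
#' reports the maximum per-circRNA site count for any single miRNA.
#'
#' @param circ_sites,utr_sites Site tables (`mirna`, `target_id`,
#'   `target_type`, `position`, `n_sites`) for circRNAs and 3'UTRs.
#'   When several 3'UTRs exist per gene the caller supplies sites from
#'   the longest (the convention used throughout).
#' @param circ_de,mrna_de DE tables ([read_de_table()] shape) keyed by
#'   `feature_id` matching the site tables' `target_id`.
#' @param lfc_threshold,padj_threshold Passed to [classify_de()].
#' @return List: `axes` (`data.table` of unique `circ_id`, `mirna`,
#'   `mrna_gene`, `direction`, ordered) and `max_sites_per_circ`.
#' @export
build_axes <- function(circ_sites, utr_sites, circ_de, mrna_de,
                       lfc_threshold = 2, padj_threshold = 0.05) {
  circ_de <- as.data.table(circ_de)
  mrna_de <- as.data.table(mrna_de)
  circ_de[, de_label := classify_de(circ_de, lfc_threshold, padj_threshold)]
  mrna_de[, de_label := classify_de(mrna_de, lfc_threshold, padj_threshold)]
  cs <- unique(as.data.table(circ_sites)[, .(mirna, target_id, n_sites)])
  us <- unique(as.data.table(utr_sites)[, .(mirna, target_id)])
  cs <- merge(cs, circ_de[, .(target_id = feature_id, de_label)],
              by = "target_id")
  us <- merge(us, mrna_de[, .(target_id = feature_id, de_label)],
              by = "target_id")
  cs <- cs[de_label %in% c("up", "down")]
  us <- us[de_label %in% c("up", "down")]
  axes <- merge(
    cs[, .(circ_id = target_id, mirna, direction = as.character(de_label))],
    us[, .(mrna_gene = target_id, mirna,
           direction = as.character(de_label))],
    by = c("mirna", "direction"), allow.cartesian = TRUE
  )
  axes <- unique(axes[, .(circ_id, mirna, mrna_gene, direction)])
  setorder(axes, circ_id, mirna, mrna_gene)
  max_sites <- if (nrow(cs)) max(cs$n_sites) else 0L
  list(axes = axes[], max_sites_per_circ = as.integer(max_sites))
}
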