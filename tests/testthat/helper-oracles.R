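# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (all-pairs scans, exhaustive
# enumeration) and never call the implementation paths they check.

library(data.table)

# all-pairs O(n^2) interval intersection
bf_intersect <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1L) {
      rows[[length(rows) + 1L]] <-
        data.table(query = i, subject = j, overlap = as.integer(ov))
    }
  }
  out <- rbindlist(rows)
  if (nrow(out)) setorder(out, query, subject)
  out
}

# linear-scan closest feature
bf_closest <- function(anchor, features, chrom = NULL) {
  best <- NULL
  for (i in seq_len(nrow(features))) {
    if (!is.null(chrom) && features$chrom[i] != chrom) next
    d <- max(features$start[i] - anchor, anchor - features$end[i], 0L)
    if (is.null(best) || d < best$distance ||
        (d == best$distance && features$start[i] < features$start[best$index])) {
      best <- list(index = i, distance = as.integer(d))
    }
  }
  best
}

# exhaustive hypergeometric tail: enumerate all C(N, n) draws
bf_hyper_upper <- function(k, K, n, N) {
  draws <- combn(N, n)
  spliced <- seq_len(K)  # first K items are "successes"
  hits <- apply(draws, 2, function(d) sum(d %in% spliced))
  mean(hits >= k)
}

# exact per-word enumeration of PPM scan p-values (motif length <= 8)
bf_scan_ppm <- function(seq, ppm, bg, p_threshold) {
  L <- ncol(ppm)
  lom <- log2(ppm / as.numeric(bg))
  bases <- c("A", "C", "G", "U")
  words <- as.matrix(expand.grid(rep(list(bases), L),
                                 stringsAsFactors = FALSE))
  idx <- function(w) cbind(match(w, bases), seq_len(L))
  wscore <- apply(words, 1, function(w) sum(lom[idx(w)]))
  wprob <- apply(words, 1, function(w) prod(bg[w]))
  ch <- strsplit(seq, "")[[1]]
  offs <- integer(); ps <- numeric()
  for (o in seq_len(length(ch) - L + 1L)) {
    w <- ch[o:(o + L - 1L)]
    if (any(!w %in% bases)) next
    s <- sum(lom[idx(w)])
    if (!is.finite(s)) next
    p <- sum(wprob[wscore >= s - 1e-9])
    if (p <= p_threshold) { offs <- c(offs, o - 1L); ps <- c(ps, p) }
  }
  list(offsets = offs, p = ps)
}

# per-variant scan tally
bf_tally <- function(exons, variants) {
  n <- integer(nrow(exons))
  for (v in seq_len(nrow(variants))) {
    for (e in seq_len(nrow(exons))) {
      if (variants$chrom[v] == exons$chrom[e] &&
          variants$pos[v] >= exons$start[e] &&
          variants$pos[v] < exons$end[e]) {
        n[e] <- n[e] + 1L
      }
    }
  }
  n
}

# exhaustive triple enumeration for axis building
bf_axes <- function(circ_sites, utr_sites, circ_labels, mrna_labels) {
  rows <- list()
  for (ci in unique(circ_sites$target_id)) {
    dc <- circ_labels[[ci]]
    if (!dc %in% c("up", "down")) next
    mirs_c <- unique(circ_sites$mirna[circ_sites$target_id == ci])
    for (m in mirs_c) {
      for (gi in unique(utr_sites$target_id[utr_sites$mirna == m])) {
        if (identical(mrna_labels[[gi]], dc)) {
          rows[[length(rows) + 1L]] <-
            data.table(circ_id = ci, mirna = m, mrna_gene = gi,
                       direction = dc)
        }
      }
    }
  }
  out <- unique(rbindlist(rows))
  if (nrow(out)) setorder(out, circ_id, mirna, mrna_gene)
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 5000L) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(200L, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
}
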