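## FIMO-style motif scanning over RNA sequences, Fisher enrichment
## against a background sequence set, and positional frequency profiles
## over circRNA flanking introns.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A",
                     R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                     B = "V", V = "B", D = "H", H = "D", N = "N")

## normalise a sequence to RNA uppercase character vector
.rna_chars <- function(seq) {
  s <- chartr("acgutT", "ACGUUU", seq)
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' Reverse-complement an RNA sequence string
#'
#' @param seq Character scalar over the IUPAC RNA alphabet (T accepted
#'   and treated as U).
#' @return Reverse complement, RNA alphabet.
#' @export
reverse_complement_rna <- function(seq) {
  ch <- .rna_chars(seq)
  paste(rev(unname(.rna_complement[ch])), collapse = "")
}

#' Construct a consensus motif
#'
#' @param name Motif name.
#' @param consensus IUPAC RNA consensus string (T accepted as U).
#' @param rbp RNA-binding protein label (e.g. `"SFPQ"`).
#' @param source_id Database identifier, if any.
#' @return Object of class `motif` (`kind = "consensus"`).
#' @export
motif_consensus <- function(name, consensus, rbp = NA_character_,
                            source_id = NA_character_) {
  consensus <- chartr("tT", "UU", toupper(consensus))
  ch <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% names(IUPAC_RNA))) {
    stop("consensus for ", name, " uses non-IUPAC letters: ",
         paste(setdiff(ch, names(IUPAC_RNA)), collapse = ""))
  }
  structure(list(name = name, rbp = rbp, kind = "consensus",
                 consensus = consensus, ppm = NULL, source_id = source_id),
            class = "motif")
}

#' Construct a position-probability-matrix motif
#'
#' @param name Motif name.
#' @param ppm Numeric matrix, 4 rows named `A`, `C`, `G`, `U` (T
#'   accepted), one column per motif position; columns must sum to 1
#'   within 1e-9.
#' @param rbp,source_id As in [motif_consensus()].
#' @return Object of class `motif` (`kind = "ppm"`).
#' @export
motif_ppm <- function(name, ppm, rbp = NA_character_,
                      source_id = NA_character_) {
  stopifnot(is.matrix(ppm), nrow(ppm) == 4L)
  rn <- toupper(rownames(ppm))
  rn[rn == "T"] <- "U"
  if (!setequal(rn, c("A", "C", "G", "U"))) {
    stop("PPM rows must be named A, C, G, U")
  }
  rownames(ppm) <- rn
  ppm <- ppm[c("A", "C", "G", "U"), , drop = FALSE]
  if (any(abs(colSums(ppm) - 1) > 1e-9)) {
    stop("PPM columns of ", name, " must each sum to 1")
  }
  structure(list(name = name, rbp = rbp, kind = "ppm", consensus = NULL,
                 ppm = ppm, source_id = source_id),
            class = "motif")
}

#' Motif length in bases
#' @param motif A `motif` object.
#' @return Integer length.
#' @export
motif_width <- function(motif) {
  if (motif$kind == "consensus") nchar(motif$consensus) else ncol(motif$ppm)
}

#' Reverse-complement a motif
#'
#' Consensus strings are reverse-complemented in IUPAC space; PPMs have
#' their columns reversed and the A/U and C/G rows swapped. Used by the
#' strand-consistency property: scanning a reverse-complemented sequence
#' with the reverse-complemented motif mirrors hit offsets.
#'
#' @param motif A `motif` object.
#' @return A `motif` object.
#' @export
reverse_complement_motif <- function(motif) {
  if (motif$kind == "consensus") {
    motif_consensus(motif$name, reverse_complement_rna(motif$consensus),
                    motif$rbp, motif$source_id)
  } else {
    ppm <- motif$ppm[c("U", "G", "C", "A"), rev(seq_len(ncol(motif$ppm))),
                     drop = FALSE]
    rownames(ppm) <- c("A", "C", "G", "U")
    motif_ppm(motif$name, ppm, motif$rbp, motif$source_id)
  }
}

## discretisation granularity for log-odds scores, in bits; fine enough
## that DP tail probabilities agree with exhaustive enumeration to ~1e-5
.SCORE_GRANULARITY <- 1e-4

## internal: DP over the discretised score distribution.
## Returns list(int_mat (integerised per-cell scores, -Inf allowed),
## shift (per-column minimum of finite entries), tail (P(score >= s) for
## shifted integer sums s = 0..max)).
.score_distribution <- function(lom, bg) {
  int_mat <- round(lom / .SCORE_GRANULARITY)
  L <- ncol(int_mat)
  shift <- vapply(seq_len(L), function(k) {
    fin <- int_mat[, k][is.finite(int_mat[, k])]
    if (!length(fin)) stop("motif position ", k, " has no usable base")
    min(fin)
  }, numeric(1))
  shifted <- sweep(int_mat, 2L, shift)
  maxsum <- sum(vapply(seq_len(L), function(k) {
    max(shifted[, k][is.finite(shifted[, k])])
  }, numeric(1)))
  pmf <- numeric(maxsum + 1L)
  pmf[1L] <- 1
  for (k in seq_len(L)) {
    new <- numeric(maxsum + 1L)
    for (b in c("A", "C", "G", "U")) {
      sk <- shifted[b, k]
      if (!is.finite(sk)) next  # zero-probability base: mass drops out
      if (sk == 0) {
        new <- new + pmf * bg[[b]]
      } else {
        idx <- seq_len(maxsum + 1L - sk)
        new[idx + sk] <- new[idx + sk] + pmf[idx] * bg[[b]]
      }
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  list(int_mat = int_mat, shift = shift, tail = tail, maxsum = maxsum)
}

#' Scan one sequence with one motif
#'
#' For PPM motifs, every offset is scored with the log2 odds of the PPM
#' against the i.i.d. background model and assigned the exact p-value
#' `P(score >= observed)` under that background, computed by dynamic
#' programming over the discretised score distribution (the FIMO
#' approach); offsets with `p <= p_threshold` are hits. For IUPAC
#' consensus motifs, hits are exact IUPAC-compatible matches and the
#' reported p is the background probability of the consensus (the
#' threshold is not applied — a match is a hit by construction).
#' Windows containing `N` in the sequence are skipped.
#'
#' @param seq RNA sequence string (A/C/G/U/N; T read as U).
#' @param motif A `motif` object.
#' @param p_threshold Per-position p-value threshold for PPM hits
#'   (default 0.001, the FIMO setting used here).
#' @param background Named base frequencies over A, C, G, U; default
#'   uniform.
#' @param sequence_id Label carried into the hit table.
#' @return `data.table` of hits: `motif_name`, `sequence_id`, `offset`
#'   (0-based), `width`, `score` (log-odds bits; `NA` for consensus),
#'   `p`.
#' @export
scan_sequence <- function(seq, motif, p_threshold = 0.001,
                          background = NULL, sequence_id = NA_character_) {
  if (is.null(background)) {
    background <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  }
  background <- background[c("A", "C", "G", "U")]
  stopifnot(abs(sum(background) - 1) < 1e-6)
  ch <- .rna_chars(seq)
  W <- motif_width(motif)
  empty <- data.table(motif_name = character(), sequence_id = character(),
                      offset = integer(), width = integer(),
                      score = numeric(), p = numeric())
  n_off <- length(ch) - W + 1L
  if (n_off < 1L) return(empty)

  if (motif$kind == "consensus") {
    allowed <- IUPAC_RNA[strsplit(motif$consensus, "")[[1L]]]
    p_cons <- prod(vapply(allowed, function(a) sum(background[a]),
                          numeric(1)))
    ok <- vapply(seq_len(n_off), function(o) {
      win <- ch[o:(o + W - 1L)]
      !any(win == "N") && all(mapply(function(c1, a) c1 %in% a, win, allowed))
    }, logical(1))
    hits <- which(ok)
    if (!length(hits)) return(empty)
    return(data.table(motif_name = motif$name, sequence_id = sequence_id,
                      offset = hits - 1L, width = W, score = NA_real_,
                      p = p_cons))
  }

  lom <- log2(motif$ppm / as.numeric(background))
  dist <- .score_distribution(lom, as.list(background))
  base_idx <- match(ch, c("A", "C", "G", "U"))  # NA for N
  rows <- lapply(seq_len(n_off), function(o) {
    bi <- base_idx[o:(o + W - 1L)]
    if (anyNA(bi)) return(NULL)  # N in window: skipped
    ints <- dist$int_mat[cbind(bi, seq_len(W))]
    if (any(!is.finite(ints))) return(NULL)  # zero-probability base
    s_int <- sum(ints) - sum(dist$shift)  # always in [0, maxsum]
    p <- dist$tail[s_int + 1L]
    if (p > p_threshold) return(NULL)
    score <- sum(lom[cbind(bi, seq_len(W))])
    data.table(motif_name = motif$name, sequence_id = sequence_id,
               offset = o - 1L, width = W, score = score, p = p)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) empty else out[]
}

#' Scan a set of sequences with a set of motifs
#'
#' @param seqs Named character vector of RNA sequences.
#' @param motifs List of `motif` objects.
#' @param ... Passed to [scan_sequence()].
#' @return Row-bound hit `data.table`.
#' @export
scan_sequences <- function(seqs, motifs, ...) {
  stopifnot(!is.null(names(seqs)))
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  out <- rbindlist(lapply(motifs, function(m) {
    rbindlist(lapply(names(seqs), function(id) {
      scan_sequence(seqs[[id]], m, sequence_id = id, ...)
    }))
  }))
  if (nrow(out) == 0L) {
    out <- data.table(motif_name = character(), sequence_id = character(),
                      offset = integer(), width = integer(),
                      score = numeric(), p = numeric())
  }
  out[]
}

#' Base composition of a sequence set
#'
#' @param seqs Character vector of RNA sequences.
#' @return Named frequency vector over A, C, G, U (N ignored).
#' @export
base_composition <- function(seqs) {
  ch <- unlist(lapply(seqs, .rna_chars), use.names = FALSE)
  ch <- ch[ch %in% c("A", "C", "G", "U")]
  tab <- table(factor(ch, levels = c("A", "C", "G", "U")))
  as.numeric(tab / sum(tab)) |> setNames(c("A", "C", "G", "U"))
}

#' Motif enrichment of a target sequence set against a background
#'
#' Per motif, sequences with at least one hit are counted in the target
#' and background sets and compared with a one-tailed Fisher exact test
#' (enrichment direction), Benjamini-Hochberg adjusted across motifs.
#' This hit-presence test is this package's documented stand-in for
#' AME-style enrichment; results carry `method = "fisher_hit_presence"`.
#' Background base frequencies default to the composition of the
#' background sequence set.
#'
#' @param target_seqs,background_seqs Named character vectors of RNA
#'   sequences.
#' @param motifs List of `motif` objects.
#' @param p_threshold Hit threshold passed to [scan_sequence()].
#' @param background_freqs Optional base frequencies; default
#'   [base_composition()] of `background_seqs`.
#' @return `data.table`: `motif_name`, `rbp`, `n_target_with_hit`,
#'   `n_target`, `n_background_with_hit`, `n_background`, `p_fisher`,
#'   `padj_bh`, `method`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, motifs,
                             p_threshold = 0.001,
                             background_freqs = NULL) {
  stopifnot(length(background_seqs) > 0L)
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (is.null(background_freqs)) {
    background_freqs <- base_composition(background_seqs)
  }
  count_hits <- function(seqs, m) {
    sum(vapply(seqs, function(s) {
      nrow(scan_sequence(s, m, p_threshold = p_threshold,
                         background = background_freqs)) > 0L
    }, logical(1)))
  }
  rows <- lapply(motifs, function(m) {
    a <- count_hits(target_seqs, m)
    c <- count_hits(background_seqs, m)
    tab <- matrix(c(a, length(target_seqs) - a,
                    c, length(background_seqs) - c), nrow = 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.table(motif_name = m$name, rbp = m$rbp,
               n_target_with_hit = a, n_target = length(target_seqs),
               n_background_with_hit = c,
               n_background = length(background_seqs),
               p_fisher = p)
  })
  out <- rbindlist(rows)
  out[, padj_bh := p.adjust(p_fisher, method = "BH")]
  out[, method := "fisher_hit_presence"]
  out[]
}

#' Positional motif-frequency profile over flanking introns
#'
#' Bins motif hits on circRNA flanking introns by distance to a chosen
#' anchor and normalises bin counts by the number of circRNAs in the
#' subset. Hit offsets are 0-based within each intron sequence in
#' transcription orientation. Anchors: `five_prime_end` measures from
#' the intron's transcription 5' boundary (distance = offset);
#' `bsj_distal_splice_site` measures from the boundary farther from the
#' BSJ — for the upstream intron that is its 5' end, for the downstream
#' intron its 3' end (distance = intron length - offset - hit width).
#'
#' @param hits Hit table with `circ_id`, `side` (`"upstream"` /
#'   `"downstream"`), `offset`, `width`.
#' @param pairs Flanking-intron pairs ([extract_flanking_introns()]
#'   table) supplying intron lengths per circRNA and side.
#' @param anchor `"five_prime_end"` or `"bsj_distal_splice_site"`.
#' @param bin_width Bin width in bases (default 100).
#' @param max_distance Optional truncation; hits farther than this from
#'   the anchor are dropped. Default covers the longest intron.
#' @param n_circ Normaliser; defaults to the number of circRNAs in
#'   `pairs`.
#' @return List of class `positional_profile`: `anchor`, `bin_width`,
#'   `breaks` (bin left edges), `counts`, `frequency`, `normaliser`.
#' @export
positional_profile <- function(hits, pairs,
                               anchor = c("five_prime_end",
                                          "bsj_distal_splice_site"),
                               bin_width = 100L, max_distance = NULL,
                               n_circ = NULL) {
  anchor <- match.arg(anchor)
  pairs <- as.data.table(pairs)
  hits <- as.data.table(hits)
  if (is.null(n_circ)) n_circ <- length(unique(pairs$circ_id))
  stopifnot(n_circ > 0L)
  lens <- rbind(
    pairs[, .(circ_id, side = "upstream", intron_len = up_len)],
    pairs[, .(circ_id, side = "downstream", intron_len = down_len)]
  )
  h <- merge(hits, lens, by = c("circ_id", "side"))
  if (nrow(h) != nrow(hits)) {
    stop("hit(s) do not map to a flanking intron of the supplied pairs")
  }
  if (any(h$offset < 0L | h$offset + h$width > h$intron_len)) {
    stop("hit outside its intron")
  }
  d <- if (anchor == "five_prime_end") {
    h$offset
  } else {
    ifelse(h$side == "upstream", h$offset,
           h$intron_len - h$offset - h$width)
  }
  if (is.null(max_distance)) {
    max_distance <- if (nrow(lens)) max(lens$intron_len) else bin_width
  }
  d <- d[d <= max_distance]
  n_bins <- max(1L, ceiling((max_distance + 1) / bin_width))
  bins <- pmin(d %/% bin_width, n_bins - 1L)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  out <- list(anchor = anchor, bin_width = as.integer(bin_width),
              breaks = (seq_len(n_bins) - 1L) * as.integer(bin_width),
              counts = counts, frequency = counts / n_circ,
              normaliser = as.integer(n_circ))
  class(out) <- "positional_profile"
  out
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("positional profile (%s, bin %db, %d circRNAs)\n",
              x$anchor, x$bin_width, x$normaliser))
  show <- head(seq_along(x$counts), 10L)
  cat(paste(sprintf("  [%d,%d): %d (%.3f)", x$breaks[show],
                    x$breaks[show] + x$bin_width, x$counts[show],
                    x$frequency[show]), collapse = "\n"), "\n")
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (alphabet length 4, columns A, C, G, T/U).
#'
#' @param path MEME-format file.
#' @return List of `motif` objects (`kind = "ppm"`).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  lapply(starts, function(s) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1L]]
    name <- hdr[2L]
    rbp <- if (length(hdr) >= 3L) hdr[3L] else NA_character_
    mrow <- grep("letter-probability matrix", lines[seq(s, length(lines))])[1L]
    if (is.na(mrow)) stop("MOTIF ", name, " lacks a letter-probability matrix")
    mrow <- s + mrow - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mrow]))
    vals <- lines[(mrow + 1L):(mrow + w)]
    ppm <- t(vapply(vals, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }, numeric(4L)))
    ppm <- t(ppm)  # 4 x w
    rownames(ppm) <- c("A", "C", "G", "U")
    motif_ppm(name, ppm, rbp = rbp, source_id = name)
  })
}

#' Read consensus motifs from a two-column TSV
#'
#' @param path TSV with header columns `name`, `consensus` and optional
#'   `rbp`.
#' @return List of `motif` objects (`kind = "consensus"`).
#' @export
read_consensus_motifs <- function(path) {
  dt <- read_tsv_table(path)
  stopifnot(all(c("name", "consensus") %in% names(dt)))
  lapply(seq_len(nrow(dt)), function(r) {
    motif_consensus(dt$name[r], dt$consensus[r],
                    rbp = if ("rbp" %in% names(dt)) dt$rbp[r]
                          else NA_character_)
  })
}

#' Extract the exonic sequence of an annotated circRNA
#'
#' Concatenates the back-spliced exon sequences of the assigned
#' transcript in transcription order: genomic order for plus-strand
#' circRNAs, reverse complement of the genomic concatenation for minus
#' strand. DNA is converted to RNA (T to U). By default the sequence is
#' linear (the linearised extracted sequence); `junction_wrap` appends
#' the first `wrap - 1` bases so BSJ-spanning motif sites of width up to
#' `wrap` become visible to a linear scan.
#'
#' @param circ Annotated catalogue row (needs `transcript_id`,
#'   `bs_exon_from`, `bs_exon_to`).
#' @param exons Transcript models.
#' @param genome Named `DNAStringSet` ([read_genome_fasta()]).
#' @param junction_wrap Integer motif width for BSJ wrap-around, or
#'   `NULL` (default, no wrap).
#' @return RNA sequence string.
#' @export
extract_circ_sequence <- function(circ, exons, genome,
                                  junction_wrap = NULL) {
  if (is.na(circ$transcript_id)) {
    stop("circRNA ", circ$circ_id, " is not annotated to a transcript")
  }
  if (!circ$chrom %in% names(genome)) {
    stop("chromosome ", circ$chrom, " missing from genome")
  }
  tx <- exons[transcript_id == circ$transcript_id &
                exon_index >= circ$bs_exon_from &
                exon_index <= circ$bs_exon_to]
  setorder(tx, start)
  parts <- vapply(seq_len(nrow(tx)), function(k) {
    as.character(Biostrings::subseq(genome[[tx$chrom[k]]],
                                    start = tx$start[k] + 1L,
                                    end = tx$end[k]))
  }, character(1))
  dna <- paste(parts, collapse = "")
  if (circ$strand == "-") {
    dna <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  }
  rna <- chartr("T", "U", dna)
  if (!is.null(junction_wrap) && junction_wrap > 1L) {
    rna <- paste0(rna, substr(rna, 1L, junction_wrap - 1L))
  }
  rna
}

#' Extract a genomic interval's sequence in transcription orientation
#'
#' @param genome Named `DNAStringSet`.
#' @param chrom,start,end Internal 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` (minus strand reverse-complemented).
#' @return RNA sequence string.
#' @export
extract_interval_sequence <- function(genome, chrom, start, end,
                                      strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " missing")
  dna <- as.character(Biostrings::subseq(genome[[chrom]], start = start + 1L,
                                         end = end))
  if (strand == "-") {
    dna <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  }
  chartr("T", "U", dna)
}
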