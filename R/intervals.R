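## Core genomic-interval arithmetic.
##
## Internal convention everywhere in this package: 0-based, half-open
## [start, end), matching BED. External 1-based inclusive coordinates
## (GTF, circRNA ids) are converted exactly once at the I/O layer.

#' Construct a validated genomic interval table
#'
#' Intervals are plain `data.table`s with columns `chrom`, `start`, `end`
#' and `strand`, using 0-based half-open coordinates. All interval-set
#' operations in the package accept and return this shape.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based start offsets.
#' @param end Integer vector, exclusive end offsets; must satisfy
#'   `start < end`.
#' @param strand Character vector over `"+"`, `"-"`, `"."`; recycled.
#' @return A `data.table` with one row per interval.
#' @examples
#' gintervals("chr1", 0, 100)
#' @export
gintervals <- function(chrom, start, end, strand = ".") {
  iv <- data.table(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(iv)
  iv
}

#' Validate an interval table
#'
#' Checks the interval invariants: non-empty chromosome names,
#' `0 <= start < end`, and strand in `+`, `-`, `.`.
#'
#' @param iv Interval `data.table` (see [gintervals()]).
#' @return `iv`, invisibly. Throws a coordinate error on violation.
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv))
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(iv))
  if (length(missing)) {
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom))) {
    stop("coordinate error: empty chromosome name")
  }
  if (any(iv$start < 0L)) stop("coordinate error: negative start")
  if (any(iv$start >= iv$end)) {
    stop("coordinate error: start must be < end (0-based half-open)")
  }
  if ("strand" %in% names(iv) && !all(iv$strand %in% c("+", "-", "."))) {
    stop("coordinate error: strand must be one of '+', '-', '.'")
  }
  invisible(iv)
}

#' Interval length in bases
#'
#' @param iv Interval table.
#' @return Integer vector `end - start` (half-open convention).
#' @examples
#' interval_length(gintervals("chr1", 0, 100)) # 100
#' @export
interval_length <- function(iv) {
  validate_intervals(iv)
  as.integer(iv$end - iv$start)
}

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' External dialects (GTF, circRNA identifiers, CIRI-style tables) are
#' 1-based inclusive; conversion subtracts one from the start only.
#'
#' @param iv Interval-shaped table with 1-based inclusive `start`/`end`.
#' @return The table with internal coordinates.
#' @seealso [to_one_based()]
#' @export
from_one_based <- function(iv) {
  out <- as.data.table(iv)
  out[, start := as.integer(start) - 1L]
  out[, end := as.integer(end)]
  validate_intervals(out)
  out[]
}

#' Convert internal coordinates back to 1-based inclusive
#'
#' Inverse of [from_one_based()]; the two compose to the identity.
#'
#' @param iv Interval table in internal coordinates.
#' @return The table with 1-based inclusive coordinates.
#' @export
to_one_based <- function(iv) {
  out <- as.data.table(iv)
  out[, start := as.integer(start) + 1L]
  out[]
}

## internal: GRanges view of an interval table (1-based closed)
.as_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = if ("strand" %in% names(iv)) {
      ifelse(iv$strand %in% c("+", "-"), iv$strand, "*")
    } else "*"
  )
}

#' All overlapping pairs between two interval sets
#'
#' Returns every pair of rows (one from each set) sharing a chromosome and
#' overlapping by at least one base under the half-open convention
#' (abutting intervals do not overlap). Strand is ignored.
#'
#' @param a,b Interval tables.
#' @return `data.table` with columns `query` (row index in `a`),
#'   `subject` (row index in `b`) and `overlap` (bases).
#' @examples
#' intervals_intersect(gintervals("chr1", 0, 10), gintervals("chr1", 5, 15))
#' @export
intervals_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.table(query = integer(), subject = integer(),
                      overlap = integer()))
  }
  validate_intervals(a); validate_intervals(b)
  hits <- GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  out <- data.table(query = qi, subject = si, overlap = as.integer(ov))
  setorder(out, query, subject)
  out[]
}

#' Fraction of a feature covered by a container interval
#'
#' Used for the "Alu overlaps intron by at least 50% of the repeat
#' element length" retention rule: the fraction is always relative to the
#' feature (repeat) length.
#'
#' @param feature Interval table (the repeat elements).
#' @param container Interval table of equal row count, or a single row
#'   recycled against every feature.
#' @return Numeric vector in `[0, 1]`; different chromosomes give 0.
#' @export
overlap_fraction <- function(feature, container) {
  validate_intervals(feature); validate_intervals(container)
  n <- nrow(feature)
  if (nrow(container) == 1L && n > 1L) {
    container <- container[rep(1L, n)]
  }
  stopifnot(nrow(container) == n)
  ov <- pmin(feature$end, container$end) - pmax(feature$start, container$start)
  ov <- pmax(ov, 0L)
  ov[feature$chrom != container$chrom] <- 0L
  as.numeric(ov) / interval_length(feature)
}

#' Closest feature to an anchor position
#'
#' Distance follows the `bedtools closest` convention: 0 if the anchor
#' falls inside (or exactly abuts, half-open) a feature, otherwise the
#' number of bases in the gap. Ties are broken by smaller start
#' coordinate, then by input order.
#'
#' @param anchor Single integer position (0-based) on `chrom`.
#' @param features Interval table to search (the search space restriction
#'   is the caller's responsibility).
#' @param chrom Chromosome of the anchor; features on other chromosomes
#'   are ignored.
#' @return A list with `index` (row in `features`) and `distance`
#'   (bases), or `NULL` when no feature is eligible.
#' @export
closest_feature <- function(anchor, features, chrom = NULL) {
  if (nrow(features) == 0L) return(NULL)
  validate_intervals(features)
  idx <- seq_len(nrow(features))
  if (!is.null(chrom)) idx <- idx[features$chrom == chrom]
  if (length(idx) == 0L) return(NULL)
  s <- features$start[idx]; e <- features$end[idx]
  d <- pmax(s - anchor, anchor - e, 0L)
  ord <- order(d, s, seq_along(idx))
  best <- ord[1L]
  list(index = idx[best], distance = as.integer(d[best]))
}
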