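## Readers and writers: GTF (Ensembl dialect), BED3/BED6, FASTA, and the
## pipeline's tab-separated tables. All conversion between external
## 1-based inclusive and internal 0-based half-open happens here.

#' Read transcript models from a GTF file
#'
#' Parses exon features from an Ensembl-dialect GTF and returns one row
#' per exon in internal coordinates, ordered by ascending genomic start
#' within each transcript (`exon_index`). Transcript invariants (single
#' chromosome and strand per transcript, non-overlapping exons) are
#' enforced.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_name`, `transcript_id`, `exon_index`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  md <- S4Vectors::mcols(gr)
  exons <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(md$gene_id),
    gene_name = if (!is.null(md$gene_name)) as.character(md$gene_name)
                else as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id)
  )
  exons[is.na(gene_name), gene_name := gene_id]
  setorder(exons, transcript_id, start)
  exons[, exon_index := seq_len(.N), by = transcript_id]
  validate_transcript_models(exons)
  exons[]
}

#' Validate transcript model invariants
#'
#' Each transcript must have at least one exon, all exons on one
#' chromosome and strand, and pairwise non-overlapping exons.
#'
#' @param exons Exon table as returned by [read_gtf()].
#' @return `exons`, invisibly; stops on violation.
#' @export
validate_transcript_models <- function(exons) {
  validate_intervals(exons)
  bad <- exons[, .(nchrom = uniqueN(chrom), nstrand = uniqueN(strand)),
               by = transcript_id][nchrom > 1L | nstrand > 1L]
  if (nrow(bad)) {
    stop("transcript(s) span multiple chromosomes/strands: ",
         paste(head(bad$transcript_id, 3L), collapse = ", "))
  }
  ov <- exons[order(transcript_id, start),
              .(overlapping = any(start[-1L] < end[-.N])), by = transcript_id]
  if (any(ov$overlapping)) {
    stop("overlapping exons within transcript(s): ",
         paste(head(ov$transcript_id[ov$overlapping], 3L), collapse = ", "))
  }
  invisible(exons)
}

#' Summed exon length per transcript
#'
#' @param exons Exon table from [read_gtf()].
#' @return `data.table` with `transcript_id`, `gene_id`, `tx_len` (bases).
#' @export
transcript_lengths <- function(exons) {
  exons[, .(gene_id = gene_id[1L], tx_len = sum(end - start)),
        by = transcript_id]
}

#' Write transcript models to GTF
#'
#' Emits exon features only, converting internal coordinates back to
#' 1-based inclusive. Round-trips with [read_gtf()].
#'
#' @param exons Exon table (internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
    exons$gene_id, exons$transcript_id, exons$gene_name
  )
  lines <- paste(exons$chrom, "circscape", "exon", exons$start + 1L,
                 exons$end, ".", exons$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED is already 0-based half-open and passes through unchanged.
#'
#' @param path Path to a BED file (no header).
#' @return Interval `data.table`, with `name`, `score`, `strand` when the
#'   file has six columns.
#' @export
read_bed <- function(path) {
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = FALSE),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e))
  )
  if (ncol(dt) < 3L) stop("malformed BED file ", path, ": fewer than 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), nm[seq_len(min(ncol(dt), 6L))])
  dt[, chrom := as.character(chrom)]
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  if ("strand" %in% names(dt)) dt[, strand := as.character(strand)]
  validate_intervals(dt)
  dt[]
}

#' Write intervals as BED
#'
#' @param records Interval table; `name`, `score`, `strand` columns are
#'   emitted when present (BED6), otherwise BED3.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  validate_intervals(records)
  # BED columns are positional: emit the longest present prefix
  ord <- c("chrom", "start", "end", "name", "score", "strand")
  n <- match(FALSE, ord %in% names(records), nomatch = 7L) - 1L
  keep <- ord[seq_len(n)]
  out <- as.data.table(records)[, ..keep]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named DNA string set
#'
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Read/write tab-separated tables with a header row
#'
#' Thin wrappers standardising the pipeline's TSV dialect (tab-separated,
#' header, UTF-8, no quoting).
#'
#' @param path File path.
#' @param x Table to write.
#' @return `read_tsv_table()` returns a `data.table`; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
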