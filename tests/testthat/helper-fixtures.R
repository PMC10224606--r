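# Small constructed fixtures shared across test files. Everything is
# built in code; nothing is read from disk.

# A five-exon plus-strand gene and a three-exon minus-strand gene.
# Exon layout of GENE1_t1 (chrT, +): [100,200) [300,400) [500,600)
# [700,800) [900,1000); GENE2_t1 (chrT, -): [2000,2100) [2300,2400)
# [2600,2700).
toy_models <- function() {
  rbind(
    data.table(chrom = "chrT",
               start = c(100L, 300L, 500L, 700L, 900L),
               end = c(200L, 400L, 600L, 800L, 1000L),
               strand = "+", gene_id = "G1", gene_name = "GENE1",
               transcript_id = "GENE1_t1", exon_index = 1:5),
    data.table(chrom = "chrT",
               start = c(2000L, 2300L, 2600L),
               end = c(2100L, 2400L, 2700L),
               strand = "-", gene_id = "G2", gene_name = "GENE2",
               transcript_id = "GENE2_t1", exon_index = 1:3)
  )
}

# an annotated catalogue row for a circRNA over exons i..j of a toy gene
toy_circ <- function(models, tx = "GENE1_t1", i = 2L, j = 4L) {
  ex <- models[transcript_id == tx][order(start)]
  data.table(
    circ_id = sprintf("%s_%s:%d-%d", ex$gene_name[1], ex$chrom[1],
                      ex$start[i] + 1L, ex$end[j]),
    chrom = ex$chrom[1], start = ex$start[i], end = ex$end[j],
    strand = ex$strand[1], host_gene = ex$gene_name[1],
    annotation = "annotated", transcript_id = tx,
    bs_exon_from = i, bs_exon_to = j, known_id = NA_character_
  )
}

# BSJ call rows with two samples
toy_call <- function(chrom, start, end, strand, detector, c1 = 5L,
                     c2 = 5L) {
  data.table(chrom = chrom, start = start, end = end, strand = strand,
             detector = detector, s1 = c1, s2 = c2)
}

# tiny deterministic genome covering the toy models
toy_genome <- function(seed = 42L, len = 3000L) {
  set.seed(seed)
  gs <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(gs) <- "chrT"
  gs
}
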