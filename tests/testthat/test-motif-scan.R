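# motif scanning (consensus + PPM with DP p-values), enrichment, and
# positional profiles

test_that("consensus scanning finds exact IUPAC matches", {
  m <- motif_consensus("m", "UGUA")
  hits <- scan_sequence("AAUGUAAA", m)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$p, 0.25^4)
  # degenerate letters and N skipping
  md <- motif_consensus("md", "URUA")  # R = A/G
  expect_equal(nrow(scan_sequence("UAUAUGUA", md)), 2L)
  expect_equal(nrow(scan_sequence("AANGUAAA", m)), 0L)
  # T is read as U
  expect_equal(scan_sequence("AATGTAAA", m)$offset, 2L)
})

test_that("an indicator PPM behaves identically to its consensus", {
  cons <- "UGUA"
  ind <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (k in 1:4) ind[substr(cons, k, k), k] <- 1
  mp <- motif_ppm("ind", ind)
  mc <- motif_consensus("cons", cons)
  seq <- "GGUGUAAUGUAC"
  hp <- scan_sequence(seq, mp, p_threshold = 1)
  hc <- scan_sequence(seq, mc)
  expect_equal(hp$offset, hc$offset)
  expect_equal(hp$p, hc$p)
})

test_that("PPM hits equal brute-force enumeration with exact p-values", {
  set.seed(41)
  for (L in c(4L, 6L, 8L)) {
    ppm <- matrix(rexp(4 * L), nrow = 4,
                  dimnames = list(c("A", "C", "G", "U"), NULL))
    ppm <- sweep(ppm, 2, colSums(ppm), "/")
    m <- motif_ppm(paste0("m", L), ppm)
    bg <- c(A = 0.3, C = 0.2, G = 0.3, U = 0.2)
    seq <- paste(sample(c("A", "C", "G", "U"), 300, TRUE, prob = bg),
                 collapse = "")
    hits <- scan_sequence(seq, m, p_threshold = 0.01, background = bg)
    oracle <- bf_scan_ppm(seq, ppm, bg, 0.01)
    expect_equal(sort(as.integer(hits$offset)), sort(oracle$offsets))
    expect_equal(sort(hits$p), sort(oracle$p), tolerance = 1e-6)
  }
})

test_that("scanning is strand-consistent under reverse complement", {
  set.seed(42)
  m <- motif_consensus("m", "UGAUCG")
  seq <- paste(sample(c("A", "C", "G", "U"), 200, TRUE), collapse = "")
  fwd <- scan_sequence(seq, m)
  rev <- scan_sequence(reverse_complement_rna(seq),
                       reverse_complement_motif(m))
  W <- motif_width(m)
  expect_equal(sort(as.integer(rev$offset)),
               sort(200L - as.integer(fwd$offset) - W))
})

test_that("motif enrichment matches the closed-form Fisher example", {
  with_hit <- replicate(5, paste0("AAA", "UGUA", "CCC"))
  without <- replicate(5, "AAACCCAAACCC")
  names(with_hit) <- paste0("t", 1:5); names(without) <- paste0("b", 1:5)
  m <- motif_consensus("m", "UGUA")
  res <- motif_enrichment(with_hit, without, list(m),
                          background_freqs = c(A = .25, C = .25,
                                               G = .25, U = .25))
  expect_equal(res$p_fisher, 1 / choose(10, 5))
  # equal hit proportions give p = 1 one-tailed
  res2 <- motif_enrichment(with_hit, with_hit, list(m),
                           background_freqs = c(A = .25, C = .25,
                                                G = .25, U = .25))
  expect_equal(res2$p_fisher, 1)
  # zero hits anywhere gives p = 1
  m0 <- motif_consensus("m0", "GGGGGGGG")
  res3 <- motif_enrichment(with_hit, without, list(m0),
                           background_freqs = c(A = .25, C = .25,
                                                G = .25, U = .25))
  expect_equal(res3$p_fisher, 1)
})

test_that("Fisher enrichment equals hypergeometric enumeration on small tables", {
  set.seed(43)
  for (rep in 1:5) {
    n_t <- sample(3:6, 1); n_b <- sample(3:6, 1)
    a <- sample(0:n_t, 1); c <- sample(0:n_b, 1)
    p_impl <- fisher.test(matrix(c(a, n_t - a, c, n_b - c), 2),
                          alternative = "greater")$p.value
    # oracle: P(X >= a) with X hypergeom over the fixed margins
    K <- a + c; N <- n_t + n_b
    p_oracle <- sum(vapply(a:min(K, n_t), function(x) {
      choose(K, x) * choose(N - K, n_t - x) / choose(N, n_t)
    }, numeric(1)))
    expect_equal(p_impl, p_oracle, tolerance = 1e-12)
  }
})

test_that("circRNA sequence extraction respects strand and exon order", {
  models <- toy_models()
  genome <- toy_genome()
  gchars <- strsplit(as.character(genome[["chrT"]]), "")[[1]]
  # single-exon plus-strand circ equals the genomic slice as RNA
  c1 <- toy_circ(models, i = 3L, j = 3L)
  s1 <- extract_circ_sequence(c1, models, genome)
  expect_equal(s1, chartr("T", "U", paste(gchars[501:600], collapse = "")))
  # minus-strand two-exon circ: reverse complement of genomic concatenation
  c2 <- toy_circ(models, tx = "GENE2_t1", i = 2L, j = 3L)
  s2 <- extract_circ_sequence(c2, models, genome)
  genomic <- paste(c(gchars[2301:2400], gchars[2601:2700]), collapse = "")
  expected <- chartr("T", "U", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genomic))))
  expect_equal(s2, expected)
  # length conservation across random synthetic circRNAs
  sim <- simulate_dataset(synth_config(seed = 6, n_genes = 10))
  ann <- copy(sim$truth)[, `:=`(annotation = "annotated")]
  for (r in seq_len(min(20L, nrow(ann)))) {
    cc <- ann[r]
    tx <- sim$exons[transcript_id == cc$transcript_id &
                      exon_index >= cc$bs_exon_from &
                      exon_index <= cc$bs_exon_to]
    expect_equal(nchar(extract_circ_sequence(cc, sim$exons, sim$genome)),
                 sum(tx$end - tx$start))
  }
  # junction wrap appends the first W-1 bases
  s1w <- extract_circ_sequence(c1, models, genome, junction_wrap = 5L)
  expect_equal(nchar(s1w), 104L)
  expect_equal(substr(s1w, 101, 104), substr(s1, 1, 4))
})

test_that("positional profiles bin by anchor distance and normalise", {
  pairs <- data.table(circ_id = sprintf("c%02d", 1:10),
                      up_len = 1000L, down_len = 1000L)
  # single hit at the 5' boundary of one upstream intron, 10 circRNAs
  hits <- data.table(circ_id = "c01", side = "upstream", offset = 0L,
                     width = 6L)
  prof <- positional_profile(hits, pairs, anchor = "five_prime_end",
                             bin_width = 100L)
  expect_equal(prof$frequency[1], 0.1)
  expect_equal(sum(prof$counts), 1L)
  # distal anchor: upstream introns anchor at their 5' end, downstream at 3'
  hits2 <- data.table(circ_id = c("c01", "c02"),
                      side = c("upstream", "downstream"),
                      offset = c(0L, 0L), width = 6L)
  prof2 <- positional_profile(hits2, pairs,
                              anchor = "bsj_distal_splice_site",
                              bin_width = 100L)
  expect_equal(prof2$counts[1], 1L)   # upstream 5' hit stays at distance 0
  # downstream 5' hit sits 1000 - 6 = 994 bases from its distal anchor
  expect_equal(prof2$counts[994 %/% 100 + 1L], 1L)
  # total hits are conserved when max_distance covers the longest intron
  set.seed(44)
  hits3 <- data.table(circ_id = sample(pairs$circ_id, 200, TRUE),
                      side = sample(c("upstream", "downstream"), 200, TRUE),
                      offset = sample(0:900, 200, TRUE), width = 6L)
  prof3 <- positional_profile(hits3, pairs, anchor = "five_prime_end")
  expect_equal(sum(prof3$counts), 200L)
  # hit outside its intron errors
  bad <- data.table(circ_id = "c01", side = "upstream", offset = 999L,
                    width = 6L)
  expect_error(positional_profile(bad, pairs, "five_prime_end"),
               "outside its intron")
})

test_that("uniform hits give a flat profile, geometric hits a 5' skew", {
  set.seed(45)
  pairs <- data.table(circ_id = sprintf("c%02d", 1:20),
                      up_len = 2000L, down_len = 2000L)
  unif <- data.table(circ_id = sample(pairs$circ_id, 600, TRUE),
                     side = sample(c("upstream", "downstream"), 600, TRUE),
                     offset = sample(0:1990, 600, TRUE), width = 6L)
  # restrict to fully-covered bins: a width-6 hit can reach distance 1994
  # at most, so the [2000, 2200) bin is structurally empty
  pu <- positional_profile(unif, pairs, "five_prime_end", bin_width = 200L,
                           max_distance = 1999L)
  gof <- suppressWarnings(chisq.test(pu$counts))
  expect_gt(gof$p.value, 0.01)
  geo <- data.table(circ_id = sample(pairs$circ_id, 600, TRUE),
                    side = sample(c("upstream", "downstream"), 600, TRUE),
                    offset = pmin(rgeom(600, 1 / 300), 1990L), width = 6L)
  pg <- positional_profile(geo, pairs, "five_prime_end", bin_width = 400L)
  expect_true(all(diff(pg$counts) <= 0))  # monotone decreasing
  # the same geometric-from-5' hits skew to the far bins of downstream
  # introns under the BSJ-distal anchor
  down <- geo[side == "downstream"]
  pd <- positional_profile(down, pairs, "bsj_distal_splice_site",
                           bin_width = 400L)
  nb <- length(pd$counts)
  expect_gt(sum(pd$counts[(nb - 1):nb]), sum(pd$counts[1:2]))
})

test_that("MEME and consensus-TSV motif readers round-trip shapes", {
  meme <- tempfile(fileext = ".txt")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGU", "",
    "MOTIF M1 SFPQ",
    "letter-probability matrix: alength= 4 w= 3 nsites= 10 E= 0",
    " 0.7 0.1 0.1 0.1", " 0.1 0.7 0.1 0.1", " 0.1 0.1 0.1 0.7"
  ), meme)
  ms <- read_meme_motifs(meme)
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$rbp, "SFPQ")
  expect_equal(dim(ms[[1]]$ppm), c(4L, 3L))
  expect_equal(ms[[1]]$ppm["A", 1], 0.7)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\trbp", "M2\tUGUAAU\tSFPQ"), tsv)
  cs <- read_consensus_motifs(tsv)
  expect_equal(cs[[1]]$consensus, "UGUAAU")
  expect_error(motif_ppm("bad", matrix(0.3, 4, 2,
    dimnames = list(c("A", "C", "G", "U"), NULL))), "sum to 1")
  expect_error(motif_consensus("bad", "UGXA"), "non-IUPAC")
})
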