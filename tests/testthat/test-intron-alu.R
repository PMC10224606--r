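# flanking-intron extraction, Alu retention/closest rules, and the
# length/IAE median-split classification

test_that("flanking introns follow transcription orientation", {
  models <- toy_models()
  # plus strand, circ over exons 2-4 of 5: upstream = intron1, downstream =
  # intron4
  p <- extract_flanking_introns(toy_circ(models, i = 2L, j = 4L), models)
  expect_equal(c(p$up_start, p$up_end), c(200L, 300L))
  expect_equal(c(p$down_start, p$down_end), c(800L, 900L))
  expect_equal(p$total_length, 200L)
  # minus strand: genomic order swaps, transcription order preserved
  m <- extract_flanking_introns(toy_circ(models, tx = "GENE2_t1", i = 2L,
                                         j = 2L), models)
  expect_equal(c(m$up_start, m$up_end), c(2400L, 2600L))  # genomic right
  expect_equal(c(m$down_start, m$down_end), c(2100L, 2300L))
  # first-exon circRNA is excluded with a message
  expect_message(
    res <- extract_flanking_introns(toy_circ(models, i = 1L, j = 3L),
                                    models),
    "lacks a flanking intron")
  expect_null(res)
})

test_that("Alu retention applies the inclusive 50% overlap rule", {
  models <- toy_models()
  pairs <- extract_flanking_introns(toy_circ(models, i = 2L, j = 4L),
                                    models)
  alus <- data.table(
    chrom = "chrT",
    start = c(210L, 150L, 250L, 1500L),
    end = c(260L, 450L, 350L, 1600L),
    name = "AluY", score = 0L,
    strand = c("+", "-", "+", "+")
  )
  kept <- filter_alu_overlap(alus, pairs)
  # fully inside: kept; 100/300 overlap: dropped; exactly 50% (250-300 of
  # 250-350): kept; elsewhere: dropped
  expect_equal(kept$start, c(210L, 250L))
  expect_equal(nrow(filter_alu_overlap(alus[0], pairs)), 0L)
})

test_that("closest Alu per intron and the opposite-strand rule", {
  models <- toy_models()
  pair <- extract_flanking_introns(toy_circ(models, i = 2L, j = 4L),
                                   models)
  # upstream intron [200,300) anchored at 300 (acceptor side); downstream
  # [800,900) anchored at 800
  alus <- data.table(chrom = "chrT",
                     start = c(210L, 240L, 850L),
                     end = c(230L, 270L, 880L),
                     family = "AluY",
                     strand = c("+", "+", "-"))
  res <- closest_alu_pair(pair, alus)
  expect_equal(res$dist_up, 30L)    # 300 - 270
  expect_equal(res$dist_down, 50L)  # 850 - 800
  expect_true(res$inverted)
  expect_equal(res$total_alu_distance, 80L)
  # same strands: not inverted
  same <- copy(alus)[, strand := "+"]
  expect_false(closest_alu_pair(pair, same)$inverted)
  # no Alu downstream: no IAE
  res0 <- closest_alu_pair(pair, alus[1:2])
  expect_true(is.na(res0$inverted))
  expect_true(is.na(res0$total_alu_distance))
  # Alu overlapping the anchor gives distance 0
  touching <- data.table(chrom = "chrT", start = c(290L, 800L),
                         end = c(310L, 820L), family = "AluY",
                         strand = c("+", "-"))
  rt <- closest_alu_pair(pair, touching)
  expect_equal(rt$dist_up, 0L)
  expect_equal(rt$dist_down, 0L)
  # equals the linear-scan oracle on random fixtures
  set.seed(51)
  for (rep in 1:5) {
    ra <- data.table(chrom = "chrT",
                     start = s <- sample(c(200:280, 800:880), 6),
                     end = s + 15L, family = "AluY",
                     strand = sample(c("+", "-"), 6, TRUE))
    ra <- ra[(start >= 200 & end <= 300) | (start >= 800 & end <= 900)]
    if (nrow(ra) == 0L) next
    res <- closest_alu_pair(pair, ra)
    up <- ra[start >= 200 & end <= 300]
    if (nrow(up)) {
      expect_equal(res$dist_up, bf_closest(300L, up, "chrT")$distance)
    }
  }
})

test_that("median splits classify with strict inequalities", {
  pairs <- data.table(circ_id = sprintf("c%d", 1:2),
                      chrom = "chrT", strand = "+",
                      up_start = 0L, up_end = c(50L, 150L),
                      down_start = 0L, down_end = c(50L, 150L),
                      up_len = c(50L, 150L), down_len = c(50L, 150L),
                      total_length = c(100L, 300L))
  iae <- data.table(circ_id = pairs$circ_id, dist_up = c(10L, 20L),
                    dist_down = c(10L, 20L),
                    strand_up = "+", strand_down = "-",
                    inverted = TRUE, total_alu_distance = c(20L, 40L))
  cl <- classify_circ_introns(pairs, iae)
  # medians: length 200, distance 30; strict <
  expect_equal(cl[circ_id == "c1", intron_class], "pIAE-short")
  expect_equal(cl[circ_id == "c2", intron_class], "Long")
  # a value exactly at the distance median is non-proximal
  iae_eq <- copy(iae)[, total_alu_distance := c(30L, 30L)]
  cl2 <- classify_circ_introns(pairs, iae_eq)
  expect_equal(cl2$intron_class, c("Short", "Long"))
})

test_that("a constructed 8-circRNA fixture populates all four classes", {
  lens <- c(100L, 120L, 140L, 160L, 400L, 420L, 440L, 460L)
  pairs <- data.table(circ_id = sprintf("c%d", 1:8), chrom = "chrT",
                      strand = "+", up_start = 0L, up_end = lens / 2L,
                      down_start = 0L, down_end = lens / 2L,
                      up_len = lens / 2L, down_len = lens / 2L,
                      total_length = lens)
  iae <- data.table(
    circ_id = pairs$circ_id,
    dist_up = c(5L, 5L, 300L, 300L, 5L, 5L, 300L, 300L),
    dist_down = c(5L, 5L, 300L, 300L, 5L, 5L, 300L, 300L),
    strand_up = "+", strand_down = "-", inverted = TRUE,
    total_alu_distance = c(10L, 10L, 600L, 600L, 10L, 10L, 600L, 600L)
  )
  cl <- classify_circ_introns(pairs, iae)
  # length median 280 -> c1-c4 short; distance median 305 -> 10 proximal
  expect_equal(cl[order(circ_id)]$intron_class,
               c("pIAE-short", "pIAE-short", "Short", "Short",
                 "pIAE-long", "pIAE-long", "Long", "Long"))
  # the median splits partition the circRNAs exactly
  expect_equal(sum(table(cl$intron_class)), 8L)
})

test_that("intron_length_compare is null for subset = all and sums to 1", {
  set.seed(52)
  pairs <- data.table(circ_id = sprintf("c%02d", 1:40), chrom = "chrT",
                      strand = "+", up_start = 0L, up_end = 100L,
                      down_start = 0L, down_end = 100L,
                      up_len = 100L, down_len = 100L,
                      total_length = sample(100:1000, 40))
  iae <- data.table(circ_id = pairs$circ_id, dist_up = 5L, dist_down = 5L,
                    strand_up = "+",
                    strand_down = sample(c("+", "-"), 40, TRUE),
                    inverted = rep(c(TRUE, FALSE), 20),
                    total_alu_distance = sample(10:500, 40))
  iae[inverted == FALSE, total_alu_distance := NA_integer_]
  cl <- classify_circ_introns(pairs, iae)
  res <- intron_length_compare(pairs$circ_id, cl)
  expect_equal(res$length_test$z, 0)
  expect_equal(res$length_test$p, 1)
  props <- as.matrix(res$class_proportions[, -1])
  expect_equal(unname(rowSums(props)), c(1, 1))
  expect_equal(props[1, ], props[2, ])
  expect_error(intron_length_compare(character(0), cl), "length")
})
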