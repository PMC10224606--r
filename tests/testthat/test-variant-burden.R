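# exon classification relative to circRNAs, variant tallies, and group
# comparisons

test_that("longest containing transcript wins, containment dominates", {
  models <- rbind(
    toy_models(),
    # a longer transcript of GENE1 missing the exon-2 boundary
    data.table(chrom = "chrT", start = c(50L, 500L, 700L, 900L),
               end = c(260L, 600L, 800L, 1100L), strand = "+",
               gene_id = "G1", gene_name = "GENE1",
               transcript_id = "GENE1_t2", exon_index = 1:4)
  )
  circ <- toy_circ(toy_models(), i = 2L, j = 4L)
  expect_equal(select_longest_transcript(models, circ), "GENE1_t1")
  # equal-length tie resolves lexicographically
  twin <- copy(toy_models())[transcript_id == "GENE1_t1",
                             transcript_id := "GENE1_t0"]
  both <- rbind(toy_models(), twin)
  expect_equal(select_longest_transcript(both, circ), "GENE1_t0")
  # no containing transcript: NULL with a message
  stray <- copy(circ)[, start := 301L]
  expect_message(res <- select_longest_transcript(models, stray),
                 "excluded")
  expect_null(res)
})

test_that("classify_exons reproduces the circ/BSJ subdivision scheme", {
  models <- toy_models()
  # circ over exons 2-4 of the 5-exon transcript
  rec <- classify_exons(models, "GENE1_t1", toy_circ(models, i = 2L, j = 4L))
  expect_equal(rec$circ_class, c("nonCirc", "circ", "circ", "circ",
                                 "nonCirc"))
  expect_equal(rec$bsj_class, c(NA, "BSJ", "nonBSJ", "BSJ", NA))
  # single-exon circRNA: that exon is circ/BSJ, everything else nonCirc
  rec1 <- classify_exons(models, "GENE1_t1", toy_circ(models, i = 3L, j = 3L))
  expect_equal(rec1$bsj_class[3], "BSJ")
  expect_equal(sum(rec1$circ_class == "circ"), 1L)
  # circ spanning all exons leaves no nonCirc exon
  rec_all <- classify_exons(models, "GENE1_t1",
                            toy_circ(models, i = 1L, j = 5L))
  expect_false(any(rec_all$circ_class == "nonCirc"))
  # every exon gets exactly one circ class; BSJ+nonBSJ = circ exons
  expect_equal(sum(rec$circ_class == "circ"),
               sum(rec$bsj_class %in% c("BSJ", "nonBSJ")))
  expect_true(all(is.na(rec$bsj_class) == (rec$circ_class == "nonCirc")))
})

test_that("shared exons de-duplicate to the most circular label", {
  models <- toy_models()
  circs <- rbind(toy_circ(models, i = 2L, j = 4L),
                 toy_circ(models, i = 3L, j = 3L))
  ec <- classify_catalog_exons(circs, models)
  expect_equal(nrow(ec), 5L)  # one record per exon
  # exon 3 is nonBSJ for circ 2-4 but BSJ for circ 3-3: BSJ wins
  expect_equal(ec[start == 500L, bsj_class], "BSJ")
  # partition completeness
  expect_true(all(ec$circ_class %in% c("circ", "nonCirc")))
})

test_that("variant tallies match the brute-force per-variant scan", {
  models <- toy_models()
  ec <- classify_catalog_exons(toy_circ(models, i = 2L, j = 4L), models)
  # 2 variants inside a 100-base exon -> 20 per Kb
  v <- data.table(chrom = "chrT", pos = c(310L, 350L), ref = "A", alt = "G",
                  impact = "low", flags = "", cohort = "gnomad")
  t1 <- tally_variants(ec, v)
  expect_equal(t1[start == 300L, n_var], 2L)
  expect_equal(t1[start == 300L, density], 2 / 0.1)
  # boundary position (half-open exon end) is not counted
  vb <- data.table(chrom = "chrT", pos = 400L, ref = "A", alt = "G",
                   impact = "low", flags = "", cohort = "gnomad")
  expect_equal(sum(tally_variants(ec, vb)[start == 300L, n_var]), 0L)
  expect_equal(tally_variants(ec, vb)[start == 500L, n_var], 0L)
  # empty variant set gives all-zero densities
  expect_true(all(tally_variants(ec, v[0])$density == 0))
  # random instances against the oracle
  set.seed(31)
  for (rep in 1:3) {
    vr <- data.table(chrom = "chrT",
                     pos = sample.int(1200L, 100L, replace = TRUE) - 1L,
                     ref = "A", alt = "G", impact = "low", flags = "",
                     cohort = "gnomad")
    expect_equal(tally_variants(ec, vr)$n_var, bf_tally(ec, vr))
  }
})

test_that("burden_compare is null on identical groups and honours filters", {
  models <- toy_models()
  ec <- classify_catalog_exons(toy_circ(models, i = 2L, j = 4L), models)
  # one variant per exon: identical density vectors (equal exon sizes)
  v <- data.table(chrom = "chrT",
                  pos = c(150L, 350L, 550L, 750L, 950L),
                  ref = "A", alt = "G", impact = "low",
                  flags = c("", "splice_region", "", "splice_region,missense",
                            ""),
                  cohort = "gnomad")
  res <- burden_compare(ec, v, grouping = "circ")
  expect_equal(res$z, 0)
  expect_equal(res$p_z, 1)
  expect_equal(res$rate_ratio, 1)
  # splice_region filter retains exactly the flagged subset
  fv <- filter_variants(v, flag = "splice_region")
  expect_equal(fv$pos, c(350L, 750L))
  expect_equal(nrow(filter_variants(v, flag = "missense")), 1L)
  expect_equal(nrow(filter_variants(v, cohort = "asd_dnv")), 0L)
  # a variant filter matching nothing degenerates to the zero comparison
  res0 <- burden_compare(ec, v, grouping = "circ", cohort = "asd_dnv")
  expect_equal(res0$n_variants_a + res0$n_variants_b, 0L)
  expect_equal(res0$z, 0)
  # an empty exon group errors with the group name
  ec_all <- classify_catalog_exons(toy_circ(models, i = 1L, j = 5L), models)
  expect_error(burden_compare(ec_all, v, grouping = "circ"),
               "empty exon group.*nonCirc")
})

test_that("impact proportions and missense fractions follow their contracts", {
  tagged <- data.table(
    chrom = "chrT", pos = 1:8, ref = "A", alt = "G",
    impact = c("low", "medium", "high", "high", "low", "none", "low",
               "medium"),
    flags = c("missense", "missense,deleterious", "", "", "missense", "",
              "", ""),
    cohort = "gnomad",
    circ_class = c(rep("circ", 4), rep("nonCirc", 4)),
    bsj_class = c("BSJ", "BSJ", "nonBSJ", "nonBSJ", NA, NA, NA, NA)
  )
  ip <- impact_proportions(tagged, by = "circ_class")
  circ_row <- ip$proportions[group == "circ"]
  expect_equal(circ_row$low, 0.25)
  expect_equal(circ_row$medium, 0.25)
  expect_equal(circ_row$high, 0.50)
  expect_equal(ip$n_excluded_none, 1L)
  expect_equal(rowSums(as.matrix(ip$proportions[, -1])), c(1, 1),
               ignore_attr = TRUE)
  md <- missense_deleterious_fractions(tagged, by = "circ_class")
  expect_equal(md[grp == "circ", fraction_missense], 0.5)
  expect_equal(md[grp == "circ", fraction_missense_deleterious], 0.5)
  expect_equal(md[grp == "nonCirc", fraction_missense], 0.25)
  expect_equal(md[grp == "nonCirc", fraction_missense_deleterious], 0)
  # a group with zero missense reports a missing conditional fraction
  none <- copy(tagged)[, flags := ""]
  md0 <- missense_deleterious_fractions(none, by = "circ_class")
  expect_true(all(md0$fraction_missense == 0))
  expect_true(all(is.na(md0$fraction_missense_deleterious)))
})

test_that("group Kb totals equal summed member exon lengths", {
  models <- toy_models()
  ec <- classify_catalog_exons(toy_circ(models, i = 2L, j = 4L), models)
  v <- data.table(chrom = "chrT", pos = 350L, ref = "A", alt = "G",
                  impact = "low", flags = "", cohort = "gnomad")
  res <- burden_compare(ec, v, grouping = "circ")
  expect_equal(res$total_kb_a,
               sum(ec[circ_class == "circ", end - start]) / 1000)
  expect_equal(res$total_kb_b,
               sum(ec[circ_class == "nonCirc", end - start]) / 1000)
})
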