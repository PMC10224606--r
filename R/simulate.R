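## Seeded synthetic-data generator. Every input the pipeline consumes
## can be generated with planted, recoverable effects: a toy genome and
## gene models, three pseudo-detector BSJ call sets with controlled
## concordance, DE tables with planted circ/linear LFC correlation and
## offset, variants with a planted circ/nonCirc density ratio, Alu
## annotations with planted inverted pairs, motif instances with a
## planted 5'-intron positional bias, and miRNA site tables. Each
## generator emits a machine-readable truth object sufficient to score
## downstream recovery.

#' Synthetic-data configuration
#'
#' Defaults describe the stated world used throughout the test-suite:
#' 50 genes, roughly 200 circRNAs, 4 samples per condition, three
#' pseudo-detectors at 0.9 concordance, planted circ/linear LFC
#' correlation 0.5 with a one-log2-unit circRNA excess, a 2x
#' circ/nonCirc variant density ratio, and a geometric 5' positional
#' motif bias. Distributional choices: negative binomial read counts,
#' Poisson variant placement, geometric positional bias.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical
#'   outputs.
#' @param n_genes Number of genes.
#' @param exons_per_gene,exon_len,intron_len Integer ranges (min, max).
#' @param n_samples_per_condition Samples per condition (two
#'   conditions).
#' @param detector_concordance Probability each pseudo-detector reports
#'   a true BSJ.
#' @param false_bsj_rate Detector-specific false BSJs per true circRNA.
#' @param nb_mu,nb_dispersion Negative-binomial read-count parameters.
#' @param circ_fraction Fraction of genes hosting circRNAs.
#' @param circs_per_host_lambda Poisson mean for extra circRNAs per
#'   host.
#' @param lfc_rho Planted circ/linear LFC correlation.
#' @param lfc_offset Planted mean circ minus linear LFC excess (log2).
#' @param lfc_sd LFC standard deviation.
#' @param variant_density_per_kb Baseline (nonCirc) variant density.
#' @param variant_density_ratio Planted circ:nonCirc density ratio.
#' @param alu_length Alu element length (bases).
#' @param planted_iae_fraction Fraction of circRNAs given inverted
#'   closest Alus in both flanking introns.
#' @param alu_absent_fraction Among non-IAE circRNAs, fraction with no
#'   flanking Alu at all.
#' @param iae_distance_range Planted BSJ-to-Alu distance range (bases).
#' @param motif_5prime_bias Geometric decay parameter for planted motif
#'   positions (0 = uniform placement).
#' @param motif_instances_lambda Poisson mean of planted instances per
#'   intron.
#' @param mirna_panel Number of miRNAs in the synthetic panel.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 50L,
                         exons_per_gene = c(5L, 12L),
                         exon_len = c(80L, 300L),
                         intron_len = c(300L, 3000L),
                         n_samples_per_condition = 4L,
                         detector_concordance = 0.9,
                         false_bsj_rate = 0.05,
                         nb_mu = 30, nb_dispersion = 5,
                         circ_fraction = 0.8,
                         circs_per_host_lambda = 4,
                         lfc_rho = 0.5, lfc_offset = 1, lfc_sd = 1.5,
                         variant_density_per_kb = 20,
                         variant_density_ratio = 2,
                         alu_length = 250L,
                         planted_iae_fraction = 0.5,
                         alu_absent_fraction = 0.1,
                         iae_distance_range = c(10L, 250L),
                         motif_5prime_bias = 0.01,
                         motif_instances_lambda = 2,
                         mirna_panel = 10L) {
  cfg <- as.list(environment())
  probs <- c(cfg$detector_concordance, cfg$circ_fraction,
             cfg$planted_iae_fraction, cfg$alu_absent_fraction,
             cfg$motif_5prime_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$exon_len[1L] < 10L || cfg$intron_len[1L] <= cfg$alu_length) {
    stop("infeasible length configuration")
  }
  stopifnot(cfg$seed == as.integer(cfg$seed))
  class(cfg) <- "synth_config"
  cfg
}

## internal: deterministic sub-seed per generator stage
.stage_seed <- function(config, stage_offset) {
  as.integer((config$seed * 101L + stage_offset) %% .Machine$integer.max)
}

## sample one element of a vector (immune to the sample(x, 1) scalar rule)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome and gene models
#'
#' Multi-exon genes on both strands over two synthetic chromosomes with
#' random intergenic spacers. Transcript models satisfy all invariants
#' (one transcript per gene).
#'
#' @param config A [synth_config()].
#' @return List: `genome` (`DNAStringSet`), `exons` (transcript model
#'   table as from [read_gtf()]).
#' @export
generate_genome <- function(config) {
  set.seed(.stage_seed(config, 0L))
  chroms <- c("chrS1", "chrS2")
  cursor <- setNames(rep(1000L, 2L), chroms)
  rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    chrom <- chroms[(g %% 2L) + 1L]
    strand <- if ((g %/% 2L) %% 2L == 0L) "+" else "-"
    n_ex <- sample(config$exons_per_gene[1L]:config$exons_per_gene[2L], 1L)
    elens <- sample(config$exon_len[1L]:config$exon_len[2L], n_ex,
                    replace = TRUE)
    ilens <- sample(config$intron_len[1L]:config$intron_len[2L],
                    max(n_ex - 1L, 0L), replace = TRUE)
    starts <- integer(n_ex)
    pos <- cursor[[chrom]]
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      pos <- pos + elens[k] + if (k < n_ex) ilens[k] else 0L
    }
    gene_id <- sprintf("SGENE%03d", g)
    rows[[g]] <- data.table(
      chrom = chrom, start = starts, end = starts + elens, strand = strand,
      gene_id = gene_id, gene_name = gene_id,
      transcript_id = paste0(gene_id, "_t1"),
      exon_index = seq_len(n_ex)
    )
    cursor[[chrom]] <- pos + sample(500:2000, 1L)
  }
  exons <- rbindlist(rows)
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    .rand_dna(max(exons[chrom == ch, end]) + 1000L)
  }, character(1)))
  names(genome) <- chroms
  validate_transcript_models(exons)
  list(genome = genome, exons = exons)
}

#' Plant ground-truth circRNAs on a synthetic gene set
#'
#' Each gene hosts circRNAs with probability `circ_fraction`; hosts get
#' `1 + Poisson(circs_per_host_lambda)` distinct exon spans, drawn so
#' that both flanking introns exist (never the first or last exon).
#'
#' @param config A [synth_config()].
#' @param exons Synthetic transcript models.
#' @return Truth `data.table`: `circ_id`, coordinates, `gene_id`,
#'   `transcript_id`, `bs_exon_from`, `bs_exon_to`, `mu` (expression
#'   mean).
#' @export
generate_truth_circs <- function(config, exons) {
  set.seed(.stage_seed(config, 1L))
  genes <- exons[, .(chrom = chrom[1L], strand = strand[1L],
                     gene_id = gene_id[1L], n_ex = max(exon_index)),
                 by = transcript_id]
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    if (runif(1L) > config$circ_fraction) next
    gi <- genes[g]
    if (gi$n_ex < 4L) next
    n_circ <- 1L + rpois(1L, config$circs_per_host_lambda)
    spans <- unique(data.table(
      i = sample(2:(gi$n_ex - 1L), n_circ, replace = TRUE)
    )[, .(i, j = vapply(i, function(ii) {
      .sample1(ii:(gi$n_ex - 1L))
    }, integer(1)))])
    tx <- exons[transcript_id == gi$transcript_id]
    setorder(tx, start)
    rows[[length(rows) + 1L]] <- spans[, {
      st <- tx$start[i]; en <- tx$end[j]
      .(chrom = gi$chrom, start = st, end = en, strand = gi$strand,
        gene_id = gi$gene_id, transcript_id = gi$transcript_id,
        bs_exon_from = i, bs_exon_to = j,
        circ_id = sprintf("%s_%s:%d-%d", gi$gene_id, gi$chrom, st + 1L, en),
        mu = stats::rlnorm(.N, meanlog = log(config$nb_mu), sdlog = 0.6))
    }]
  }
  out <- rbindlist(rows)
  unique(out, by = "circ_id")
}

#' Generate pseudo-detector BSJ call tables
#'
#' Each true circRNA is reported by each of three pseudo-detectors with
#' probability `detector_concordance`; per-sample read counts are drawn
#' from a negative binomial around the circRNA's planted mean.
#' Detector-specific false BSJs (coordinates inside introns, so they
#' never annotate) are added at `false_bsj_rate` per true circRNA.
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [generate_truth_circs()].
#' @return List: `calls` (row-bound call table with `detector`
#'   column), `detectors` (labels), `truth` (pass-through).
#' @export
generate_bsj_calls <- function(config, truth) {
  set.seed(.stage_seed(config, 2L))
  detectors <- c("detA", "detB", "detC")
  n_s <- 2L * config$n_samples_per_condition
  sample_cols <- sprintf("s%02d", seq_len(n_s))
  rows <- list()
  for (d in detectors) {
    keep <- runif(nrow(truth)) <= config$detector_concordance
    tk <- truth[keep]
    if (nrow(tk)) {
      counts <- matrix(
        rnbinom(nrow(tk) * n_s, mu = rep(tk$mu, each = n_s),
                size = config$nb_dispersion),
        nrow = nrow(tk), byrow = TRUE, dimnames = list(NULL, sample_cols))
      rows[[length(rows) + 1L]] <- cbind(
        tk[, .(chrom, start, end, strand)],
        data.table(detector = d), as.data.table(counts))
    }
    n_false <- rpois(1L, config$false_bsj_rate * nrow(truth))
    if (n_false > 0L) {
      fi <- truth[sample(.N, n_false, replace = TRUE)]
      shift <- sample(13:97, n_false, replace = TRUE)  # off exon boundaries
      counts <- matrix(rnbinom(n_false * n_s, mu = 3, size = 2),
                       nrow = n_false, dimnames = list(NULL, sample_cols))
      rows[[length(rows) + 1L]] <- cbind(
        data.table(chrom = fi$chrom, start = fi$start + shift,
                   end = fi$end + shift, strand = fi$strand, detector = d),
        as.data.table(counts))
    }
  }
  list(calls = rbindlist(rows), detectors = detectors, truth = truth)
}

#' Generate circular and linear differential-expression tables
#'
#' Host-gene linear LFCs are normal with standard deviation `lfc_sd`;
#' each circRNA's LFC is drawn bivariate-normal against its host's with
#' correlation `lfc_rho` and mean excess `lfc_offset`. Adjusted
#' p-values come from simulated Wald p-values with Benjamini-Hochberg
#' correction.
#'
#' @param config A [synth_config()].
#' @param truth Truth circRNA table.
#' @return List: `circ_de`, `linear_de` (DE tables), `pairing`
#'   (`circ_id`, `gene_id`).
#' @export
generate_de_tables <- function(config, truth) {
  set.seed(.stage_seed(config, 3L))
  hosts <- unique(truth$gene_id)
  z_host <- setNames(rnorm(length(hosts)), hosts)
  lfc_lin <- config$lfc_sd * z_host
  rho <- config$lfc_rho
  z_circ <- rho * z_host[truth$gene_id] +
    sqrt(1 - rho^2) * rnorm(nrow(truth))
  lfc_circ <- config$lfc_offset + config$lfc_sd * z_circ
  se <- 0.5
  mk <- function(ids, lfc) {
    p <- 2 * pnorm(-abs(lfc) / se)
    data.table(feature_id = ids,
               base_mean = stats::rlnorm(length(ids), log(100), 1),
               lfc = lfc, padj = p.adjust(p, "BH"))
  }
  list(
    circ_de = mk(truth$circ_id, lfc_circ),
    linear_de = mk(hosts, unname(lfc_lin)),
    pairing = truth[, .(circ_id, gene_id)]
  )
}

## internal, generator-private exon labelling (kept independent of the
## burden module so recovery tests have a genuine oracle)
.truth_exon_classes <- function(truth, exons) {
  rbindlist(lapply(seq_len(nrow(truth)), function(r) {
    tr <- truth[r]
    tx <- exons[transcript_id == tr$transcript_id]
    setorder(tx, start)
    tx[, .(chrom, start, end, strand, transcript_id, gene_id,
           exon_index,
           circ = exon_index >= tr$bs_exon_from &
             exon_index <= tr$bs_exon_to)]
  }))[, .(circ = any(circ)), by = .(chrom, start, end, strand,
                                    transcript_id, gene_id, exon_index)]
}

#' Generate a variant table with a planted circ/nonCirc density ratio
#'
#' Variants are placed by a Poisson process at density
#' `variant_density_per_kb` in non-circularised exons and
#' `variant_density_ratio` times that in circularised exons, with
#' categorical impact and flag annotations.
#'
#' @param config A [synth_config()].
#' @param truth Truth circRNA table.
#' @param exons Synthetic transcript models.
#' @param cohort Cohort label stamped on every variant.
#' @return List: `variants` (variant table), `truth_classes`
#'   (generator-side exon labels used for planting).
#' @export
generate_variants <- function(config, truth, exons, cohort = "gnomad") {
  set.seed(.stage_seed(config, 4L))
  cls <- .truth_exon_classes(truth, exons)
  rows <- lapply(seq_len(nrow(cls)), function(r) {
    e <- cls[r]
    len_kb <- (e$end - e$start) / 1000
    rate <- config$variant_density_per_kb * len_kb *
      (if (e$circ) config$variant_density_ratio else 1)
    n <- rpois(1L, rate)
    if (n == 0L) return(NULL)
    pos <- e$start + sample.int(e$end - e$start, n, replace = TRUE) - 1L
    impact <- sample(c("low", "medium", "high", "none"), n, replace = TRUE,
                     prob = c(0.6, 0.25, 0.1, 0.05))
    missense <- runif(n) < 0.35
    deleterious <- missense & runif(n) < 0.3
    splice <- runif(n) < 0.12
    flags <- vapply(seq_len(n), function(k) {
      paste(c("missense"[missense[k]], "splice_region"[splice[k]],
              "deleterious"[deleterious[k]]), collapse = ",")
    }, character(1))
    data.table(chrom = e$chrom, pos = pos,
               ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               impact = impact, flags = flags, cohort = cohort)
  })
  variants <- rbindlist(rows)
  if (nrow(variants)) setorder(variants, chrom, pos)
  list(variants = variants, truth_classes = cls)
}

#' Generate a repeat annotation with planted inverted Alu pairs
#'
#' A `planted_iae_fraction` share of circRNAs receives opposite-strand
#' Alu elements in both flanking introns at controlled BSJ distances;
#' the remainder receive same-strand Alus or (for
#' `alu_absent_fraction` of them) none.
#'
#' @param config A [synth_config()].
#' @param pairs Flanking-intron pair table
#'   ([catalog_flanking_introns()]).
#' @return List: `alus` (BED6-shaped table, `name` = family), `truth`
#'   (`circ_id`, `planted_inverted`, `d_up`, `d_down`).
#' @export
generate_alu_annotation <- function(config, pairs) {
  set.seed(.stage_seed(config, 5L))
  al <- config$alu_length
  place <- function(chrom, s, e, anchor_at_end, d) {
    if (anchor_at_end) data.table(chrom = chrom, start = e - d - al,
                                  end = e - d)
    else data.table(chrom = chrom, start = s + d, end = s + d + al)
  }
  alu_rows <- list(); truth_rows <- list()
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r]
    planted <- runif(1L) <= config$planted_iae_fraction
    if (!planted && runif(1L) < config$alu_absent_fraction) {
      truth_rows[[r]] <- data.table(circ_id = p$circ_id,
                                    planted_inverted = FALSE,
                                    d_up = NA_integer_, d_down = NA_integer_)
      next
    }
    dmax_up <- min(config$iae_distance_range[2L], p$up_len - al - 1L)
    dmax_down <- min(config$iae_distance_range[2L], p$down_len - al - 1L)
    d_up <- .sample1(config$iae_distance_range[1L]:max(dmax_up,
                     config$iae_distance_range[1L]))
    d_down <- .sample1(config$iae_distance_range[1L]:max(dmax_down,
                       config$iae_distance_range[1L]))
    s_up <- .sample1(c("+", "-"))
    s_down <- if (planted) setdiff(c("+", "-"), s_up) else s_up
    # BSJ side: upstream intron anchored at the acceptor-exon boundary,
    # downstream at the donor boundary (strand-dependent end)
    up_alu <- place(p$chrom, p$up_start, p$up_end,
                    anchor_at_end = p$strand == "+", d_up)
    down_alu <- place(p$chrom, p$down_start, p$down_end,
                      anchor_at_end = p$strand == "-", d_down)
    fam <- sample(c("AluSx", "AluY", "AluJb"), 2L, replace = TRUE)
    alu_rows[[length(alu_rows) + 1L]] <- rbind(
      up_alu[, .(chrom, start, end, name = fam[1L], score = 0L,
                 strand = s_up)],
      down_alu[, .(chrom, start, end, name = fam[2L], score = 0L,
                   strand = s_down)])
    truth_rows[[r]] <- data.table(circ_id = p$circ_id,
                                  planted_inverted = planted,
                                  d_up = d_up, d_down = d_down)
  }
  list(alus = rbindlist(alu_rows), truth = rbindlist(truth_rows))
}

#' Plant motif instances with a 5' positional bias into sequences
#'
#' Inserts concrete consensus instances into intron sequences at
#' offsets drawn geometrically from the 5' end (decay
#' `motif_5prime_bias`; 0 places uniformly), never overlapping each
#' other, and records every planted offset in a truth table.
#'
#' @param config A [synth_config()].
#' @param intron_seqs Table with `circ_id`, `side`, `seq`.
#' @param motif A concrete (A/C/G/U only) consensus `motif`.
#' @return List: `seqs` (mutated table), `truth` (`circ_id`, `side`,
#'   `offset`).
#' @export
plant_motifs <- function(config, intron_seqs, motif) {
  set.seed(.stage_seed(config, 6L))
  stopifnot(motif$kind == "consensus",
            !grepl("[^ACGU]", motif$consensus))
  w <- motif_width(motif)
  seqs <- copy(as.data.table(intron_seqs))
  truth <- list()
  for (r in seq_len(nrow(seqs))) {
    L <- nchar(seqs$seq[r])
    if (L < w) next
    n_inst <- rpois(1L, config$motif_instances_lambda)
    if (n_inst == 0L) next
    taken <- integer()
    offs <- integer()
    for (k in seq_len(n_inst)) {
      for (try in 1:20) {
        o <- if (config$motif_5prime_bias > 0) {
          min(rgeom(1L, config$motif_5prime_bias), L - w)
        } else {
          sample.int(L - w + 1L, 1L) - 1L
        }
        if (!any(abs(o - taken) < w)) { taken <- c(taken, o); offs <- c(offs, o); break }
      }
    }
    s <- seqs$seq[r]
    for (o in offs) {
      s <- paste0(substr(s, 1L, o), motif$consensus,
                  substr(s, o + w + 1L, L))
    }
    seqs[r, seq := s]
    if (length(offs)) {
      truth[[length(truth) + 1L]] <- data.table(
        circ_id = seqs$circ_id[r], side = seqs$side[r], offset = sort(offs))
    }
  }
  list(seqs = seqs, truth = rbindlist(truth))
}

#' Generate miRNA site tables with derivable truth axes
#'
#' A synthetic panel of miRNAs is assigned sites (1-3 per target, the
#' observed per-circRNA maximum) in random subsets of circRNAs and
#' mRNA 3'UTRs. Truth axes are derived by the same-direction rule with
#' a generator-private loop, independent of [build_axes()].
#'
#' @param config A [synth_config()].
#' @param circ_de,mrna_de DE tables ([generate_de_tables()]).
#' @return List: `circ_sites`, `utr_sites`, `truth_axes`, `mirnas`
#'   (panel sequences).
#' @export
generate_mirna_sites <- function(config, circ_de, mrna_de) {
  set.seed(.stage_seed(config, 7L))
  mirnas <- setNames(
    vapply(seq_len(config$mirna_panel), function(i) {
      paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
            collapse = "")
    }, character(1)),
    sprintf("sim-miR-%02d", seq_len(config$mirna_panel)))
  pick_sites <- function(ids, type) {
    n_pick <- max(1L, round(0.6 * length(ids)))
    chosen <- sample(ids, min(n_pick, length(ids)))
    rbindlist(lapply(chosen, function(id) {
      mir <- sample(names(mirnas), sample(1:3, 1L))
      data.table(mirna = mir, target_id = id, target_type = type,
                 position = sample.int(500L, length(mir)),
                 n_sites = sample(1:3, length(mir), replace = TRUE))
    }))
  }
  circ_sites <- pick_sites(circ_de$feature_id, "circ")
  utr_sites <- pick_sites(mrna_de$feature_id, "utr3")
  # generator-private derivation of expected axes
  lab <- function(de) {
    ifelse(is.na(de$padj) | de$padj >= 0.05, "ns",
           ifelse(de$lfc >= 2, "up", ifelse(de$lfc <= -2, "down", "ns")))
  }
  cl <- setNames(lab(circ_de), circ_de$feature_id)
  ml <- setNames(lab(mrna_de), mrna_de$feature_id)
  truth <- list()
  for (ci in unique(circ_sites$target_id)) {
    dc <- cl[[ci]]
    if (dc == "ns") next
    for (m in unique(circ_sites[target_id == ci, mirna])) {
      for (gi in unique(utr_sites[mirna == m, target_id])) {
        if (identical(ml[[gi]], dc)) {
          truth[[length(truth) + 1L]] <- data.table(
            circ_id = ci, mirna = m, mrna_gene = gi, direction = dc)
        }
      }
    }
  }
  truth_axes <- if (length(truth)) {
    unique(rbindlist(truth))[order(circ_id, mirna, mrna_gene)]
  } else {
    data.table(circ_id = character(), mirna = character(),
               mrna_gene = character(), direction = character())
  }
  list(circ_sites = circ_sites, utr_sites = utr_sites,
       truth_axes = truth_axes, mirnas = mirnas)
}

#' Generate the full synthetic dataset
#'
#' Runs every generator in dependency order under the configured seed.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `genome`, `exons`, `truth`, `calls`,
#'   `de` (circ/linear/pairing), `variants`, `pairs` (flanking
#'   introns), `alus`, `mirna` components.
#' @export
simulate_dataset <- function(config = synth_config()) {
  gen <- generate_genome(config)
  truth <- generate_truth_circs(config, gen$exons)
  calls <- generate_bsj_calls(config, truth)
  de <- generate_de_tables(config, truth)
  vars <- generate_variants(config, truth, gen$exons)
  ann <- copy(truth)[, `:=`(annotation = "annotated",
                            host_gene = gene_id)]
  pairs <- catalog_flanking_introns(ann, gen$exons)
  alu <- generate_alu_annotation(config, pairs)
  mir <- generate_mirna_sites(config, de$circ_de, de$linear_de)
  list(config = config, genome = gen$genome, exons = gen$exons,
       truth = truth, calls = calls, de = de, variants = vars,
       pairs = pairs, alu = alu, mirna = mir)
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTA, GTF, per-detector call TSVs, DE tables, variant
#' table, Alu BED and miRNA site tables, plus a `truth/` directory with
#' every truth table. Output is byte-identical under a fixed
#' configuration seed.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$exons, file.path(dir, "models.gtf"))
  for (d in sim$calls$detectors) {
    write_tsv_table(sim$calls$calls[detector == d][, detector := NULL],
                    file.path(dir, paste0("bsj_", d, ".tsv")))
  }
  write_tsv_table(sim$de$circ_de, file.path(dir, "de_circ.tsv"))
  write_tsv_table(sim$de$linear_de, file.path(dir, "de_linear.tsv"))
  write_tsv_table(sim$de$pairing, file.path(dir, "pairing.tsv"))
  write_tsv_table(sim$variants$variants, file.path(dir, "variants.tsv"))
  write_bed(sim$alu$alus, file.path(dir, "alu.bed"))
  write_tsv_table(
    data.table(name = "SFPQ_M1", consensus = "UGUAAU", rbp = "SFPQ"),
    file.path(dir, "motifs.tsv"))
  write_tsv_table(sim$mirna$circ_sites, file.path(dir, "mirna_circ_sites.tsv"))
  write_tsv_table(sim$mirna$utr_sites, file.path(dir, "mirna_utr_sites.tsv"))
  write_tsv_table(sim$truth, file.path(dir, "truth", "circs.tsv"))
  write_tsv_table(sim$variants$truth_classes,
                  file.path(dir, "truth", "exon_classes.tsv"))
  write_tsv_table(sim$alu$truth, file.path(dir, "truth", "alu.tsv"))
  write_tsv_table(sim$mirna$truth_axes,
                  file.path(dir, "truth", "axes.tsv"))
  invisible(dir)
}
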