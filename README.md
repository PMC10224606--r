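# circscape

Downstream characterisation of circular RNAs (circRNAs) detected from
total RNA sequencing. circRNAs arise from back-splicing: a downstream
splice donor joins an upstream acceptor, producing a covalently closed
transcript identified by its back-spliced junction (BSJ) coordinates.
Detection from total RNA-seq relies on BSJ-spanning reads and is prone
to false positives, so practical pipelines intersect the calls of
several detection programmes and only then characterise the surviving
catalogue. `circscape` implements that downstream characterisation as a
tested, reusable R package for transcriptomics researchers:

* **Catalogue construction** — merge per-detector BSJ call tables
  (coordinate dialects normalised on read), filter on minimum
  expression and ≥ 2-detector support, annotate splice status against
  gene models (`annotated` when both BSJ ends coincide exactly with
  exon boundaries of one transcript, `de novo` otherwise), and
  summarise host genes (multi-isoform hosts, "hotspot" genes with more
  than ten circRNA isoforms).
* **Circ/linear concordance** — Pearson correlation of circRNA and
  host-gene log2 fold-changes, the fraction of circRNAs more than
  two-fold above their linear counterpart, DESeq2-style up/down/ns
  classification at |LFC| ≥ 2 and adjusted p < 0.05, DEXSeq-style
  exon-bin aggregation and differential-splicing classification, and
  one-tailed hypergeometric over-representation tests
  `P(X ≥ k)` with `N` universe genes, `K` spliced, `n` selected.
* **Variant burden** — exons of the longest transcript containing both
  back-spliced exons are split into `circ`/`nonCirc` and, within circ,
  `BSJ`/`nonBSJ`; variant frequencies are normalised per Kb of exon and
  compared with a two-sample Z-test
  (`z = (m̄ₐ − m̄ᵦ) / √(seₐ² + seᵦ²)`) plus a Wilcoxon rank-sum
  companion, with impact-class and missense/deleterious breakdowns.
* **Motif scanning** — FIMO-style scanning of circRNA and
  flanking-intron sequences with position probability matrices scored
  as log-odds against an i.i.d. background; per-position p-values are
  exact tail probabilities of the discretised score distribution
  (dynamic programming), hits at p ≤ 0.001. Enrichment against a
  background sequence set uses a one-tailed Fisher test on hit
  presence; positional profiles bin hit-to-anchor distances and
  normalise by the number of circRNAs.
* **Intron/Alu classification** — flanking introns extracted in
  transcription orientation; Alu repeats kept when ≥ 50% of the element
  overlaps a flanking intron; a circRNA has inverted Alu elements (IAE)
  when the closest retained Alus in its two flanking introns lie on
  opposite strands; median splits over total intron length and total
  BSJ-to-Alu distance yield the `Short`/`Long`/`pIAE-short`/`pIAE-long`
  classes.
* **miRNA axes** — circRNA:miRNA:mRNA triples emitted when both ends
  carry sites for the same miRNA and share a regulation direction, with
  a clearly labelled seed-match stand-in for external site prediction.
* **Synthetic data** — a seeded generator for every input above with
  planted, recoverable effects (detector concordance, LFC correlation
  and offset, variant density ratio, inverted-Alu pairs, positional
  motif bias), so the whole pipeline is testable offline.

## Worked example

```r
library(circscape)

sim   <- simulate_dataset(synth_config(seed = 42))
merged <- merge_bsj_calls(sim$calls$calls)
expr_f <- filter_expression(merged)          # total reads >= 5, >= 2 samples
final  <- filter_detector_support(expr_f)    # >= 2 detectors
ann    <- annotate_splice_status(final, sim$exons)
host_gene_summary(ann, n_total = nrow(merged),
                  n_expression_filtered = nrow(expr_f))
#> circRNA catalogue summary
#>   raw calls:              208
#>   expression-filtered:    208 (100.0%)
#>   multi-detector:         173 (83.2%)
#>   known / novel / de novo: 0 / 173 / 0
#>   host genes:             41 (41 multi-isoform, 0 hotspot)

ec <- classify_catalog_exons(ann, sim$exons)
burden_compare(ec, sim$variants$variants, grouping = "circ")
#> variant burden circ vs nonCirc
#>   circ: 1645 variants / 41.42 Kb = 39.713 per Kb (222 exons)
#>   nonCirc: 518 variants / 24.43 Kb = 21.207 per Kb (131 exons)
#>   rate ratio 1.873; z = 12.862, p_z = 7.33e-38, p_wilcoxon = 1.08e-25

lfc_correlation(sim$de$circ_de, sim$de$linear_de, sim$de$pairing)$r
#> [1] 0.513
```

The 173 multi-detector circRNAs are the characterisation set; the
singleton-detector records dropped here are the simulator's planted
false BSJ calls plus truth circRNAs missed by two detectors. The
variant rate ratio of 1.87 per Kb recovers the generator's planted 2×
circ/nonCirc density ratio, and the LFC correlation of 0.51 recovers
the planted 0.5.

## Command line

```sh
inst/cli/circscape simulate --seed 1 --outdir simdata
inst/cli/circscape run --config pipeline.json
```

`run` executes catalog → concordance → burden → motifs → introns → axes
from a JSON configuration (paths, stage toggles, thresholds) and writes
stage TSVs plus a `summary.json` that echoes every threshold used.

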