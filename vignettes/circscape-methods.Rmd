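---
title: "circscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models and procedures, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test-suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates

All internal coordinates are 0-based half-open (BED convention);
external 1-based inclusive dialects (GTF, CIRI-style detector tables,
user-facing circRNA identifiers of the form `HOSTGENE_chrom:start-end`)
are converted exactly once at the I/O layer, and the conversion is an
involution. Distances between a point and a disjoint interval are gap
lengths in bases, with abutting half-open intervals at distance zero —
the `bedtools closest` convention. Ties in closest-feature queries
break deterministically by smaller start coordinate, then input order.
Interval intersection and closest-feature search are backed by
IRanges/GenomicRanges behind these contracts; the test-suite checks
both against brute-force all-pairs and linear-scan oracles at up to
n = 500.

One documented oddity in the motivating data: a pair of unannotated
exons is printed with a "90-b" label whose 1-based inclusive
coordinates span 30 bases. The package trusts coordinates; the
30-base value is what the tests assert.

## Catalogue construction

BSJ calls agreeing within `slack` bases on both ends (default 0, exact)
and sharing chromosome and strand merge into one circRNA. Three open
choices, each configurable:

* **Count combination.** Per-sample counts are combined as the maximum
  across detectors (default) rather than the sum: the detectors see the
  same reads, so summing would double-count; the mean is available.
* **Coordinate choice.** The merged record takes the coordinates of
  the first detector present in a configurable priority order, making
  output deterministic under detector reordering.
* **Expression thresholds.** The original filtering is delegated to an
  upstream tool whose thresholds are not printed; the defaults here
  (total reads ≥ 5, ≥ 2 samples with ≥ 1 read) are deliberately
  conservative and explicit.

Records with identical coordinates on opposite strands are never merged
and carry a `strand_conflict` flag. Merging is idempotent, and the
expression and detector-support filters commute — both properties are
tested.

A circRNA is `annotated` when both BSJ ends coincide *exactly* with
exon boundaries of a single transcript; near-misses are `de_novo` with
host gene `intergenic`. When transcripts of two genes match, the gene
of the longest matching transcript wins with a logged warning.
Single-exon circRNAs are annotated with equal back-spliced exon
indices. Hotspot hosts are genes with more than ten (i.e. ≥ 11)
circRNAs — strictly more, a boundary the tests pin.

## Concordance statistics

Differential-expression labels use inclusive LFC (|LFC| ≥ 2) and strict
adjusted-p (padj < 0.05) thresholds; missing padj is never significant.
Exon bins aggregate to annotated exons with mean LFC and **minimum**
bin padj: the gene-level rule classifies a gene as differentially
spliced when *at least one* bin qualifies, and the min-padj aggregation
is the exon-level statement of the same rule (a documented choice where
the convention is otherwise unspecified). The splicing-rate and gene-set
tests are one-tailed upper hypergeometric probabilities, P(X ≥ k) —
the direction of "enrichment" — with Benjamini–Hochberg adjustment
across sets; whether the original test was one- or two-tailed is not
stated, and one-tailed is assumed throughout. The two-sample Z-test
uses unbiased (n − 1) standard deviations and per-group standard
errors of the mean; the Wilcoxon rank-sum companion is exact below
n = 25 per group without ties and a tie-corrected normal approximation
otherwise.

## Variant burden

For each annotated circRNA, exons come from the longest transcript
whose exon boundaries contain both BSJ ends — containment dominates
length, so a shorter containing transcript beats a longer
non-containing one. Exons between the BSJ boundaries inclusive are
`circ` (assuming no exon is spliced out of the circRNA); the two
boundary exons are `BSJ`, strictly internal ones `nonBSJ`; the rest
`nonCirc`. Exons shared between several circRNAs of one gene are
de-duplicated keeping the most circular label (BSJ > nonBSJ > nonCirc)
so nothing is double-counted; whether the original analysis
de-duplicated is unstated, and this is our choice. Variants map to
exons by (start) position under the half-open rule; indels by their
start. Densities are counts per Kb of exon. The Z-test and Wilcoxon
run on the **per-exon density vectors**, not pooled counts, because the
figure legends pair the tests with per-Kb frequencies; pooled per-Kb
frequencies and their ratio are reported alongside. Cohorts (gnomAD,
de novo variant sets) are analysed separately, never pooled.

## Motif scanning

PPM motifs are scored as log2 odds against an i.i.d. background; the
per-position p-value is the exact tail probability of the score under
that background, computed by dynamic programming over the discretised
score distribution (granularity 1e-4 bits — fine enough that the
tests' exhaustive enumeration oracle agrees to ~1e-5 in p). Windows
containing `N` are skipped; bases with zero PPM probability make a
window ineligible, which is exactly what makes an indicator PPM behave
identically to its consensus. Hits are offsets with p ≤ 0.001 (the
FIMO threshold used throughout). IUPAC consensus motifs hit on exact
compatibility, with p defined as the background probability of the
consensus and no threshold applied — a match is a hit by construction.

Enrichment against a background sequence set is a one-tailed Fisher
exact test on hit presence per sequence, BH-adjusted across motifs.
This is a documented stand-in for AME-style enrichment, not a
re-implementation of its default pipeline; results carry
`method = "fisher_hit_presence"`. Background base frequencies default
to the composition of the background set.

CircRNA sequences are extracted linearly (matching the apparent use of
linearised sequences upstream); the `junction_wrap` option appends the
first W − 1 bases so BSJ-spanning sites of width up to W become visible.

### Positional profiles

Hits on flanking introns are binned by distance to an anchor (default
bin 100 b — the original binning is not stated) and normalised by the
number of circRNAs in the subset. Anchor geometry deserves care: the
BSJ acceptor sits at the **3' end of the upstream intron** and the
donor at the **5' end of the downstream intron**. The
`bsj_distal_splice_site` anchor is therefore the 5' end for upstream
introns and the 3' end for downstream introns. A consequence the tests
exercise: hits planted geometrically from 5' ends look 5'-skewed under
both anchors for upstream introns, but 3'-skewed under the distal
anchor for downstream introns.

## Intron length and inverted Alu classification

Alu elements (family prefix `"Alu"` in the repeat annotation) are
retained when at least 50% of the element (inclusive) overlaps a
flanking intron. Per intron, the closest retained element to the BSJ
splice-site coordinate on that side is found, distance measured to the
element's nearest edge (overlap → 0); edge rather than midpoint is the
`bedtools` behaviour and the original choice is unstated. A circRNA
has inverted Alu elements when the two closest elements lie on opposite
annotation strands — annotation strands, not strands relative to the
transcript. Median splits are strict: total intron length below the
cohort median is `Short`, total Alu distance below the IAE-cohort
median is proximal (`pIAE-`); values equal to a median fall on the
Long/non-proximal side, following the "less than the median" wording.
The four classes partition the circRNAs with both flanking introns.

## The synthetic-data generator

Defaults state the world the tests run in: 50 genes over two synthetic
chromosomes on both strands, 5–12 exons of 80–300 b separated by
introns of 300–3000 b, ~200 circRNAs (80% of genes host, 1 + Poisson(4)
isoforms each), 4 samples per condition, three pseudo-detectors at 0.9
concordance with negative-binomial counts (mu 30, size 5) and a 5%
detector-specific false-BSJ rate, planted circ/linear LFC correlation
0.5 with a one-log2-unit circRNA excess (the magnitudes reported for
the motivating dataset), a 2× circ/nonCirc variant density ratio at 20
variants/Kb baseline (Poisson placement), 250-b Alu elements planted
inverted for 50% of circRNAs at 10–250 b from the BSJ, geometric
(p = 0.01) 5'-biased motif planting, and a 10-miRNA panel. Every
generator is seeded (per-stage sub-seeds derived from the configuration
seed) and byte-identical under a fixed seed; every planted effect comes
with a machine-readable truth table produced by generator-private code,
independent of the analysis paths it scores.

What the generator does *not* emulate: read-level sequencing noise,
splice-isoform diversity beyond one transcript per gene, realistic
human base composition or repeat structure, linked variants, and — by
design — interaction between circRNA isoforms of one host when Alu
truth must be recoverable: isoforms of one gene share flanking introns,
so a planted element for one isoform can be the closest element of
another. Recovery tests therefore use single-isoform configurations
(`circs_per_host_lambda = 0`); multi-isoform datasets remain valid
inputs, just without per-circRNA Alu truth guarantees. A green test
establishes that the implementation recovers what was planted under
these idealised conditions, not that it would recover effects from real
sequencing data.

## Pipeline and configuration

Stages run in dependency order (catalog → concordance → burden →
motifs → introns → axes); the JSON summary echoes every threshold for
provenance, and reruns on identical inputs are bit-identical apart from
the timestamped log. The configuration format is JSON rather than YAML
because the target R environment provides no YAML parser; the structure
(inputs, stage toggles, thresholds, seed) is unchanged and unknown keys
are rejected. Exit codes distinguish validation (2) from runtime (1)
failures.

## miRNA axes

The primary mode ingests externally produced site tables; the built-in
seed matcher (reverse complement of miRNA positions 2–8, zero
mismatches by default) is an explicitly labelled simplification whose
rows carry `method = "seed_match"`. Axes require both the circRNA and
the mRNA to carry at least one site for the same miRNA and to share a
DE direction; whether the original analysis additionally constrained
effect sizes beyond the DE thresholds is not stated, and DE-label
matching is what is implemented. When a gene has several annotated
3'UTRs the longest is used.

## Known limitations

* The catalogue's headline counts from the motivating study are
  dataset-dependent and not reproducible without its sequencing data;
  the acceptance layer therefore combines the three printed worked
  examples with planted-effect recovery on synthetic data.
* Merging with positive `slack` uses greedy single-linkage on sorted
  starts; pathological call clusters spanning more than `slack` from
  the cluster representative split deterministically but arbitrarily.
* The AME and RNA22 stand-ins are simplifications and say so in their
  output metadata; they are not drop-in replacements for those tools.
* `de_novo` circRNAs are given host gene `intergenic` even when they
  overlap a gene body; host assignment for non-annotated BSJs is out
  of scope here.
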