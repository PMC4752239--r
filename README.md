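# prokmethylome

Analysis of prokaryotic DNA methylomes from single-molecule sequencing
kinetics: calling unmethylated methyltransferase target sites and testing
them for the statistical signatures of gene regulation.

## The problem

Prokaryotic DNA methyltransferases (MTases) methylate short recognition
motifs genome-wide — GATC for the *E. coli* Dam MTase, GANTC for CcrM,
and hundreds of other specificities. "Orphan" MTases, encoded without a
cognate restriction enzyme, are candidate gene regulators, and their
hallmark is a small set of target sites that stay reproducibly
**unmethylated** (typically shielded by bound regulatory proteins).
Kinetic sequencing exposes methylation through the inter-pulse duration
ratio (ipdR): the delay in base incorporation relative to an unmodified
control, elevated at m6A/m4C and weakly at m5C positions.

This package is for microbiologists and genomicists who have per-base
ipdR/coverage tracks, a genome with annotation and a list of methylated
motifs, and want to know: which motif instances are unmethylated, are
they enriched in gene regulatory regions (overall, per COG functional
category, or at transcription-factor binding sites), do they form
significant clusters, do motifs cluster in non-coding regions the way
replication-origin regulators do, and are any of these patterns conserved
across genomes?

## The statistics at the core

For a palindromic motif with methylatable bases on both strands, two
data-derived thresholds are computed from trimmed means over the central
60% of ranked ipdR values:

```
under_thr = 0.1 * avg_motif + 0.9 * avg_nonmotif     (10% methylated)
meth_thr  = 0.5 * avg_motif + 0.5 * avg_nonmotif     (50% methylated)
```

An instance is *unmethylated* iff both strands have >= 20x coverage and
ipdR < under_thr, and *methylated* iff both are covered with ipdR >=
meth_thr. Downstream tests: fold enrichment of unmethylated vs methylated
sites in regulatory regions (100 bp upstream to 50 bp downstream of CDS
starts) with two-sided Fisher exact p-values; composition-matched
resampling (1000 draws) for motif-level enrichment; a 10,000-iteration
permutation null for runs of >= 3 adjacent unmethylated sites; an upper
binomial tail `P(X >= obs)` with locally estimated motif density,
Bonferroni-corrected at 1e-5, for motif clusters in non-coding regions;
and bitscore-ratio ortholog scoring (conserved at > 50% of a taxon's
species, similarity >= 35) with reciprocal-best-hit matching of flanking
genes for cross-genome conservation.

A synthetic-methylome generator (`build_scenario()`) produces genomes,
annotations and lognormal kinetic tracks with known ground truth, so the
entire pipeline is testable without any external data.

## Worked example

Simulate an orphan-MTase methylome (200 kb, 500 GATC sites, 20 planted
unmethylated with regulatory bias), then run calling and enrichment:

```r
library(prokmethylome)

sc    <- build_scenario("orphan_regulatory", seed = 1)
inst  <- find_motif_instances(sc$genome, sc$motif)
thr   <- compute_thresholds(sc$track, inst, sc$motif, sc$genome)
calls <- call_instances(sc$track, inst, thr)
call_summary(calls)$counts
#>   methylated unmethylated    ambiguous low_coverage
#>          480           20            0            0

c(thr$under_thr, thr$meth_thr)
#> [1] 1.299 2.497

enr <- unmethylated_region_enrichment(calls, sc$regions)
#> unmethylated motifs in regulatory regions: 12/20 (60%) vs 12.1% of methylated
#> fold enrichment 5.0, Fisher p = 1.18e-06
```

All 20 planted unmethylated sites are recovered (none of the 480
methylated sites is miscalled), the thresholds land where the kinetic
model predicts (background ipdR 1.0, methylated 4.0 give 1.3 and 2.5),
and the planted regulatory bias is detected as a 5-fold enrichment with
a vanishing Fisher p-value.

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate.R` through `06_conservation.R` — each a thin narrative
script over the package functions that prints what it finds and writes
its tables under `results/`.

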