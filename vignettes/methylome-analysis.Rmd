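---
title: "Calling and interpreting unmethylated sites in prokaryotic methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting unmethylated sites in prokaryotic methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokmethylome)
```

## The problem

Most prokaryotic genomes carry DNA methyltransferases (MTases) that
methylate every occurrence of a short recognition motif — either as the
protective half of a restriction–modification (RM) system, or as "orphan"
MTases with no cognate restriction enzyme. Orphan MTases such as Dam
(GATC) and CcrM (GANTC) regulate gene expression and DNA replication, and
a telltale signature of such regulatory roles is the existence of a small
set of motif instances that are reproducibly *unmethylated*, typically
because a bound regulatory protein shields them from the MTase.

Single-molecule real-time sequencing measures methylation through
polymerase kinetics: the inter-pulse duration ratio (ipdR) is the delay in
base incorporation relative to an unmodified control and is elevated at
modified bases — strongly for N6-methyladenine (m6A) and
N4-methylcytosine (m4C), weakly for 5-methylcytosine (m5C). This package
implements the downstream analysis: given a genome, its annotation, a
per-base ipdR/coverage track and the genome's methylated motifs, it calls
unmethylated motif instances and asks whether they carry the statistical
signatures of regulation — enrichment in gene regulatory regions, spatial
clustering, motif clusters at replication origins, and cross-genome
conservation.

## Methylation calling

For a palindromic Type II motif with a methylatable base on each strand,
every genomic instance has two evidence channels (forward and reverse
ipdR). Two thresholds are derived per motif from the data themselves:

* the **average motif ipdR**, a trimmed mean over the ipdR of all
  methylatable motif positions (both strands pooled), and the **average
  non-motif ipdR**, a trimmed mean over all other genome positions of the
  same nucleotide. Both use the central 60% of ranked values so that a
  small unmethylated subpopulation or outliers cannot bias the averages;
  the trim count is `floor(0.2 n)` per end.
* the **under-methylated threshold**
  `0.1 * avg_motif + 0.9 * avg_nonmotif` — the ipdR expected if only 10%
  of molecules were methylated — and the **methylated threshold**
  `0.5 * avg_motif + 0.5 * avg_nonmotif`.

An instance is called **unmethylated** only when *both* strands have at
least 20-fold read coverage and ipdR strictly below the under-methylated
threshold; **methylated** when both strands are covered and at or above
the methylated threshold; **low-coverage** when either strand has fewer
than 20 reads (a position absent from the track counts as coverage 0);
otherwise **ambiguous**. The coverage requirement is applied to methylated
calls as well, so sites without data are never classified by default
ipdR values. Ties at the thresholds go against the unmethylated call
(strict `<`) and in favor of the methylated call (`>=`).

Two points were genuinely open and are decided here: the two strands are
*pooled* before the trimmed mean rather than averaged per strand (the
pooled estimator uses all evidence symmetrically), and the background base
set excludes only the footprints of the motif under analysis, not other
motifs' sites (which would require joint knowledge of all motifs and
changes the estimate negligibly at realistic motif densities).
Non-palindromic (Type I/IIG/III) motifs are methylated on one strand only;
they are scanned and reported but excluded from the unmethylated-site
statistics, which require double-strand evidence.

```{r thresholds}
threshold_set(3.0, 1.0)[c("under_thr", "meth_thr")]
```

## Motif model

Motifs are IUPAC strings with a 0-based methylatable-base offset and a
modification type. Palindromy is decided under IUPAC complementation
(R/Y, S/S, W/W, K/M, B/V, D/H, N/N), so RAATTY is palindromic. Scanning
is exhaustive on both strands with overlapping hits reported; genome `N`
(including masked ambiguity codes) matches no motif symbol. Structural
classification follows RM-system architecture: an internal run of three
or more Ns makes a bipartite Type I motif (known Type I spacers are
longer, so 3 is safely inclusive); palindromic double-strand motifs are
Type II; otherwise up to 5 *specific* (non-N) positions suggests Type
III and 6 or more Type IIG — degenerate symbols count as specific
positions, which is why RAATTY behaves as a 6-position motif. Circular
genomes are scanned linearly; an instance spanning the origin junction
would be missed, which avoids double counting at the cost of at most one
instance per replicon.

## Enrichment statistics

Gene regulatory regions are defined as 100 bp upstream to 50 bp
downstream of each CDS start, strand-aware and clipped at contig edges.
"In a region" means footprint overlap, the least arbitrary choice for
4–11 bp motifs against 150 bp regions.

*Motifs as such*: the in-region fraction of instances is compared with
the mean over 1000 random placements matched per instance for length and
exact base composition (composition classes are precomputed over all
genome windows; sampling is with replacement across draws). *Unmethylated
motifs*: their in-region fraction is compared with that of methylated
instances. Both comparisons report a fold and a two-sided Fisher exact
p-value; for the resampling test the Fisher control row pools all random
placements. Per-COG-letter tests repeat the unmethylated comparison on
regions restricted to each functional category (flagged at p < 0.01), and
the TFBS test swaps regulatory regions for supplied binding-site
intervals (flagged at p < 0.05). Significance flags additionally require
the observed fraction to exceed the background, so a depleted category is
never flagged as enriched.

## Clusters of unmethylated sites

A cluster is a run of at least 3 unmethylated calls, consecutive in the
position-ordered instance list, with each start-to-start gap strictly
below the genome-wide mean inter-motif distance; ambiguous or
low-coverage calls break runs. The null distribution redraws which `n` of
the contig's `l` instances are unmethylated (10,000 iterations, sampling
without replacement), keeps all real positions, and re-applies the full
spatial criterion; an iteration counts as a success when any run of at
least the observed size `k` appears. The p-value uses the add-one
Monte-Carlo estimator `(1 + successes) / (1 + iterations)`, so it is
never exactly zero, and clusters are significant at p <= 0.01. Testing
runs of size `>= k` (rather than `>= 3`) makes the reported p answer "how
surprising is a run this large", and is the conservative reading of an
ambiguous prescription. Equally spaced instances never cluster under the
strict gap rule; this boundary case is asserted in the tests.

## The non-coding (replication origin) scan

Non-coding regions are the complement of CDS intervals, with RNA genes
also removed. For each region the local motif density (motifs/bp) is
estimated from up to 100 flanking non-coding regions (up to 50 per side
by region order; fewer when the contig runs out, flagged); the expected
count is `region length x density` and the raw p-value the upper binomial
tail `P(X >= observed)` with size = region length and probability =
density. Bonferroni correction uses the number of non-coding regions;
regions pass below 1e-5. The published formula for this test passes an
expected *count* where the binomial needs a *probability* and computes
the strictly-greater tail; both are treated as typographical (the
documented default computes `P(X >= obs)` with the density as the
probability), and `noncoding_tail = "gt"` switches to the
strictly-greater reading. Density profiles for origin-of-replication
figures count instances in 500 bp windows at 50 bp steps across 50 kb —
991 windows when unclipped.

## Cross-genome conservation

Ortholog candidacy uses the bitscore-ratio similarity score
`100 * bitscore(hit) / bitscore(self)`, orthologous at score >= 35
(inclusive); an MTase is conserved in a taxon when strictly more than 50%
of its species carry an ortholog. Reciprocal best hits require a unique
best subject in both directions, with ties excluded. Unmethylated sites
are conserved between genomes when both flanking genes (nearest gene on
each side) map to the other site's flanking genes by RBH, in either order
so that strand flips do not break conservation. Orphan MTase families are
built per modification group (m6A vs m4C/m5C combined) by agglomerative
clustering of pairwise protein identities; "minimum linkage at 0.35" is
read as requiring the *minimum* within-family identity to stay at or
above 0.35 (complete linkage on `1 - identity` cut at 0.65), with
conventional single linkage available by argument. Clusters are then
subdivided by identical canonical motif and shared taxon. Bitscore tables
and identity matrices are inputs: computing them is an alignment
problem, delegated to whatever search tool produced them.

## The synthetic methylome generator

The generator emulates the data-generating assumptions of kinetic
methylome sequencing so that each stage is testable against known truth:

* ipdR is lognormal, parameterized by its median so presets are
  interpretable: median 1.0 at unmethylated and background positions and
  4.0 / 3.0 / 1.5 at methylated bases for m6A / m4C / m5C, reflecting the
  relative kinetic signal of the three marks. The lognormal gives
  positive support and right skew. `sigma` (default 0.25) is per-read
  scale; since a position's ipdR is an aggregate over its reads, the
  per-position scale is `sigma / sqrt(coverage)`.
* coverage is Poisson (default mean 60/strand) and independent of
  methylation state by construction, which makes the coverage-parity
  diagnostic in `call_summary()` a real check rather than a tautology.
* `plant_methylome()` first scrubs natural occurrences of the motif
  (point mutations at the methylatable base) and then plants exactly the
  requested instance count, so the truth table is exact; planted
  unmethylated sites go into regulatory regions at a configurable
  fraction (default 0.6), or entirely upstream of one COG letter's genes;
  an optional cluster of extra instances in one intergenic region
  emulates a replication-origin locus.

Default study conditions: 200 kb genomes at GC 0.5, 150 genes of
300–1500 bp with >=150 bp intergenic gaps, 500 GATC instances of which 20
are unmethylated (the `orphan_regulatory` preset); the `ori_cluster`
preset plants 400 ATCGAT instances (a 1/500 bp background) plus 20 in one
600 bp intergenic region. These sizes keep a full scenario under a few
seconds while giving every test comfortable statistical room; the
acceptance checks run 20 scenario seeds per criterion.

What the generator does *not* emulate: real genome composition and repeat
structure, read-level alignment artefacts, hemimethylation during
replication, context-dependent kinetic variation, and MTase competition
at partially protected sites. Passing the recovery tests therefore shows
the statistical machinery is correct under the stated model, not that the
thresholds are optimal for any particular organism.

## Numerical choices and degenerate inputs

* Trim count for the central 60%: `floor(0.2 n)` per end (rounding was
  unspecified; floor keeps at least 60% of the data).
* A motif average at or below the background average yields degenerate
  thresholds; the threshold set is flagged and a warning raised rather
  than silently calling everything unmethylated.
* Monte-Carlo p-values use the add-one estimator; exact enumeration
  oracles in the test-suite confirm agreement within three Monte-Carlo
  standard errors for all configurations with `l <= 12`.
* Fisher tests are two-sided throughout (the conservative default).
* Non-coding regions with zero flanking density are untestable and
  flagged, never significant.
* Empty call sets: enrichment against zero methylated calls is an error
  (no background exists); zero unmethylated calls give fold 0, not NA.

## Limitations

Single-strand (Type I/IIG/III) motifs are reported but not statistically
analysed for unmethylated sites — the double-strand evidence rule does
not apply to them. Near-palindromic motif pairs (e.g. GGATG/CATCC) are
likewise excluded from calling. The RM-gene tables, bitscore tables and
TFBS intervals are inputs; this package deliberately contains no database
search. Identifying a flagged non-coding cluster *as* the replication
origin remains an annotation statement about the anchor gene, not a
computation.
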