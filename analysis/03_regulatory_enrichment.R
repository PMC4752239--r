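#!/usr/bin/env Rscript

# Stage 3: enrichment of motifs and unmethylated sites in gene regulatory
# regions (100 bp upstream to 50 bp downstream of CDS starts). Tests
# (a) whether motifs as such concentrate in regulatory regions, against
# 1000 composition-matched random placements, and (b) whether
# unmethylated motifs concentrate there relative to methylated ones,
# overall and per COG functional category.

library(prokmethylome)

dir <- "results/scenarios/orphan_regulatory"
genome <- read_genome_fasta(file.path(dir, "genome.fasta"))
genes <- read_gff3(file.path(dir, "genes.gff3"))
calls <- read.delim(file.path(dir, "calls.tsv"))
cfg <- pipeline_config()
regions <- define_regulatory_regions(genes, genome, cfg)

inst <- calls[, c("contig_id", "start", "end", "strand_of_match",
                  "meth_pos_fwd", "meth_pos_rev", "seq")]
e_motif <- motif_region_enrichment(inst, regions, genome, cfg, seed = 11)
cat(sprintf(
  "All motifs in regulatory regions: %.1f%% vs %.1f%% background (fold %.2f, Fisher p = %.3g)\n",
  100 * e_motif$observed_fraction, 100 * e_motif$background_fraction,
  e_motif$fold, e_motif$p_value))

e_un <- unmethylated_region_enrichment(calls, regions)
cat(sprintf(
  "Unmethylated motifs in regulatory regions: %d/%d (%.0f%%) vs %.1f%% of methylated (fold %.1f, Fisher p = %.3g)\n",
  e_un$n_in, e_un$n_total, 100 * e_un$observed_fraction,
  100 * e_un$background_fraction, e_un$fold, e_un$p_value))

cog <- cog_category_enrichment(calls, regions)
print(cog, row.names = FALSE)

enr <- data.frame(
  test = c("all_motifs_resampling", "unmethylated_vs_methylated"),
  n_in = c(e_motif$n_in, e_un$n_in),
  n_total = c(e_motif$n_total, e_un$n_total),
  observed_fraction = c(e_motif$observed_fraction, e_un$observed_fraction),
  background_fraction = c(e_motif$background_fraction,
                          e_un$background_fraction),
  fold = c(e_motif$fold, e_un$fold),
  p_value = c(e_motif$p_value, e_un$p_value))
write.table(enr, "results/regulatory_enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cog, "results/cog_enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/regulatory_enrichment.tsv and results/cog_enrichment.tsv\n")
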