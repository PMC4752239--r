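#!/usr/bin/env Rscript

# Stage 5: motif clusters in non-coding regions -- the replication-origin
# signature. Every non-coding region is tested against a binomial null
# whose rate is the local motif density over the 100 flanking non-coding
# regions, Bonferroni-corrected, significant below 1e-5. A 500 bp /
# 50 bp-step density profile across 50 kb around the detected cluster is
# written for plotting.

library(prokmethylome)

dir <- "results/scenarios/ori_cluster"
genome <- read_genome_fasta(file.path(dir, "genome.fasta"))
genes <- read_gff3(file.path(dir, "genes.gff3"))
motif <- read_motif_table(file.path(dir, "motifs.tsv"))[[1]]
cfg <- pipeline_config()

inst <- find_motif_instances(genome, motif)
noncoding <- extract_noncoding_regions(genes, genome)
cat(sprintf("%d %s instances; %d non-coding regions\n", nrow(inst),
            motif$pattern, nrow(noncoding)))

scan <- noncoding_enrichment_scan(noncoding, inst, cfg)
sig <- scan[scan$significant, , drop = FALSE]
cat(sprintf("%d region(s) significant at Bonferroni p < %g:\n",
            nrow(sig), cfg$noncoding_alpha))
print(sig[, c("start", "end", "observed", "expected", "fold",
              "p_bonferroni")], row.names = FALSE)

write.table(scan, "results/noncoding_scan.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

if (nrow(sig)) {
  # anchor the density profile on the start of the gene nearest the
  # cluster, as for a replication-origin locus
  mid <- (sig$start[1] + sig$end[1]) %/% 2
  nearest <- genes[which.min(abs(genes$start - mid)), ]
  prof <- density_profile(nchar(genome[[1]]), inst, nearest$start - 1L, cfg)
  write.table(prof, "results/ori_density_profile.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf(
    "Density profile around %s (start %d): %d windows, max %d motifs/500bp at offset %d\n",
    nearest$gene_id, nearest$start, nrow(prof), max(prof$count),
    prof$window_start[which.max(prof$count)] - (nearest$start - 1L)))
}
cat("\nWrote results/noncoding_scan.tsv and results/ori_density_profile.tsv\n")
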