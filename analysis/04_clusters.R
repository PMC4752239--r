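#!/usr/bin/env Rscript

# Stage 4: clusters of adjacent unmethylated sites. A cluster is >= 3
# consecutive unmethylated motifs with every gap below the genome-wide
# mean inter-motif distance; significance comes from a 10,000-iteration
# permutation null that redraws which instances are unmethylated while
# keeping all real positions.

library(prokmethylome)

dir <- "results/scenarios/orphan_regulatory"
calls <- read.delim(file.path(dir, "calls.tsv"))
cfg <- pipeline_config()

gap <- mean_intermotif_distance(calls)
cat(sprintf("Genome-wide mean inter-motif distance: %.1f bp\n", gap[[1]]))

clusters <- unmethylated_cluster_analysis(calls, gap, cfg, seed = 17)
if (nrow(clusters)) {
  cat(sprintf("%d cluster(s) of adjacent unmethylated sites:\n",
              nrow(clusters)))
  print(clusters[, c("contig_id", "start", "end", "k", "span", "p_value",
                     "significant")], row.names = FALSE)
} else {
  cat("No run of >= 3 adjacent unmethylated sites in this methylome",
      "(with 20 unmethylated sites scattered over 500 instances, runs of",
      "3 are rare by chance; a negative result here is expected).\n")
}
write.table(clusters, "results/unmethylated_clusters.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/unmethylated_clusters.tsv\n")
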