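#!/usr/bin/env Rscript

# Stage 1: generate the synthetic methylomes all later stages analyse.
# Four scenarios with known ground truth are written under
# results/scenarios/: an orphan MTase with planted unmethylated sites in
# regulatory regions, an RM-system methylome (fully methylated), a
# replication-origin motif cluster, and a weak-signal m5C methylome.

library(prokmethylome)

seed <- 1L
out_root <- "results/scenarios"

for (preset in c("orphan_regulatory", "rm_system", "ori_cluster",
                 "m5c_low_signal")) {
  dir <- file.path(out_root, preset)
  sc <- build_scenario(preset, seed = seed, dir = dir)
  n_un <- sum(sc$truth$state == "unmethylated")
  cat(sprintf(
    "%-18s motif %-7s instances %4d unmethylated %2d ori-planted %2d\n",
    preset, sc$motif$pattern, nrow(sc$truth), n_un, sum(sc$truth$ori)))
}

cat("\nScenario inputs (FASTA, GFF3, kinetics CSV, motif TSV) and truth",
    "tables written under", out_root, "\n")
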