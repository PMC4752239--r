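#!/usr/bin/env Rscript

# Stage 6: cross-genome conservation analyses, demonstrated on synthetic
# stand-ins. Two "strains" are emulated by the simulated genome and a
# renamed copy of its annotation, with synthetic all-vs-all bitscore
# tables (clear self-best structure); the orphan-family step runs on a
# synthetic pairwise identity matrix with two planted families. These
# tables play the role the BLAST outputs play on real data and are not
# equivalent to a database search.

library(prokmethylome)

dir <- "results/scenarios/orphan_regulatory"
genes_a <- read_gff3(file.path(dir, "genes.gff3"))
calls_a <- read.delim(file.path(dir, "calls.tsv"))

genes_b <- genes_a
genes_b$gene_id <- sub("^gene", "strainB_gene", genes_a$gene_id)
calls_b <- calls_a

## Reciprocal best hits from synthetic bitscore tables: each gene's true
## ortholog scores 500, everything else a low off-target score.
mk_scores <- function(q_ids, s_ids) {
  df <- expand.grid(query = q_ids, subject = s_ids,
                    stringsAsFactors = FALSE)
  df$bitscore <- ifelse(sub(".*gene", "", df$query) ==
                          sub(".*gene", "", df$subject), 500, 40)
  df
}
rbh <- reciprocal_best_hits(mk_scores(genes_a$gene_id, genes_b$gene_id),
                            mk_scores(genes_b$gene_id, genes_a$gene_id))
cat(sprintf("Reciprocal best hits: %d of %d genes paired\n", length(rbh),
            nrow(genes_a)))

## Conserved unmethylated sites between the two strains
pairs <- conserved_unmethylated_sites(calls_a, calls_b, genes_a, genes_b,
                                      rbh)
n_un <- sum(calls_a$state == "unmethylated")
cat(sprintf("Conserved unmethylated sites: %d pairs from %d sites\n",
            nrow(pairs), n_un))
write.table(pairs, "results/conserved_unmethylated_sites.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## Ortholog scoring and taxon-level conservation of an MTase
score <- similarity_score(175, 500)
cat(sprintf("Example similarity score 100*175/500 = %.0f (ortholog: %s)\n",
            as.numeric(score), attr(score, "ortholog")))
taxonomy <- data.frame(species = sprintf("sp%02d", 1:20), genus = "SynGen",
                       stringsAsFactors = FALSE)
hits <- data.frame(species = sprintf("sp%02d", 1:13), similarity = 62)
cons <- conservation_fraction(hits, taxonomy, "genus", "SynGen")
cat(sprintf("MTase orthologs in %d/%d genus species (%.0f%%): conserved = %s\n",
            cons$n_species_with_ortholog, cons$n_species_total,
            100 * cons$fraction, cons$conserved))

## Orphan MTase families from a synthetic identity matrix: two planted
## blocks (Dam-like m6A family; an m4C family) plus one singleton.
ids <- c("dam1", "dam2", "dam3", "hal1", "hal2", "solo1")
sim <- matrix(0.12, 6, 6, dimnames = list(ids, ids))
sim[1:3, 1:3] <- 0.72
sim[4:5, 4:5] <- 0.55
diag(sim) <- 1
fam <- cluster_orphan_families(
  sim,
  mod_types = setNames(c("m6A", "m6A", "m6A", "m4C", "m4C", "m6A"), ids),
  motifs = setNames(c("GATC", "GATC", "GATC", "CATG", "CATG", "TTAA"), ids),
  taxa = setNames(c(rep("Gammaproteobacteria", 3), rep("Haloarchaea", 2),
                    "Actinobacteria"), ids))
print(fam, row.names = FALSE)
write.table(fam, "results/orphan_families.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/conserved_unmethylated_sites.tsv and results/orphan_families.tsv\n")
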