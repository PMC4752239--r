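test_that("similarity scores are bitscore ratios with an inclusive
           ortholog threshold at 35", {
  s <- similarity_score(70, 200)
  expect_equal(as.numeric(s), 35)
  expect_true(attr(s, "ortholog"))
  expect_equal(as.numeric(similarity_score(100, 100)), 100)
  s2 <- similarity_score(69.9, 200)
  expect_false(attr(s2, "ortholog"))
  s3 <- similarity_score(200, 100)
  expect_equal(as.numeric(s3), 200)
  expect_true(attr(s3, "anomalous"))
  expect_error(similarity_score(10, 0), "> 0")
})

test_that("conservation requires orthologs in strictly more than half the
           species", {
  tax <- data.frame(species = paste0("sp", 1:10), genus = "G",
                    stringsAsFactors = FALSE)
  hits <- data.frame(species = paste0("sp", 1:6), similarity = 80)
  cc <- conservation_fraction(hits, tax, "genus", "G")
  expect_true(cc$conserved)
  expect_equal(cc$n_species_with_ortholog, 6)
  # exactly half is not conserved
  cc5 <- conservation_fraction(hits[1:5, ], tax, "genus", "G")
  expect_false(cc5$conserved)
  # species counted once regardless of hit multiplicity
  cc_dup <- conservation_fraction(rbind(hits[1:5, ], hits[1:5, ]), tax,
                                  "genus", "G")
  expect_equal(cc_dup$n_species_with_ortholog, 5)
  # sub-threshold similarities do not count
  weak <- data.frame(species = paste0("sp", 1:9), similarity = 34.9)
  expect_equal(conservation_fraction(weak, tax, "genus",
                                     "G")$n_species_with_ortholog, 0)
  # the 121-of-156 case is conserved (78%)
  tax_big <- data.frame(species = paste0("h", 1:156), class = "Halo",
                        stringsAsFactors = FALSE)
  hits_big <- data.frame(species = paste0("h", 1:121), similarity = 50)
  cc_big <- conservation_fraction(hits_big, tax_big, "class", "Halo")
  expect_true(cc_big$conserved)
  expect_equal(round(100 * cc_big$fraction), 78)
  expect_error(conservation_fraction(hits, tax, "genus", "NoSuch"),
               "no species")
})

test_that("reciprocal best hits form an injective matching and drop ties", {
  ab <- data.frame(query = c("a1", "a1", "a2", "a2"),
                   subject = c("b1", "b2", "b1", "b2"),
                   bitscore = c(100, 20, 30, 90), stringsAsFactors = FALSE)
  ba <- data.frame(query = c("b1", "b1", "b2", "b2"),
                   subject = c("a1", "a2", "a1", "a2"),
                   bitscore = c(95, 25, 10, 88), stringsAsFactors = FALSE)
  rbh <- reciprocal_best_hits(ab, ba)
  expect_identical(rbh, c(a1 = "b1", a2 = "b2"))

  # tie for best excludes the query
  ab_tie <- ab
  ab_tie$bitscore[1:2] <- 50
  rbh2 <- reciprocal_best_hits(ab_tie, ba)
  expect_false("a1" %in% names(rbh2))

  # random tables vs exhaustive oracle
  set.seed(37)
  for (i in 1:15) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    ab <- expand.grid(query = paste0("a", 1:na),
                      subject = paste0("b", 1:nb),
                      stringsAsFactors = FALSE)
    ab$bitscore <- sample(100, nrow(ab))
    ba <- expand.grid(query = paste0("b", 1:nb),
                      subject = paste0("a", 1:na),
                      stringsAsFactors = FALSE)
    ba$bitscore <- sample(100, nrow(ba))
    rbh <- reciprocal_best_hits(ab, ba)
    # oracle: check every pair by direct maxima
    for (a in paste0("a", 1:na)) {
      sa <- ab[ab$query == a, ]
      best_b <- sa$subject[which.max(sa$bitscore)]
      sb <- ba[ba$query == best_b, ]
      best_a <- sb$subject[which.max(sb$bitscore)]
      if (identical(best_a, a)) {
        expect_identical(unname(rbh[a]), best_b)
      } else {
        expect_false(a %in% names(rbh))
      }
    }
    expect_false(anyDuplicated(rbh) > 0)  # injective
  }
})

test_that("unmethylated sites pair across genomes when flanking genes are
           reciprocal best hits", {
  genes <- data.frame(contig_id = "c1",
                      start = c(1001L, 3001L, 5001L),
                      end = c(2000L, 4000L, 6000L), strand = "+",
                      feature_type = "CDS",
                      gene_id = c("a1", "a2", "a3"), product = NA,
                      cog_letter = NA, stringsAsFactors = FALSE)
  genesB <- genes
  genesB$gene_id <- c("b1", "b2", "b3")
  calls <- make_calls(starts = c(2200L, 4200L),
                      states = c("unmethylated", "methylated"))
  rbh <- c(a1 = "b1", a2 = "b2", a3 = "b3")
  callsB <- calls
  pairs <- conserved_unmethylated_sites(calls, callsB, genes, genesB, rbh)
  expect_equal(nrow(pairs), 1)   # only the unmethylated site pairs
  expect_equal(pairs$start_a, 2200L)
  expect_false(pairs$single_flank)

  # shuffled gene labels break all pairs
  rbh_shuffled <- c(a1 = "b3", a2 = "b1", a3 = "b2")
  expect_equal(nrow(conserved_unmethylated_sites(calls, callsB, genes,
                                                 genesB, rbh_shuffled)), 0)

  # strand flip: flanking genes in reversed order still pair
  genesB_flip <- genesB
  genesB_flip$gene_id <- c("b2", "b1", "b3")
  rbh2 <- c(a1 = "b1", a2 = "b2")
  pairs_flip <- conserved_unmethylated_sites(calls, callsB, genes,
                                             genesB_flip, rbh2)
  expect_equal(nrow(pairs_flip), 1)
})

test_that("orphan families respect the identity cutoff, modification
           grouping and motif/taxon subdivision", {
  ids <- c("m1", "m2")
  sim <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(ids, ids))
  fam <- cluster_orphan_families(
    sim, mod_types = c(m1 = "m6A", m2 = "m6A"),
    motifs = c(m1 = "GATC", m2 = "GATC"),
    taxa = c(m1 = "Gammaproteobacteria", m2 = "Gammaproteobacteria"))
  expect_equal(length(unique(fam$family)), 1)
  expect_false(any(fam$singleton))

  sim_low <- matrix(c(1, 0.30, 0.30, 1), 2, dimnames = list(ids, ids))
  fam_low <- cluster_orphan_families(
    sim_low, mod_types = c(m1 = "m6A", m2 = "m6A"),
    motifs = c(m1 = "GATC", m2 = "GATC"),
    taxa = c(m1 = "G", m2 = "G"))
  expect_equal(length(unique(fam_low$family)), 2)
  expect_true(all(fam_low$singleton))

  # different modification groups never share a family
  fam_mod <- cluster_orphan_families(
    sim, mod_types = c(m1 = "m6A", m2 = "m4C"),
    motifs = c(m1 = "GATC", m2 = "GATC"), taxa = c(m1 = "G", m2 = "G"))
  expect_equal(length(unique(fam_mod$family)), 2)

  # two planted 3-member blocks are recovered exactly, order-invariantly
  ids6 <- paste0("m", 1:6)
  sim6 <- matrix(0.1, 6, 6, dimnames = list(ids6, ids6))
  sim6[1:3, 1:3] <- 0.8
  sim6[4:6, 4:6] <- 0.7
  diag(sim6) <- 1
  args <- list(mod_types = setNames(rep("m6A", 6), ids6),
               motifs = setNames(rep("GATC", 6), ids6),
               taxa = setNames(rep("G", 6), ids6))
  fam6 <- do.call(cluster_orphan_families, c(list(sim6), args))
  expect_equal(length(unique(fam6$family)), 2)
  expect_equal(length(unique(fam6$family[fam6$mtase_id %in% ids6[1:3]])), 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  fam6p <- do.call(cluster_orphan_families,
                   c(list(sim6[perm, perm]), args))
  expect_identical(fam6$mtase_id, fam6p$mtase_id)
  expect_identical(fam6$family == fam6$family[1],
                   fam6p$family == fam6p$family[1])

  expect_error(cluster_orphan_families(
    matrix(c(1, 0.2, 0.5, 1), 2, dimnames = list(ids, ids)),
    mod_types = c(m1 = "m6A", m2 = "m6A"),
    motifs = c(m1 = "GATC", m2 = "GATC"), taxa = c(m1 = "G", m2 = "G")),
    "symmetric")
})
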