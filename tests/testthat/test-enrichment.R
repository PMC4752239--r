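make_genes <- function(starts, ends, strands, contig = "c1",
                       cogs = NA_character_) {
  data.frame(contig_id = contig, start = starts, end = ends,
             strand = strands, feature_type = "CDS",
             gene_id = paste0("g", seq_along(starts)),
             product = NA_character_, cog_letter = cogs,
             stringsAsFactors = FALSE)
}

test_that("regulatory regions span -100/+50 around the CDS start, by
           strand, clipped at contig edges", {
  genome <- c(c1 = strrep("A", 1000))
  r <- define_regulatory_regions(make_genes(201, 800, "+"), genome)
  expect_equal(c(r$start, r$end), c(100L, 250L))
  r <- define_regulatory_regions(make_genes(201, 800, "-"), genome)
  expect_equal(c(r$start, r$end), c(750L, 900L))
  r <- define_regulatory_regions(make_genes(1, 300, "+"), genome)
  expect_equal(c(r$start, r$end), c(0L, 50L))
  # one interval per CDS, overlaps retained
  g2 <- make_genes(c(201, 251), c(800, 900), c("+", "+"))
  expect_equal(nrow(define_regulatory_regions(g2, genome)), 2)
})

test_that("non-coding regions are the complement of CDS and RNA genes", {
  genome <- c(c1 = strrep("A", 500))
  genes <- make_genes(c(101, 301), c(200, 400), c("+", "-"))
  nc <- extract_noncoding_regions(genes, genome)
  expect_equal(nc$start, c(0L, 200L, 400L))
  expect_equal(nc$end, c(100L, 300L, 500L))
  # fully coding contig
  expect_equal(nrow(extract_noncoding_regions(make_genes(1, 500, "+"),
                                              genome)), 0)
  # RNA genes are removed from the non-coding set too
  genes2 <- rbind(genes,
                  data.frame(contig_id = "c1", start = 451, end = 460,
                             strand = "+", feature_type = "RNA",
                             gene_id = "r1", product = NA, cog_letter = NA))
  nc2 <- extract_noncoding_regions(genes2, genome)
  expect_equal(nc2$end[nc2$start == 400], 450L)
  # per-base labelling oracle on random annotations
  set.seed(8)
  for (i in 1:10) {
    s <- sort(sample.int(480, 4))
    g <- make_genes(s, pmin(s + sample(5:40, 4), 500L),
                    rep(c("+", "-"), 2))
    nc <- extract_noncoding_regions(g, genome)
    lab <- rep(TRUE, 500)
    for (j in 1:4) lab[g$start[j]:g$end[j]] <- FALSE
    from_regions <- rep(FALSE, 500)
    for (j in seq_len(nrow(nc)))
      from_regions[(nc$start[j] + 1L):nc$end[j]] <- TRUE
    expect_identical(from_regions, lab)
  }
})

test_that("composition-matched sampling preserves base multisets and is
           deterministic under seed", {
  set.seed(2)
  seq <- random_genome_seq(2000)
  inst <- find_motif_instances(c(c1 = seq), motif_spec("GANC", 1L, "m6A"))
  inst <- inst[inst$strand_of_match == "+", ][1:5, ]
  samp <- sample_composition_matched_sites(seq, inst$seq, n_sets = 50,
                                           seed = 99)
  key_of <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  for (i in seq_len(nrow(inst))) {
    wins <- substring(seq, samp[i, ] + 1L, samp[i, ] + 4L)
    expect_true(all(vapply(wins, key_of, "") == key_of(inst$seq[i])))
  }
  samp2 <- sample_composition_matched_sites(seq, inst$seq, n_sets = 50,
                                            seed = 99)
  expect_identical(samp, samp2)
  expect_error(
    sample_composition_matched_sites("ATATATAT", "GGGG", 10, 1),
    "composition")
})

test_that("mean sampled in-region fraction matches the analytic
           expectation under uniform placement", {
  set.seed(31)
  seq <- random_genome_seq(20000)
  regions <- data.frame(contig_id = "c1",
                        start = seq(1000L, 17000L, by = 4000L),
                        end = seq(1000L, 17000L, by = 4000L) + 500L)
  inst <- find_motif_instances(c(c1 = seq), motif_spec("GATC", 1L, "m6A"))
  e <- motif_region_enrichment(inst, regions, c(c1 = seq),
                               pipeline_config(n_resamplings = 400L),
                               seed = 5)
  # GATC composition is uniform over the genome, so the background equals
  # the fraction of 4-bp windows overlapping a region
  n_win <- 20000 - 4 + 1
  hit <- rep(FALSE, n_win)
  for (j in seq_len(nrow(regions))) {
    lo <- max(regions$start[j] - 3L, 0L)
    hi <- min(regions$end[j] - 1L, n_win - 1L)
    hit[(lo + 1):(hi + 1)] <- TRUE
  }
  p_exp <- mean(hit)
  se <- sqrt(p_exp * (1 - p_exp) / (nrow(inst) * 400))
  expect_lt(abs(e$background_fraction - p_exp), 3 * se + 0.005)
  expect_equal(e$fold, e$observed_fraction / e$background_fraction)
})

test_that("unmethylated-site enrichment reproduces printed folds and the
           exact Fisher example", {
  # all unmethylated in regions vs 50% methylated => fold 2
  regions <- data.frame(contig_id = "c1", start = 0L, end = 1000L)
  calls <- make_calls(starts = c(1:4 * 100L, 2000L, 2100L, 500L, 600L),
                      states = c(rep("methylated", 6),
                                 rep("unmethylated", 2)))
  e <- unmethylated_region_enrichment(calls, regions)
  expect_equal(e$observed_fraction, 1)
  expect_equal(e$background_fraction, 4 / 6)
  expect_equal(e$fold, 1.5)

  # table [[5,0],[0,5]]: two-sided Fisher p = 2/252
  calls <- make_calls(starts = c(1:5 * 10L, 2001L + 1:5 * 10L),
                      states = c(rep("unmethylated", 5),
                                 rep("methylated", 5)))
  e <- unmethylated_region_enrichment(calls,
    data.frame(contig_id = "c1", start = 0L, end = 1000L))
  expect_equal(e$p_value, 2 / 252, tolerance = 1e-10)

  # identical fractions => fold 1
  calls <- make_calls(starts = c(10L, 3000L, 20L, 3100L),
                      states = c("unmethylated", "unmethylated",
                                 "methylated", "methylated"))
  e <- unmethylated_region_enrichment(calls,
    data.frame(contig_id = "c1", start = 0L, end = 1000L))
  expect_equal(e$fold, 1)
  expect_error(
    unmethylated_region_enrichment(
      make_calls(starts = 10L, states = "unmethylated"), regions),
    "methylated")
})

test_that("Fisher p-values equal the hypergeometric summation oracle", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher(tab),
                 tolerance = 1e-10)
  }
})

test_that("COG-category tests flag only the letter carrying the planted
           signal", {
  sc <- build_scenario("cog_targeted", seed = 6)
  thr <- compute_thresholds(sc$track, sc$truth[, 1:7], sc$motif, sc$genome)
  calls <- call_instances(sc$track, sc$truth[, 1:7], thr)
  tab <- cog_category_enrichment(calls, sc$regions)
  expect_true(tab$significant[tab$cog_letter == "K"])
  expect_false(any(tab$significant[tab$cog_letter != "K"]))
  # no unmethylated sites => all folds zero
  all_meth <- calls
  all_meth$state[all_meth$state == "unmethylated"] <- "methylated"
  tab0 <- cog_category_enrichment(all_meth, sc$regions)
  expect_true(all(tab0$fold == 0))
  expect_false(any(tab0$significant))
})

test_that("TFBS overlap uses the same exact test with its own flag", {
  tfbs <- data.frame(contig_id = "c1", start = 0L, end = 1000L)
  calls <- make_calls(starts = c(1:5 * 10L, 2001L + 1:5 * 10L),
                      states = c(rep("unmethylated", 5),
                                 rep("methylated", 5)))
  e <- tfbs_overlap_enrichment(calls, tfbs)
  expect_equal(e$p_value, 2 / 252, tolerance = 1e-10)
  expect_true(e$significant)
  expect_error(tfbs_overlap_enrichment(calls, tfbs[0, ]), "empty")
})
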