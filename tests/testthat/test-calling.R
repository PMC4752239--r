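test_that("trimmed central mean drops the outer quantiles symmetrically", {
  expect_equal(trimmed_central_mean(1:10, 0.6), 5.5)
  expect_equal(trimmed_central_mean(c(5, 5, 5), 0.6), 5)
  expect_error(trimmed_central_mean(numeric(0)), "empty")
  set.seed(9)
  x <- runif(1000)
  drop <- floor(0.2 * 1000)
  oracle <- mean(sort(x)[(drop + 1):(1000 - drop)])
  expect_equal(trimmed_central_mean(x, 0.6), oracle, tolerance = 1e-12)
  # full fraction keeps everything
  expect_equal(trimmed_central_mean(x, 1), mean(x))
})

test_that("threshold formulas combine motif and background averages", {
  thr <- threshold_set(3.0, 1.0)
  expect_equal(thr$under_thr, 1.2)
  expect_equal(thr$meth_thr, 2.0)
  expect_false(thr$degenerate)
  expect_lt(thr$under_thr, thr$meth_thr)   # ordering when motif > background
  expect_warning(thr <- threshold_set(1.0, 1.0), "degenerate")
  expect_equal(thr$under_thr, 1.0)
  expect_equal(thr$meth_thr, 1.0)
})

test_that("thresholds recomputed from a simulated track match direct
           trimmed means", {
  sc <- build_scenario("orphan_regulatory", seed = 21)
  inst <- sc$truth[, c("contig_id", "start", "end", "strand_of_match",
                       "meth_pos_fwd", "meth_pos_rev", "seq")]
  thr <- compute_thresholds(sc$track, inst, sc$motif, sc$genome)
  # independent recomputation straight from the track arrays
  ch <- sc$track$data$contig1
  motif_vals <- c(ch[["+"]]$ipdR[inst$meth_pos_fwd + 1L],
                  ch[["-"]]$ipdR[inst$meth_pos_rev + 1L])
  bases <- strsplit(sc$genome[[1]], "")[[1]]
  fp <- logical(length(bases))
  for (i in seq_len(nrow(inst))) fp[(inst$start[i] + 1L):inst$end[i]] <- TRUE
  bg_vals <- c(ch[["+"]]$ipdR[bases == "A" & !fp],
               ch[["-"]]$ipdR[bases == "T" & !fp])
  slice_mean <- function(v) {
    v <- sort(v[!is.na(v)])
    d <- floor(0.2 * length(v))
    mean(v[(d + 1):(length(v) - d)])
  }
  expect_equal(thr$avg_motif_ipdR, slice_mean(motif_vals), tolerance = 1e-12)
  expect_equal(thr$avg_nonmotif_ipdR, slice_mean(bg_vals), tolerance = 1e-12)
  # m6A preset: background ~1, motif ~4 => under ~1.3, meth ~2.5
  expect_equal(thr$under_thr, 1.3, tolerance = 0.05)
  expect_equal(thr$meth_thr, 2.5, tolerance = 0.05)
})

test_that("instance calling applies the coverage and threshold rules", {
  thr <- list(under_thr = 1.2, meth_thr = 2.0)
  inst <- data.frame(contig_id = "c1", start = c(0L, 10L, 20L, 30L),
                     end = c(4L, 14L, 24L, 34L), strand_of_match = "+",
                     meth_pos_fwd = c(1L, 11L, 21L, 31L),
                     meth_pos_rev = c(2L, 12L, 22L, 32L),
                     seq = "GATC", stringsAsFactors = FALSE)
  tr <- make_track(40L,
    fwd = list(pos = c(2L, 12L, 22L, 32L), ipdR = c(1.0, 3.1, 19, 1.5),
               cov = c(30L, 30L, 19L, 30L)),
    rev = list(pos = c(3L, 13L, 23L, 33L), ipdR = c(1.1, 2.9, 19, 1.5),
               cov = c(30L, 30L, 50L, 30L)))
  calls <- call_instances(tr, inst, thr)
  expect_identical(calls$state,
                   c("unmethylated", "methylated", "low_coverage",
                     "ambiguous"))
  # positions absent from the track count as coverage 0
  tr2 <- make_track(40L)
  calls2 <- call_instances(tr2, inst, thr)
  expect_true(all(calls2$state == "low_coverage"))
  expect_true(all(calls2$cov_fwd == 0L))
  # non-palindromic (single-strand) motifs are refused
  inst$meth_pos_rev <- NA_integer_
  expect_error(call_instances(tr, inst, thr), "single-strand")
})

test_that("boundary ties go to methylated at the upper threshold and
           break unmethylated at the lower", {
  thr <- list(under_thr = 1.2, meth_thr = 2.0)
  inst <- data.frame(contig_id = "c1", start = 0L, end = 4L,
                     strand_of_match = "+", meth_pos_fwd = 1L,
                     meth_pos_rev = 2L, seq = "GATC",
                     stringsAsFactors = FALSE)
  at_under <- make_track(10L,
    fwd = list(pos = 2L, ipdR = 1.2, cov = 30L),
    rev = list(pos = 3L, ipdR = 1.0, cov = 30L))
  expect_identical(call_instances(at_under, inst, thr)$state, "ambiguous")
  at_meth <- make_track(10L,
    fwd = list(pos = 2L, ipdR = 2.0, cov = 30L),
    rev = list(pos = 3L, ipdR = 2.0, cov = 30L))
  expect_identical(call_instances(at_meth, inst, thr)$state, "methylated")
})

test_that("lowering ipdR never promotes an instance toward methylated", {
  thr <- list(under_thr = 1.3, meth_thr = 2.5)
  rank_of <- c(unmethylated = 1, ambiguous = 2, low_coverage = 2,
               methylated = 3)
  inst <- data.frame(contig_id = "c1", start = 0L, end = 4L,
                     strand_of_match = "+", meth_pos_fwd = 1L,
                     meth_pos_rev = 2L, seq = "GATC",
                     stringsAsFactors = FALSE)
  set.seed(13)
  for (i in 1:40) {
    ipd <- runif(2, 0.5, 4)
    tr <- make_track(10L,
      fwd = list(pos = 2L, ipdR = ipd[1], cov = 30L),
      rev = list(pos = 3L, ipdR = ipd[2], cov = 30L))
    s1 <- call_instances(tr, inst, thr)$state
    drop <- runif(1, 0, ipd[1] - 0.01)
    tr2 <- make_track(10L,
      fwd = list(pos = 2L, ipdR = ipd[1] - drop, cov = 30L),
      rev = list(pos = 3L, ipdR = ipd[2], cov = 30L))
    s2 <- call_instances(tr2, inst, thr)$state
    expect_lte(rank_of[[s2]], rank_of[[s1]])
  }
})

test_that("call summaries reproduce printed fractions and planted truth", {
  calls <- make_calls(starts = seq_len(17562) * 10L,
                      states = c(rep("methylated", 17544),
                                 rep("unmethylated", 18)))
  s <- call_summary(calls)
  expect_equal(round(s$pct_methylated, 1), 99.9)
  expect_equal(s$counts[["unmethylated"]], 18L)

  all_meth <- make_calls(starts = 1:50 * 10L, states = "methylated")
  expect_equal(call_summary(all_meth)$fractions[["unmethylated"]], 0)

  sc <- build_scenario("orphan_regulatory", seed = 4)
  thr <- compute_thresholds(sc$track, sc$truth[, 1:7], sc$motif, sc$genome)
  calls <- call_instances(sc$track, sc$truth[, 1:7], thr)
  s <- call_summary(calls)
  expect_equal(sum(s$counts), 500L)
  expect_equal(s$counts[["unmethylated"]],
               sum(sc$truth$state == "unmethylated"))
})
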