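# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, brute-force restatement of the quantity it
# checks, sharing no code with the package implementation path.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive per-position scan: 0-based starts where pattern matches seq on
# the forward strand; genome N matches nothing
oracle_scan <- function(seq, pattern) {
  sym <- strsplit(pattern, "")[[1]]
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases); L <- length(sym)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(bases[s + j] %in% IUPAC_ORACLE[[sym[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

oracle_revcomp <- function(pattern) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# two-sided Fisher p by hypergeometric point-probability summation
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper binomial tail P(X >= obs) by pmf summation
oracle_binom_tail <- function(obs, size, prob) {
  if (obs <= 0) return(1)
  sum(dbinom(obs:size, size, prob))
}

# exact cluster-null p: over all C(l, n) unmethylated-index subsets, the
# fraction containing a run of >= k list-consecutive indices whose real
# gaps are all < mean_gap
oracle_cluster_p <- function(positions, n, k, mean_gap) {
  l <- length(positions)
  subsets <- utils::combn(l, n)
  hit <- 0
  for (col in seq_len(ncol(subsets))) {
    samp <- subsets[, col]
    run <- 1; best <- 1
    for (j in seq_len(n - 1)) {
      if (samp[j + 1] == samp[j] + 1 &&
          positions[samp[j + 1]] - positions[samp[j]] < mean_gap) {
        run <- run + 1
      } else run <- 1
      best <- max(best, run)
    }
    if (best >= k) hit <- hit + 1
  }
  hit / ncol(subsets)
}

random_iupac_motif <- function(len = sample(4:8, 1)) {
  syms <- c(rep(c("A", "C", "G", "T"), 5), "R", "Y", "S", "W", "N")
  paste(sample(syms, len, replace = TRUE), collapse = "")
}

random_genome_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# build a call table directly (for tests of stages downstream of calling)
make_calls <- function(contig = "c1", starts, states, L = 4L,
                       cov = 30L, ipdR = 1) {
  data.frame(contig_id = contig, start = starts, end = starts + L,
             strand_of_match = "+", meth_pos_fwd = starts + 1L,
             meth_pos_rev = starts + 2L, seq = strrep("A", L),
             state = states, ipdR_fwd = ipdR, ipdR_rev = ipdR,
             cov_fwd = cov, cov_rev = cov, stringsAsFactors = FALSE)
}

# populate a track from explicit per-position values
make_track <- function(len, contig = "c1", fwd = NULL, rev = NULL) {
  tr <- kinetic_track(setNames(len, contig))
  if (!is.null(fwd))
    tr <- track_set(tr, contig, "+", fwd$pos, fwd$ipdR, fwd$cov)
  if (!is.null(rev))
    tr <- track_set(tr, contig, "-", rev$pos, rev$ipdR, rev$cov)
  tr
}
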