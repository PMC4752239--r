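#' Find clusters of adjacent unmethylated motifs
#'
#' A cluster is a maximal run of at least `cluster_min_size` consecutive
#' (in the position-ordered instance list) unmethylated calls in which
#' every successive start-to-start gap is strictly less than the
#' genome-wide mean inter-motif distance. Ambiguous and low-coverage calls
#' break runs, as does a gap at or above the mean.
#'
#' @param calls call table from [call_instances()] (ordered by position
#'   within contig).
#' @param mean_gap genome-wide mean inter-motif distance: a scalar, or a
#'   named per-contig vector as returned by [mean_intermotif_distance()].
#' @param cfg configuration list.
#' @return data.frame with one row per cluster: `contig_id, start, end,
#'   k, span, first_index, last_index, n, l` where `first_index`/
#'   `last_index` are row positions in the contig's ordered call table,
#'   `n` is the contig's unmethylated count and `l` its total instance
#'   count.
#' @export
find_unmethylated_clusters <- function(calls, mean_gap,
                                       cfg = pipeline_config()) {
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), k = integer(), span = integer(),
                      first_index = integer(), last_index = integer(),
                      n = integer(), l = integer(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  out <- list()
  for (contig in unique(calls$contig_id)) {
    df <- calls[calls$contig_id == contig, , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    gap <- if (length(mean_gap) > 1 || !is.null(names(mean_gap)))
      mean_gap[[contig]] else mean_gap
    u <- df$state == "unmethylated"
    m <- nrow(df)
    if (m < 2) next
    ok_pair <- u[-m] & u[-1] & (diff(df$start) < gap)
    grp <- cumsum(c(TRUE, !ok_pair))
    for (g in split(seq_len(m), grp)) {
      if (length(g) < cfg$cluster_min_size || !all(u[g])) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig, start = df$start[g[1]],
        end = df$end[g[length(g)]], k = length(g),
        span = df$start[g[length(g)]] - df$start[g[1]],
        first_index = g[1], last_index = g[length(g)],
        n = sum(u), l = m, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Longest qualifying run within a sorted index sample: sampled instances
# count as consecutive when their list indices differ by 1 and the real
# genomic gap between them is < mean_gap.
max_sampled_run <- function(samp, positions, mean_gap) {
  if (length(samp) < 2) return(length(samp))
  ok <- diff(samp) == 1L &
    (positions[samp[-1]] - positions[samp[-length(samp)]] < mean_gap)
  r <- rle(ok)
  best <- suppressWarnings(max(r$lengths[r$values]))
  if (!is.finite(best)) 1L else best + 1L
}

#' Permutation p-value for an unmethylated-site cluster
#'
#' The null keeps the real genomic positions of all `l` motif instances on
#' the contig and, in each iteration, draws which `n` of them are
#' unmethylated (sampling without replacement), then re-applies the full
#' cluster criterion. The p-value is the add-one Monte-Carlo estimate
#' `(1 + #iterations with a cluster of size >= k) / (1 + iters)`, so it is
#' never exactly zero. A cluster is significant at `p <= cluster_alpha`.
#'
#' @param positions sorted start positions of all motif instances on the
#'   contig.
#' @param n number of unmethylated instances on the contig.
#' @param k observed cluster size; an iteration succeeds when any run of
#'   size >= k exists.
#' @param mean_gap genome-wide mean inter-motif distance for the contig.
#' @param iters permutation iterations.
#' @param seed RNG seed.
#' @return the permutation p-value.
#' @export
cluster_permutation_pvalue <- function(positions, n, k, mean_gap,
                                       iters = 10000L, seed = 1L) {
  l <- length(positions)
  if (n > l) stop("n (unmethylated) cannot exceed l (total instances)")
  stopifnot(k >= 2, !is.unsorted(positions))
  succ <- with_seed(seed, {
    s <- 0L
    for (i in seq_len(iters)) {
      samp <- sort.int(sample.int(l, n))
      if (max_sampled_run(samp, positions, mean_gap) >= k) s <- s + 1L
    }
    s
  })
  (1 + succ) / (1 + iters)
}

#' Detect clusters and attach permutation p-values
#'
#' Convenience wrapper: runs [find_unmethylated_clusters()] and computes a
#' [cluster_permutation_pvalue()] for each cluster found.
#'
#' @inheritParams find_unmethylated_clusters
#' @param seed RNG seed (default `cfg$rng_seed`).
#' @return the cluster table with `p_value`, `n_permutations` and
#'   `significant` columns appended.
#' @export
unmethylated_cluster_analysis <- function(calls, mean_gap,
                                          cfg = pipeline_config(),
                                          seed = cfg$rng_seed) {
  cl <- find_unmethylated_clusters(calls, mean_gap, cfg)
  cl$p_value <- numeric(nrow(cl))
  cl$n_permutations <- rep(as.integer(cfg$n_permutations), nrow(cl))
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      contig <- cl$contig_id[i]
      df <- calls[calls$contig_id == contig, , drop = FALSE]
      pos <- sort(df$start)
      gap <- if (length(mean_gap) > 1 || !is.null(names(mean_gap)))
        mean_gap[[contig]] else mean_gap
      cl$p_value[i] <- cluster_permutation_pvalue(
        pos, cl$n[i], cl$k[i], gap, cfg$n_permutations, seed + i)
    }
  }
  cl$significant <- cl$p_value <= cfg$cluster_alpha
  cl
}
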