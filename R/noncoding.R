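# Motif clusters in non-coding regions: the replication-origin signature.
# Each non-coding region is tested against a binomial null whose success
# probability is the local motif density estimated from the flanking
# non-coding regions, with Bonferroni correction over the number of
# non-coding regions in the genome.

#' Local non-coding motif density around a region
#'
#' Density (motifs/bp) across up to `flank_regions` flanking non-coding
#' regions (up to half per side by region order, excluding the focal
#' region). When fewer are available all existing ones are used and the
#' result is flagged.
#'
#' @param region_index row index of the focal region within `noncoding`
#'   (regions of one contig, ordered by start).
#' @param noncoding non-coding region data.frame for one contig.
#' @param instances motif instance table.
#' @param flank_regions number of flanking regions to use (100).
#' @return density in motifs/bp, with attributes `flanking_short`
#'   (logical) and `flank_length` (total bp used).
#' @export
local_motif_density <- function(region_index, noncoding, instances,
                                flank_regions = 100L) {
  stopifnot(nrow(noncoding) >= 2, region_index >= 1,
            region_index <= nrow(noncoding))
  per_side <- flank_regions %/% 2L
  left <- seq_len(nrow(noncoding)) < region_index
  right <- seq_len(nrow(noncoding)) > region_index
  take <- c(utils::tail(which(left), per_side),
            utils::head(which(right), per_side))
  short <- length(take) < flank_regions
  flank <- noncoding[take, , drop = FALSE]
  total_len <- sum(flank$end - flank$start)
  if (total_len == 0) stop("zero flanking region length")
  n_motifs <- sum(footprint_overlaps(instances, flank))
  structure(n_motifs / total_len, flanking_short = short,
            flank_length = total_len)
}

#' Scan non-coding regions for motif clusters
#'
#' For each non-coding region, the expected motif count is
#' `region length x local density`; the raw p-value is the upper binomial
#' tail P(X >= observed) with size = region length and success probability
#' = local density (the strict P(X > observed) variant is available via
#' `cfg$noncoding_tail = "gt"`). P-values are Bonferroni-corrected by the
#' number of non-coding regions in the genome; regions are significant at
#' corrected p below `noncoding_alpha` (1e-5). Regions whose flanking
#' density is zero are untestable and flagged.
#'
#' @param noncoding non-coding regions from [extract_noncoding_regions()].
#' @param instances motif instance table.
#' @param cfg configuration list.
#' @return data.frame with one row per region: observed and expected
#'   counts, local density, fold, raw and corrected p-values,
#'   `significant` and `flagged` columns.
#' @export
noncoding_enrichment_scan <- function(noncoding, instances,
                                      cfg = pipeline_config()) {
  out <- list()
  for (contig in unique(noncoding$contig_id)) {
    nc <- noncoding[noncoding$contig_id == contig, , drop = FALSE]
    nc <- nc[order(nc$start), , drop = FALSE]
    ins <- instances[instances$contig_id == contig, , drop = FALSE]
    n_regions <- nrow(nc)
    if (n_regions < 2) next
    obs_all <- vapply(seq_len(n_regions), function(i)
      sum(footprint_overlaps(ins, nc[i, , drop = FALSE])), integer(1))
    for (i in seq_len(n_regions)) {
      len <- nc$end[i] - nc$start[i]
      dens <- local_motif_density(i, nc, ins, cfg$flank_regions)
      flagged <- attr(dens, "flanking_short")
      dens <- min(as.numeric(dens), 1)
      obs <- obs_all[i]
      expected <- len * dens
      if (dens == 0) {
        p_raw <- NA_real_
        flagged <- TRUE
      } else if (cfg$noncoding_tail == "ge") {
        p_raw <- stats::pbinom(obs - 1, size = len, prob = dens,
                               lower.tail = FALSE)
      } else {
        p_raw <- stats::pbinom(obs, size = len, prob = dens,
                               lower.tail = FALSE)
      }
      p_bonf <- if (is.na(p_raw)) NA_real_ else min(1, p_raw * n_regions)
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig, start = nc$start[i], end = nc$end[i],
        length = len, observed = obs, local_density = dens,
        expected = expected,
        fold = if (expected > 0) obs / expected else NA_real_,
        p_raw = p_raw, p_bonferroni = p_bonf,
        significant = !is.na(p_bonf) && p_bonf < cfg$noncoding_alpha,
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      observed = integer(), local_density = numeric(),
                      expected = numeric(), fold = numeric(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      significant = logical(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif density profile around an anchor position
#'
#' Counts motif instances (footprint overlap) in sliding windows of
#' `window_bp` with step `step_bp` across a `span_bp` region centered on
#' the anchor (a gene start or end near a motif cluster). Windows falling
#' outside the contig are clipped away; the unclipped window count is
#' `floor((span - window)/step) + 1`, i.e. 991 at the defaults.
#'
#' @param contig_length length of the contig.
#' @param instances motif instances on that contig.
#' @param anchor 0-based genome coordinate to center on.
#' @param cfg configuration list.
#' @return data.frame with `window_start` (0-based) and `count`.
#' @export
density_profile <- function(contig_length, instances, anchor,
                            cfg = pipeline_config()) {
  n_win <- (cfg$span_bp - cfg$window_bp) %/% cfg$step_bp + 1L
  starts <- anchor - cfg$span_bp %/% 2L + cfg$step_bp * (seq_len(n_win) - 1L)
  keep <- starts >= 0L & (starts + cfg$window_bp) <= contig_length
  starts <- starts[keep]
  counts <- integer(length(starts))
  if (length(starts) && nrow(instances)) {
    win <- IRanges::IRanges(starts + 1L, starts + cfg$window_bp)
    ins <- IRanges::IRanges(instances$start + 1L, instances$end)
    counts <- IRanges::countOverlaps(win, ins)
  }
  data.frame(window_start = starts, count = as.integer(counts))
}

# Nearest annotated gene on each side of an interval, by gene start order.
# Returns c(left_gene_id, right_gene_id); NA at contig edges.
flanking_gene_ids <- function(genes, contig, start0, end0) {
  g <- genes[genes$contig_id == contig, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  gs <- g$start - 1L
  left <- which(gs <= start0)
  right <- which(gs > start0)
  c(if (length(left)) g$gene_id[max(left)] else NA_character_,
    if (length(right)) g$gene_id[min(right)] else NA_character_)
}

#' Match significant non-coding motif clusters across two genomes
#'
#' Two significant regions are paired when their flanking genes are
#' reciprocal best hits between the genomes (either flanking-gene order,
#' to allow strand flips).
#'
#' @param statsA,statsB scan tables from [noncoding_enrichment_scan()].
#' @param genesA,genesB annotation data.frames of the two genomes.
#' @param rbh named character vector mapping genome-A gene ids to their
#'   reciprocal best hits in genome B (see [reciprocal_best_hits()]).
#' @return data.frame of conserved region pairs (coordinates in both
#'   genomes).
#' @export
match_clusters_across_genomes <- function(statsA, statsB, genesA, genesB,
                                          rbh) {
  sigA <- statsA[statsA$significant, , drop = FALSE]
  sigB <- statsB[statsB$significant, , drop = FALSE]
  empty <- data.frame(contig_a = character(), start_a = integer(),
                      end_a = integer(), contig_b = character(),
                      start_b = integer(), end_b = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sigA) || !nrow(sigB)) return(empty)
  flankB <- lapply(seq_len(nrow(sigB)), function(j)
    flanking_gene_ids(genesB, sigB$contig_id[j], sigB$start[j], sigB$end[j]))
  out <- list()
  for (i in seq_len(nrow(sigA))) {
    fa <- flanking_gene_ids(genesA, sigA$contig_id[i], sigA$start[i],
                            sigA$end[i])
    ma <- unname(rbh[fa])
    if (all(is.na(ma))) next
    for (j in seq_len(nrow(sigB))) {
      fb <- flankB[[j]]
      paired <- (identical(ma, fb)) ||
        (identical(ma, rev(fb))) ||
        (sum(!is.na(ma)) == 1 && stats::na.omit(ma)[1] %in% stats::na.omit(fb))
      if (paired) {
        out[[length(out) + 1L]] <- data.frame(
          contig_a = sigA$contig_id[i], start_a = sigA$start[i],
          end_a = sigA$end[i], contig_b = sigB$contig_id[j],
          start_b = sigB$start[j], end_b = sigB$end[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
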