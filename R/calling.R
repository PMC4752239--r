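#' Trimmed central mean
#'
#' Mean of the central fraction of ranked values: values are sorted
#' ascending, `floor((1 - central_fraction)/2 * n)` values are dropped from
#' each end, and the mean of the remainder returned. With the default
#' central fraction of 0.6 this minimizes the influence of unmethylated
#' sites and other outliers on the average motif ipdR.
#'
#' @param values numeric vector (non-empty).
#' @param central_fraction fraction kept, in (0, 1].
#' @return mean of the central values.
#' @export
trimmed_central_mean <- function(values, central_fraction = 0.6) {
  if (!length(values)) stop("empty value list")
  stopifnot(central_fraction > 0, central_fraction <= 1)
  values <- sort(values)
  n <- length(values)
  drop <- floor((1 - central_fraction) / 2 * n)
  mean(values[(drop + 1):(n - drop)])
}

#' Threshold set from average motif and non-motif ipdR
#'
#' The under-methylated threshold is
#' `0.1 * avg_motif + 0.9 * avg_nonmotif` (the ipdR expected if 10\% of
#' molecules were methylated); the methylated threshold is
#' `0.5 * avg_motif + 0.5 * avg_nonmotif`.
#'
#' @param avg_motif trimmed-mean ipdR over motif methylatable positions.
#' @param avg_nonmotif trimmed-mean ipdR over same-base non-motif positions.
#' @param cfg configuration from [pipeline_config()].
#' @return list with `avg_motif_ipdR`, `avg_nonmotif_ipdR`, `under_thr`,
#'   `meth_thr` and a `degenerate` flag (TRUE when the motif average does
#'   not exceed the background average, so the thresholds carry no signal).
#' @export
threshold_set <- function(avg_motif, avg_nonmotif, cfg = pipeline_config()) {
  w_u <- cfg$under_meth_weight
  w_m <- cfg$meth_weight
  out <- list(
    avg_motif_ipdR = avg_motif,
    avg_nonmotif_ipdR = avg_nonmotif,
    under_thr = w_u * avg_motif + (1 - w_u) * avg_nonmotif,
    meth_thr = w_m * avg_motif + (1 - w_m) * avg_nonmotif,
    degenerate = avg_motif <= avg_nonmotif
  )
  if (out$degenerate)
    warning("avg motif ipdR <= avg non-motif ipdR; thresholds are degenerate")
  out
}

#' Compute per-motif ipdR thresholds from a kinetic track
#'
#' The average motif ipdR is the trimmed central mean over ipdR at all
#' methylatable motif positions, both strands pooled. The average non-motif
#' ipdR is the trimmed central mean over all genome positions of the same
#' nucleotide as the methylated base (on either strand) lying outside every
#' instance footprint of this motif; other motifs' sites are not excluded
#' from the background.
#'
#' @param track a [kinetic_track()].
#' @param instances instance table from [find_motif_instances()].
#' @param motif the [motif_spec()] scanned.
#' @param genome named character vector of contig sequences.
#' @param cfg configuration list.
#' @return a threshold set as from [threshold_set()].
#' @export
compute_thresholds <- function(track, instances, motif, genome,
                               cfg = pipeline_config()) {
  stopifnot(inherits(track, "kinetic_track"))
  if (nrow(instances) < 10)
    warning("fewer than 10 motif instances; thresholds will be unstable")
  mb <- meth_base(motif)
  mb_comp <- chartr("ACGT", "TGCA", mb)

  motif_vals <- numeric(0)
  bg_vals <- numeric(0)
  for (contig in unique(instances$contig_id)) {
    ins <- instances[instances$contig_id == contig, , drop = FALSE]
    fwd <- ins$meth_pos_fwd[!is.na(ins$meth_pos_fwd)]
    rev <- ins$meth_pos_rev[!is.na(ins$meth_pos_rev)]
    if (length(fwd))
      motif_vals <- c(motif_vals, track_get(track, contig, "+", fwd)$ipdR)
    if (length(rev))
      motif_vals <- c(motif_vals, track_get(track, contig, "-", rev)$ipdR)

    seq <- genome[[contig]]
    len <- nchar(seq)
    in_footprint <- logical(len)
    if (nrow(ins)) {
      idx <- unlist(mapply(seq.int, ins$start + 1L, ins$end,
                           SIMPLIFY = FALSE))
      in_footprint[idx] <- TRUE
    }
    bases <- strsplit(seq, "")[[1]]
    fwd_bg <- which(bases == mb & !in_footprint)
    rev_bg <- which(bases == mb_comp & !in_footprint)
    if (length(fwd_bg))
      bg_vals <- c(bg_vals, track_get(track, contig, "+", fwd_bg - 1L)$ipdR)
    if (length(rev_bg))
      bg_vals <- c(bg_vals, track_get(track, contig, "-", rev_bg - 1L)$ipdR)
  }
  motif_vals <- motif_vals[!is.na(motif_vals)]
  bg_vals <- bg_vals[!is.na(bg_vals)]
  if (!length(motif_vals)) stop("no kinetic data at motif positions")
  if (!length(bg_vals)) stop("no non-motif positions of base ", mb,
                             " with kinetic data")
  threshold_set(trimmed_central_mean(motif_vals, cfg$central_fraction),
                trimmed_central_mean(bg_vals, cfg$central_fraction),
                cfg)
}

#' Classify motif instances as methylated / unmethylated / ambiguous /
#' low-coverage
#'
#' Only palindromic double-strand motifs (both methylatable-base
#' coordinates present) are called: an instance is `unmethylated` when both
#' strands have at least `min_coverage` reads and ipdR strictly below the
#' under-methylated threshold; `methylated` when both strands are covered
#' and have ipdR at or above the methylated threshold; `low_coverage` when
#' either strand has fewer than `min_coverage` reads (positions absent from
#' the track count as coverage 0); otherwise `ambiguous`.
#'
#' @param track a [kinetic_track()].
#' @param instances instance table (palindromic motif).
#' @param thresholds a [threshold_set()].
#' @param cfg configuration list.
#' @return the instance table with columns `state, ipdR_fwd, ipdR_rev,
#'   cov_fwd, cov_rev` appended, ordered by contig and start.
#' @export
call_instances <- function(track, instances, thresholds,
                           cfg = pipeline_config()) {
  if (!nrow(instances)) {
    instances$state <- character(0)
    instances$ipdR_fwd <- instances$ipdR_rev <- numeric(0)
    instances$cov_fwd <- instances$cov_rev <- integer(0)
    return(instances)
  }
  if (any(is.na(instances$meth_pos_fwd)) || any(is.na(instances$meth_pos_rev)))
    stop("calling requires a palindromic double-strand motif; ",
         "single-strand motifs are reported without methylation calls")
  out <- instances
  out$ipdR_fwd <- NA_real_; out$ipdR_rev <- NA_real_
  out$cov_fwd <- 0L; out$cov_rev <- 0L
  for (contig in unique(out$contig_id)) {
    sel <- out$contig_id == contig
    f <- track_get(track, contig, "+", out$meth_pos_fwd[sel])
    r <- track_get(track, contig, "-", out$meth_pos_rev[sel])
    out$ipdR_fwd[sel] <- f$ipdR
    out$ipdR_rev[sel] <- r$ipdR
    out$cov_fwd[sel] <- ifelse(is.na(f$cov), 0L, f$cov)
    out$cov_rev[sel] <- ifelse(is.na(r$cov), 0L, r$cov)
  }
  covered <- out$cov_fwd >= cfg$min_coverage & out$cov_rev >= cfg$min_coverage
  both_low <- covered & out$ipdR_fwd < thresholds$under_thr &
    out$ipdR_rev < thresholds$under_thr
  both_high <- covered & out$ipdR_fwd >= thresholds$meth_thr &
    out$ipdR_rev >= thresholds$meth_thr
  out$state <- ifelse(!covered, "low_coverage",
               ifelse(both_low, "unmethylated",
               ifelse(both_high, "methylated", "ambiguous")))
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize methylation calls
#'
#' Counts and fractions per state plus the median per-strand coverage per
#' state -- the coverage diagnostic confirming that unmethylated sites are
#' not low-coverage artefacts. The per-call table retains both strands'
#' ipdR for scatter plotting.
#'
#' @param calls call table from [call_instances()].
#' @return list with `counts`, `fractions`, `pct_methylated` (percent of
#'   all instances called methylated), `median_coverage` per state, and the
#'   `calls` table.
#' @export
call_summary <- function(calls) {
  states <- c("methylated", "unmethylated", "ambiguous", "low_coverage")
  counts <- vapply(states, function(s) sum(calls$state == s), integer(1))
  n <- nrow(calls)
  fractions <- if (n) counts / n else counts * NA_real_
  med_cov <- vapply(states, function(s) {
    sel <- calls$state == s
    if (!any(sel)) return(NA_real_)
    stats::median(c(calls$cov_fwd[sel], calls$cov_rev[sel]))
  }, numeric(1))
  list(counts = counts, fractions = fractions,
       pct_methylated = if (n) 100 * counts[["methylated"]] / n else NA_real_,
       median_coverage = med_cov, calls = calls)
}
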