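# Enrichment statistics for motifs and unmethylated sites in gene
# regulatory regions. Fold enrichments compare an observed in-region
# fraction against either composition-matched random placements (for all
# motifs) or the methylated-motif fraction (for unmethylated motifs);
# significance comes from two-sided Fisher's exact tests.

composition_key <- function(seqs) {
  # base multiset of each window as "nA.nC.nG.nT"
  m <- vapply(c("A", "C", "G", "T"), function(b) {
    vapply(gregexpr(b, seqs, fixed = TRUE), function(g)
      if (g[1] == -1L) 0L else length(g), integer(1))
  }, integer(length(seqs)))
  if (length(seqs) == 1) m <- matrix(m, nrow = 1)
  apply(m, 1, paste, collapse = ".")
}

# Rolling base counts: composition key of every L-window of seq (windows
# containing N get NA). Returns character vector over 0-based starts
# 0..(len-L).
window_keys <- function(seq, L) {
  bases <- strsplit(seq, "")[[1]]
  len <- length(bases)
  if (len < L) return(character(0))
  n_win <- len - L + 1L
  counts <- sapply(c("A", "C", "G", "T", "N"), function(b) {
    cs <- c(0L, cumsum(bases == b))
    cs[(L + 1):(len + 1)] - cs[1:n_win]
  })
  keys <- paste(counts[, 1], counts[, 2], counts[, 3], counts[, 4],
                sep = ".")
  keys[counts[, 5] > 0] <- NA_character_
  keys
}

#' Sample composition-matched control positions
#'
#' For each real motif instance, draws one random genome window of the
#' same length and identical nucleotide composition, repeated `n_sets`
#' times (candidate positions are reused across samplings). Matching is
#' per realized instance sequence, so degenerate motifs are matched window
#' by window.
#'
#' @param seq a single contig sequence.
#' @param instance_seqs character vector of realized instance sequences
#'   (all the same length).
#' @param n_sets number of samplings.
#' @param seed RNG seed.
#' @return integer matrix `length(instance_seqs)` x `n_sets` of 0-based
#'   window start positions.
#' @export
sample_composition_matched_sites <- function(seq, instance_seqs,
                                             n_sets = 1000L, seed = 1L) {
  stopifnot(length(instance_seqs) >= 1)
  L <- unique(nchar(instance_seqs))
  stopifnot(length(L) == 1)
  keys <- window_keys(seq, L)
  cand <- split(seq_along(keys) - 1L, keys)   # 0-based starts per key
  inst_keys <- composition_key(instance_seqs)
  missing <- setdiff(unique(inst_keys), names(cand))
  if (length(missing))
    stop("no genome window matches composition ", paste(missing, collapse = ";"))
  n_inst <- length(instance_seqs)
  out <- matrix(0L, nrow = n_inst, ncol = n_sets)
  with_seed(seed, {
    for (key in unique(inst_keys)) {
      rows <- which(inst_keys == key)
      pool <- cand[[key]]
      draws <- pool[sample.int(length(pool), length(rows) * n_sets,
                               replace = TRUE)]
      out[rows, ] <- draws
    }
  })
  out
}

# TRUE/FALSE over 0-based window starts 0..(len-L): does the window
# [p, p+L) overlap any region?
window_overlap_lookup <- function(len, L, regions) {
  n_win <- len - L + 1L
  hit <- logical(max(n_win, 0L))
  if (n_win <= 0L || !nrow(regions)) return(hit)
  for (i in seq_len(nrow(regions))) {
    lo <- max(regions$start[i] - L + 1L, 0L)
    hi <- min(regions$end[i] - 1L, n_win - 1L)
    if (lo <= hi) hit[(lo + 1L):(hi + 1L)] <- TRUE
  }
  hit
}

make_enrichment <- function(n_in, n_total, bg_in, bg_total, p_value, method,
                            n_resamplings = NA_integer_, seed = NA_integer_) {
  observed <- if (n_total > 0) n_in / n_total else NA_real_
  background <- if (bg_total > 0) bg_in / bg_total else NA_real_
  fold <- if (!is.na(background) && background > 0) observed / background
          else NA_real_
  structure(list(
    n_in = n_in, n_total = n_total,
    observed_fraction = observed, background_fraction = background,
    fold = fold, p_value = p_value, method = method,
    n_resamplings = n_resamplings, seed = seed,
    undefined_background = is.na(background) || background == 0
  ), class = "enrichment_result")
}

#' Enrichment of motif instances in regulatory regions
#'
#' Observed fraction = fraction of instances whose footprint overlaps any
#' regulatory interval; background = mean in-region fraction over
#' composition-matched random samplings. Significance is a two-sided
#' Fisher's exact test on the 2x2 table (in/out region x real/pooled
#' random placements).
#'
#' @param instances instance table from [find_motif_instances()].
#' @param regions regulatory regions from [define_regulatory_regions()].
#' @param genome named character vector of contig sequences.
#' @param cfg configuration list.
#' @param seed RNG seed for the samplings (default `cfg$rng_seed`).
#' @return an `enrichment_result` list.
#' @export
motif_region_enrichment <- function(instances, regions, genome,
                                    cfg = pipeline_config(),
                                    seed = cfg$rng_seed) {
  stopifnot(nrow(instances) > 0)
  n_total <- nrow(instances)
  n_in <- sum(footprint_overlaps(instances, regions))
  L <- unique(instances$end - instances$start)
  stopifnot(length(L) == 1)

  rand_in <- 0; rand_total <- 0
  for (contig in unique(instances$contig_id)) {
    ins <- instances[instances$contig_id == contig, , drop = FALSE]
    r <- regions[regions$contig_id == contig, , drop = FALSE]
    lookup <- window_overlap_lookup(nchar(genome[[contig]]), L, r)
    samp <- sample_composition_matched_sites(genome[[contig]], ins$seq,
                                             cfg$n_resamplings, seed)
    rand_in <- rand_in + sum(lookup[samp + 1L])
    rand_total <- rand_total + length(samp)
  }
  tab <- matrix(c(n_in, n_total - n_in, rand_in, rand_total - rand_in), 2,
                byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  make_enrichment(n_in, n_total, rand_in, rand_total, p,
                  method = "resampling", cfg$n_resamplings, seed)
}

#' Enrichment of unmethylated motifs in a region set
#'
#' Compares the in-region fraction of unmethylated calls against that of
#' methylated calls (the background); two-sided Fisher's exact test on the
#' 2x2 table (in/out x unmethylated/methylated). Ambiguous and
#' low-coverage calls take part in neither row.
#'
#' @param calls call table from [call_instances()].
#' @param regions region data.frame.
#' @return an `enrichment_result`.
#' @export
unmethylated_region_enrichment <- function(calls, regions) {
  meth <- calls[calls$state == "methylated", , drop = FALSE]
  unmeth <- calls[calls$state == "unmethylated", , drop = FALSE]
  if (!nrow(meth)) stop("no methylated calls to form the background")
  u_in <- sum(footprint_overlaps(unmeth, regions))
  m_in <- sum(footprint_overlaps(meth, regions))
  tab <- matrix(c(u_in, nrow(unmeth) - u_in, m_in, nrow(meth) - m_in), 2,
                byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  res <- make_enrichment(u_in, nrow(unmeth), m_in, nrow(meth), p, "fisher")
  # no unmethylated sites: enrichment is zero by definition, not undefined
  if (!nrow(unmeth)) res$fold <- 0
  res
}

#' Per-COG-category enrichment of unmethylated motifs
#'
#' Repeats [unmethylated_region_enrichment()] with the regulatory regions
#' restricted to each COG functional letter in turn; letters with no
#' region are skipped with a note.
#'
#' @param calls call table.
#' @param regions regulatory regions carrying `cog_letter`.
#' @param alpha per-letter significance level for the flag (0.01).
#' @return data.frame with one row per letter: counts, fractions, fold,
#'   Fisher p and `significant` flag.
#' @export
cog_category_enrichment <- function(calls, regions, alpha = 0.01) {
  letters_seen <- sort(unique(stats::na.omit(regions$cog_letter)))
  rows <- lapply(letters_seen, function(let) {
    r <- regions[!is.na(regions$cog_letter) & regions$cog_letter == let, ,
                 drop = FALSE]
    if (!nrow(r)) {
      message("COG letter ", let, " has no regions; skipped")
      return(NULL)
    }
    e <- unmethylated_region_enrichment(calls, r)
    data.frame(cog_letter = let, n_unmeth_in = e$n_in,
               n_unmeth = e$n_total,
               observed_fraction = e$observed_fraction,
               background_fraction = e$background_fraction,
               fold = ifelse(is.na(e$fold) && e$n_in == 0, 0, e$fold),
               p_value = e$p_value,
               significant = e$p_value < alpha && enriched_direction(e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cog_letter = character(), n_unmeth_in = integer(),
                      n_unmeth = integer(), observed_fraction = numeric(),
                      background_fraction = numeric(), fold = numeric(),
                      p_value = numeric(), significant = logical())
  rownames(out) <- NULL
  out
}

#' Overlap of unmethylated motifs with transcription factor binding sites
#'
#' Fraction of unmethylated vs methylated instances overlapping any
#' supplied TFBS interval, with a two-sided Fisher's exact test
#' (significance flag at p < 0.05).
#'
#' @param calls call table.
#' @param tfbs TFBS intervals, e.g. from [read_bed_regions()].
#' @param alpha significance level for the flag (0.05).
#' @return an `enrichment_result` with an added `significant` flag.
#' @export
tfbs_overlap_enrichment <- function(calls, tfbs, alpha = 0.05) {
  if (!nrow(tfbs)) stop("empty TFBS interval set")
  res <- unmethylated_region_enrichment(calls, tfbs)
  res$significant <- res$p_value < alpha && enriched_direction(res)
  res
}

# enrichment (not depletion): observed fraction exceeds background,
# including the degenerate case of a zero background with observations
enriched_direction <- function(e) {
  !is.na(e$observed_fraction) && !is.na(e$background_fraction) &&
    e$observed_fraction > e$background_fraction
}
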