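#' Run the full methylome analysis
#'
#' Orchestrates all stages per motif in dependency order: instance
#' scanning, threshold derivation, methylation calling, call summary,
#' regulatory-region enrichment (all motifs and unmethylated motifs, plus
#' per-COG-letter tests), unmethylated-site cluster detection with
#' permutation p-values, and the non-coding motif-cluster scan.
#' Non-palindromic motifs are reported with instance counts and
#' classification only (no double-strand methylation calls). Re-running
#' with the same inputs, configuration and seed reproduces identical
#' outputs.
#'
#' @param genome named character vector of contig sequences.
#' @param genes annotation data.frame (1-based coordinates).
#' @param track a [kinetic_track()].
#' @param motifs list of [motif_spec()] objects.
#' @param cfg configuration list.
#' @param out_dir when non-NULL, per-motif TSV/BED reports and a JSON run
#'   summary are written there.
#' @return a run summary list: per-motif results (`instances`, `type`,
#'   `thresholds`, `calls`, `summary`, `enrichment`, `clusters`,
#'   `noncoding`) plus `config` and `seed` provenance.
#' @export
run_methylome_analysis <- function(genome, genes, track, motifs,
                                   cfg = pipeline_config(), out_dir = NULL) {
  regions <- define_regulatory_regions(genes, genome, cfg)
  noncoding <- extract_noncoding_regions(genes, genome)
  per_motif <- list()
  for (mi in seq_along(motifs)) {
    motif <- motifs[[mi]]
    res <- list(pattern = motif$pattern, mod_type = motif$mod_type,
                type = classify_motif(motif))
    res$instances <- find_motif_instances(genome, motif)
    res$error <- NULL
    if (nrow(res$instances) >= 2) {
      res$mean_intermotif <- mean_intermotif_distance(res$instances)
      res$noncoding <- noncoding_enrichment_scan(noncoding, res$instances,
                                                 cfg)
      res$motif_enrichment <- tryCatch(
        motif_region_enrichment(res$instances, regions, genome, cfg,
                                seed = cfg$rng_seed + mi),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "stage_error"))
    }
    callable <- nrow(res$instances) >= 2 &&
      !any(is.na(res$instances$meth_pos_fwd)) &&
      !any(is.na(res$instances$meth_pos_rev))
    if (callable) {
      stage <- tryCatch({
        thresholds <- compute_thresholds(track, res$instances, motif,
                                         genome, cfg)
        calls <- call_instances(track, res$instances, thresholds, cfg)
        list(thresholds = thresholds, calls = calls,
             summary = call_summary(calls))
      }, error = function(e) structure(list(message = conditionMessage(e)),
                                       class = "stage_error"))
      if (inherits(stage, "stage_error")) {
        res$error <- stage$message
      } else {
        res <- c(res, stage)
        res$unmeth_enrichment <- tryCatch(
          unmethylated_region_enrichment(res$calls, regions),
          error = function(e) NULL)
        res$cog_enrichment <- tryCatch(
          cog_category_enrichment(res$calls, regions),
          error = function(e) NULL)
        res$clusters <- unmethylated_cluster_analysis(
          res$calls, res$mean_intermotif, cfg, seed = cfg$rng_seed + mi)
      }
    }
    per_motif[[motif$pattern]] <- res
  }
  summary <- list(motifs = per_motif, config = cfg, seed = cfg$rng_seed,
                  n_regulatory_regions = nrow(regions),
                  n_noncoding_regions = nrow(noncoding))
  if (!is.null(out_dir)) write_run_reports(summary, out_dir)
  summary
}

# Per-motif TSV/BED reports plus a JSON summary of the headline numbers.
write_run_reports <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- list(seed = summary$seed,
                 n_regulatory_regions = summary$n_regulatory_regions,
                 n_noncoding_regions = summary$n_noncoding_regions,
                 motifs = list())
  for (pattern in names(summary$motifs)) {
    res <- summary$motifs[[pattern]]
    stub <- file.path(out_dir, gsub("[^A-Za-z0-9]", "_", pattern))
    utils::write.table(res$instances, paste0(stub, "_instances.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    entry <- list(pattern = pattern, mod_type = res$mod_type,
                  category = res$type$category,
                  n_instances = nrow(res$instances), error = res$error)
    if (!is.null(res$calls)) {
      utils::write.table(res$calls, paste0(stub, "_calls.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      un <- res$calls[res$calls$state == "unmethylated", , drop = FALSE]
      if (nrow(un)) {
        un$name <- "unmethylated"
        un$score <- pmin(un$ipdR_fwd, un$ipdR_rev)
        un$strand <- "+"
      }
      write_bed(un, paste0(stub, "_unmethylated.bed"))
      entry$state_counts <- as.list(res$summary$counts)
      entry$pct_methylated <- res$summary$pct_methylated
      entry$thresholds <- res$thresholds[c("avg_motif_ipdR",
                                           "avg_nonmotif_ipdR",
                                           "under_thr", "meth_thr")]
      if (!is.null(res$unmeth_enrichment))
        entry$unmeth_enrichment <- res$unmeth_enrichment[
          c("observed_fraction", "background_fraction", "fold", "p_value")]
    }
    if (!is.null(res$clusters)) {
      utils::write.table(res$clusters, paste0(stub, "_clusters.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      entry$n_significant_clusters <- sum(res$clusters$significant)
    }
    if (!is.null(res$noncoding)) {
      utils::write.table(res$noncoding, paste0(stub, "_noncoding_scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      entry$n_significant_noncoding <- sum(res$noncoding$significant)
    }
    if (!is.null(res$cog_enrichment)) {
      utils::write.table(res$cog_enrichment, paste0(stub, "_cog.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    digest$motifs[[pattern]] <- entry
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(digest, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(out_dir)
}
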