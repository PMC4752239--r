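# Genomic-context classification of MTase genes (orphan vs RM-associated)
# and matching of methylated motifs to candidate MTases under the
# uniqueness rule: a motif is matched only when exactly one compatible
# candidate gene exists.

#' Classify an MTase as orphan candidate or RM-associated
#'
#' An MTase is RM-associated when any restriction endonuclease gene lies
#' within `window_genes` annotated genes or `window_bp` bases of it on the
#' same contig; otherwise it is a candidate orphan. The windows quantify
#' "flanking genome sequence" and are configurable.
#'
#' @param mtase one row of an MTase gene table (list or single-row
#'   data.frame with `gene_id, contig_id, start, end`).
#' @param reases REase gene table (possibly empty).
#' @param genes full gene annotation (used for gene-rank distance), sorted
#'   or not.
#' @param window_genes gene-count window (5).
#' @param window_bp base-pair window (10000).
#' @return `"orphan_candidate"` or `"rm_associated"`.
#' @export
classify_orphan <- function(mtase, reases, genes, window_genes = 5L,
                            window_bp = 10000L) {
  if (!nrow(reases)) return("orphan_candidate")
  re <- reases[reases$contig_id == mtase$contig_id, , drop = FALSE]
  if (!nrow(re)) return("orphan_candidate")
  # interval distance in bp
  bp_dist <- pmax(0L, pmax(re$start - mtase$end, mtase$start - re$end))
  if (any(bp_dist <= window_bp)) return("rm_associated")
  g <- genes[genes$contig_id == mtase$contig_id, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  rank_of <- function(start, end) {
    # rank of the annotated gene containing/overlapping the coordinates,
    # else of the nearest by start
    hit <- which(g$start <= end & g$end >= start)
    if (length(hit)) return(hit[1])
    which.min(abs(g$start - start))
  }
  if (!nrow(g)) return("orphan_candidate")
  m_rank <- rank_of(mtase$start, mtase$end)
  re_rank <- vapply(seq_len(nrow(re)), function(i)
    rank_of(re$start[i], re$end[i]), integer(1))
  if (any(abs(re_rank - m_rank) <= window_genes)) "rm_associated"
  else "orphan_candidate"
}

# rm_type compatible with a structural motif category?
rm_type_compatible <- function(rm_type, category) {
  if (rm_type == "unknown") return(TRUE)
  switch(category,
         TypeI_bipartite = rm_type == "I",
         TypeII_palindromic = rm_type == "II",
         TypeIIG_like = rm_type == "IIG",
         TypeIII_like = rm_type == "III",
         FALSE)
}

#' Match methylated motifs to candidate MTase genes
#'
#' Candidates for a motif are MTases whose RM type is compatible with the
#' motif's structural category (I = bipartite, II = palindromic,
#' IIG = long non-palindromic, III = short non-palindromic; unknown types
#' are compatible with all) and whose predicted specificity, when present,
#' equals the motif pattern (exact string equality after canonicalizing
#' palindromes to the lexicographically smaller strand). A motif is
#' `matched` iff exactly one candidate exists, `ambiguous` with more than
#' one, `unmatched` with none.
#'
#' @param motifs list of [motif_spec()] objects.
#' @param mtases MTase gene table with `gene_id, rm_type, specificity`
#'   columns.
#' @return data.frame with one row per motif: `pattern, category,
#'   matched_gene, status, n_candidates`.
#' @export
match_motifs_to_mtases <- function(motifs, mtases) {
  rows <- lapply(motifs, function(motif) {
    category <- classify_motif(motif)$category
    compat <- vapply(mtases$rm_type, rm_type_compatible, logical(1),
                     category = category)
    if ("specificity" %in% names(mtases)) {
      has_spec <- !is.na(mtases$specificity) & nzchar(mtases$specificity)
      spec_ok <- !has_spec
      spec_ok[has_spec] <- vapply(mtases$specificity[has_spec],
                                  function(s) identical(canonical_pattern(s),
                                                        canonical_pattern(motif$pattern)),
                                  logical(1))
      compat <- compat & spec_ok
    }
    cand <- mtases$gene_id[compat]
    data.frame(
      pattern = motif$pattern, category = category,
      matched_gene = if (length(cand) == 1) cand else NA_character_,
      status = if (length(cand) == 1) "matched"
               else if (length(cand) > 1) "ambiguous" else "unmatched",
      n_candidates = length(cand), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
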