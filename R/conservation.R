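# Cross-genome conservation analyses: bitscore-ratio ortholog scoring,
# conservation fractions over taxa, reciprocal best hits, conserved
# unmethylated sites, and clustering of orphan MTases into families.

#' Bitscore-ratio similarity score
#'
#' `100 * bitscore(hit to database) / bitscore(hit to self)`. A hit is a
#' potential ortholog when the score is 35 or more (inclusive). Scores
#' above 100 are possible for anomalous inputs and flagged.
#'
#' @param bitscore_hit bitscore of the query against the database subject.
#' @param bitscore_self bitscore of the query against itself (> 0).
#' @param threshold ortholog-call threshold (35).
#' @return numeric score with attribute `ortholog` (logical) and
#'   `anomalous` (TRUE when the score exceeds 100).
#' @export
similarity_score <- function(bitscore_hit, bitscore_self, threshold = 35) {
  if (any(bitscore_self <= 0)) stop("bitscore_self must be > 0")
  score <- 100 * bitscore_hit / bitscore_self
  structure(score, ortholog = score >= threshold, anomalous = score > 100)
}

#' Conservation call for an MTase across a taxonomic group
#'
#' Counts each species once regardless of hit multiplicity; the MTase is
#' conserved when the fraction of species with a potential ortholog is
#' strictly greater than `conservation_fraction` (default: > 50\%).
#'
#' @param hits data.frame with columns `species` and `similarity` (one row
#'   per database hit).
#' @param taxonomy data.frame with columns `species` plus taxon-level
#'   columns (e.g. `genus, family, class`).
#' @param level taxon level column name.
#' @param focal_taxon taxon whose species form the denominator.
#' @param cfg configuration list (similarity threshold, conservation
#'   fraction).
#' @return list: `n_species_with_ortholog`, `n_species_total`, `fraction`,
#'   `conserved`.
#' @export
conservation_fraction <- function(hits, taxonomy, level, focal_taxon,
                                  cfg = pipeline_config()) {
  stopifnot(level %in% names(taxonomy))
  members <- unique(taxonomy$species[taxonomy[[level]] == focal_taxon])
  if (!length(members)) stop("no species in ", level, " ", focal_taxon)
  if (nrow(hits) && !all(hits$species %in% taxonomy$species))
    stop("taxonomy does not cover all hit species")
  orth <- unique(hits$species[hits$similarity >= cfg$similarity_threshold])
  n_with <- sum(members %in% orth)
  frac <- n_with / length(members)
  list(n_species_with_ortholog = n_with, n_species_total = length(members),
       fraction = frac, conserved = frac > cfg$conservation_fraction)
}

# unique best subject per query; ties for best -> no call
best_hits <- function(scores) {
  out <- character(0)
  for (q in unique(scores$query)) {
    s <- scores[scores$query == q, , drop = FALSE]
    top <- max(s$bitscore)
    best <- s$subject[s$bitscore == top]
    if (length(best) == 1) out[q] <- best
  }
  out
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is reported iff b is a's unique best subject in the
#' A-vs-B table and a is b's unique best subject in B-vs-A. Ties for best
#' exclude the gene deterministically.
#'
#' @param scoresAB,scoresBA data.frames with `query, subject, bitscore`.
#' @return named character vector mapping A gene ids to B gene ids (an
#'   injective partial matching).
#' @export
reciprocal_best_hits <- function(scoresAB, scoresBA) {
  ab <- best_hits(scoresAB)
  ba <- best_hits(scoresBA)
  keep <- !is.na(ba[ab]) & ba[ab] == names(ab)
  ab[which(keep)]
}

#' Conserved unmethylated sites between two genomes
#'
#' Every unmethylated site is located between its two nearest flanking
#' genes; sites in genomes A and B are paired when both flanking genes of
#' the A site map by reciprocal best hit to the flanking genes of the B
#' site (either order, so strand flips are tolerated). A site at a contig
#' edge has a single flanking gene, which must then match; such pairs are
#' flagged.
#'
#' @param callsA,callsB call tables from [call_instances()].
#' @param genesA,genesB annotation data.frames.
#' @param rbh RBH mapping from [reciprocal_best_hits()] (A ids to B ids).
#' @return data.frame of conserved site pairs with coordinates in both
#'   genomes and a `single_flank` flag.
#' @export
conserved_unmethylated_sites <- function(callsA, callsB, genesA, genesB,
                                         rbh) {
  ua <- callsA[callsA$state == "unmethylated", , drop = FALSE]
  ub <- callsB[callsB$state == "unmethylated", , drop = FALSE]
  empty <- data.frame(contig_a = character(), start_a = integer(),
                      contig_b = character(), start_b = integer(),
                      single_flank = logical(), stringsAsFactors = FALSE)
  if (!nrow(ua) || !nrow(ub)) return(empty)
  fb <- lapply(seq_len(nrow(ub)), function(j)
    flanking_gene_ids(genesB, ub$contig_id[j], ub$start[j], ub$end[j]))
  out <- list()
  for (i in seq_len(nrow(ua))) {
    fa <- flanking_gene_ids(genesA, ua$contig_id[i], ua$start[i], ua$end[i])
    ma <- unname(rbh[fa])
    n_flank <- sum(!is.na(fa))
    if (all(is.na(ma))) next
    for (j in seq_len(nrow(ub))) {
      fbj <- fb[[j]]
      ok <- if (n_flank == 2 && sum(!is.na(ma)) == 2) {
        identical(ma, fbj) || identical(ma, rev(fbj))
      } else {
        m1 <- stats::na.omit(ma)[1]
        !is.na(m1) && m1 %in% stats::na.omit(fbj)
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          contig_a = ua$contig_id[i], start_a = ua$start[i],
          contig_b = ub$contig_id[j], start_b = ub$start[j],
          single_flank = n_flank < 2 || sum(!is.na(ma)) < 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster orphan MTases into candidate families
#'
#' MTases are first split by methylated-base type (m6A vs m4C/m5C
#' combined). Within each group, agglomerative clustering on the pairwise
#' protein identity matrix groups MTases so that the minimum pairwise
#' identity within a cluster is at least `family_identity_cutoff`
#' (complete linkage on 1 - identity, cut at 1 - cutoff; set
#' `linkage = "single"` for conventional single-linkage instead).
#' Clusters are then subdivided so that all members share an identical
#' canonical motif and a common taxon label. Single-member families are
#' reported with `singleton = TRUE`.
#'
#' @param similarity square symmetric matrix of pairwise identities in
#'   [0, 1] with MTase ids as dimnames.
#' @param mod_types named vector of modification types per MTase.
#' @param motifs named vector of IUPAC recognition patterns per MTase.
#' @param taxa named vector of taxon labels per MTase.
#' @param cfg configuration list.
#' @param linkage `"min"` (default; minimum within-cluster identity >=
#'   cutoff) or `"single"`.
#' @return data.frame with one row per MTase: `mtase_id, mod_type_group,
#'   family, shared_motif, taxon, singleton`.
#' @export
cluster_orphan_families <- function(similarity, mod_types, motifs, taxa,
                                    cfg = pipeline_config(),
                                    linkage = c("min", "single")) {
  linkage <- match.arg(linkage)
  if (!isSymmetric(unname(similarity)))
    stop("similarity matrix must be symmetric")
  ids <- rownames(similarity)
  stopifnot(!is.null(ids), all(ids %in% names(mod_types)),
            all(ids %in% names(motifs)), all(ids %in% names(taxa)))
  group_of <- ifelse(mod_types[ids] == "m6A", "m6A", "m4C_m5C")
  out <- list()
  for (grp in unique(group_of)) {
    gids <- sort(ids[group_of == grp])  # sort => order-invariant output
    if (length(gids) == 1) {
      memb <- stats::setNames(1L, gids)
    } else {
      d <- stats::as.dist(1 - similarity[gids, gids])
      method <- if (linkage == "min") "complete" else "single"
      hc <- stats::hclust(d, method = method)
      memb <- stats::cutree(hc, h = 1 - cfg$family_identity_cutoff)
    }
    # subdivide by identical canonical motif and common taxon
    canon <- vapply(motifs[gids], canonical_pattern, character(1))
    key <- paste(memb[gids], canon, taxa[gids], sep = "|")
    fam_ids <- match(key, unique(key))
    out[[length(out) + 1L]] <- data.frame(
      mtase_id = gids, mod_type_group = grp,
      family = paste0(grp, "_", fam_ids),
      shared_motif = unname(canon), taxon = unname(taxa[gids]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  fam_size <- table(res$family)
  res$singleton <- fam_size[res$family] == 1
  res <- res[order(res$mtase_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
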