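#' Define gene regulatory regions
#'
#' A regulatory region spans 100 bp upstream of a CDS start to 50 bp
#' downstream of the CDS start (both configurable), oriented by gene
#' strand and clipped at contig edges. One interval per CDS; overlapping
#' intervals are retained separately. Coordinates are 0-based half-open.
#'
#' @param genes annotation data.frame from [read_gff3()] (1-based
#'   inclusive coordinates).
#' @param genome named character vector of contig sequences.
#' @param cfg configuration list.
#' @return region data.frame with columns `contig_id,start,end,strand,
#'   gene_id,cog_letter,label`.
#' @export
define_regulatory_regions <- function(genes, genome, cfg = pipeline_config()) {
  cds <- genes[genes$feature_type == "CDS", , drop = FALSE]
  up <- cfg$upstream_bp
  dn <- cfg$downstream_bp
  s0 <- cds$start - 1L            # 0-based start
  e0 <- cds$end                   # 0-based exclusive end
  start <- ifelse(cds$strand == "+", s0 - up, e0 - dn)
  end <- ifelse(cds$strand == "+", s0 + dn, e0 + up)
  lens <- nchar(genome)[cds$contig_id]
  start <- pmax(start, 0L)
  end <- pmin(end, lens)
  keep <- start < end
  out <- data.frame(contig_id = cds$contig_id[keep],
                    start = as.integer(start[keep]),
                    end = as.integer(end[keep]),
                    strand = cds$strand[keep], gene_id = cds$gene_id[keep],
                    cog_letter = if ("cog_letter" %in% names(cds))
                      cds$cog_letter[keep] else NA_character_,
                    label = "regulatory", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Non-coding regions of a genome
#'
#' Complement of the union of CDS intervals; RNA-gene intervals are also
#' removed (they are neither coding nor analysed). Zero-length gaps are
#' omitted. Coordinates 0-based half-open.
#'
#' @param genes annotation data.frame (1-based inclusive coordinates).
#' @param genome named character vector of contig sequences.
#' @return region data.frame ordered by contig and start.
#' @export
extract_noncoding_regions <- function(genes, genome) {
  out <- list()
  for (contig in names(genome)) {
    len <- nchar(genome[[contig]])
    g <- genes[genes$contig_id == contig &
                 genes$feature_type %in% c("CDS", "RNA"), , drop = FALSE]
    if (nrow(g)) {
      covered <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
      gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), covered)
    } else {
      gaps <- IRanges::IRanges(1L, len)
    }
    if (length(gaps)) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig, start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps), strand = ".",
        gene_id = NA_character_, cog_letter = NA_character_,
        label = "noncoding", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), cog_letter = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Which intervals overlap any region?
#'
#' Membership is footprint overlap: an interval is "in" a region set when
#' any part of it intersects any interval of the set on the same contig.
#'
#' @param intervals data.frame with `contig_id,start,end` (0-based
#'   half-open), e.g. motif instances.
#' @param regions region data.frame.
#' @return logical vector along `intervals` rows.
#' @export
footprint_overlaps <- function(intervals, regions) {
  hit <- logical(nrow(intervals))
  if (!nrow(intervals) || !nrow(regions)) return(hit)
  for (contig in unique(intervals$contig_id)) {
    qi <- which(intervals$contig_id == contig)
    r <- regions[regions$contig_id == contig, , drop = FALSE]
    if (!nrow(r)) next
    q <- IRanges::IRanges(intervals$start[qi] + 1L, intervals$end[qi])
    s <- IRanges::IRanges(r$start + 1L, r$end)
    hit[qi] <- IRanges::overlapsAny(q, s)
  }
  hit
}
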