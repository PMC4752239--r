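#' Read a genome FASTA
#'
#' Sequences are upper-cased on ingest. IUPAC ambiguity codes other than N
#' are masked to N with a warning; masked bases never match any motif
#' symbol downstream.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names = contig ids).
#' @export
read_genome_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  seqs <- toupper(as.character(set))
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    warning("non-ACGTN IUPAC codes masked to N in contig(s): ",
            paste(ids[amb], collapse = ", "))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' CDS and RNA-typed features are parsed; coordinates are kept 1-based
#' inclusive as in the file (conversion to internal 0-based half-open
#' happens only when regions are constructed). CDS features without an
#' `ID` or `locus_tag` attribute get a synthesized id with a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `contig_id,start,end,strand,feature_type,
#'   gene_id,product,cog_letter`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), gene_id = character(),
                      product = character(), cog_letter = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("malformed GFF3 line (fewer than 9 fields)")
  get <- function(i) vapply(f, `[[`, character(1), i)
  type_raw <- get(3)
  feature_type <- ifelse(type_raw == "CDS", "CDS",
                  ifelse(grepl("RNA", type_raw, ignore.case = TRUE), "RNA",
                         "other"))
  start <- as.integer(get(4)); end <- as.integer(get(5))
  if (any(is.na(start)) || any(is.na(end))) stop("non-numeric GFF3 coordinates")
  if (any(start > end)) stop("GFF3 feature with start > end")
  attr_field <- get(9)
  pull_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- vapply(regexpr(paste0("(^|;)\\s*", key, "="), attr_field), `>`,
                  logical(1), 0L)
    out[hit] <- sub(paste0("^.*", key, "="), "", m)
    out
  }
  gene_id <- pull_attr("ID")
  lt <- pull_attr("locus_tag")
  gene_id[is.na(gene_id)] <- lt[is.na(gene_id)]
  keep <- feature_type %in% c("CDS", "RNA")
  missing_id <- keep & is.na(gene_id)
  if (any(missing_id)) {
    warning(sum(missing_id), " feature(s) without ID/locus_tag; ids synthesized")
    gene_id[missing_id] <- paste0("feat_", which(missing_id))
  }
  df <- data.frame(contig_id = get(1), start = start, end = end,
                   strand = get(7), feature_type = feature_type,
                   gene_id = gene_id, product = pull_attr("product"),
                   cog_letter = pull_attr("cog"), stringsAsFactors = FALSE)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene annotations as GFF3
#'
#' @param genes annotation data.frame as from [read_gff3()].
#' @param path output file.
#' @param source source column value.
#' @export
write_gff3 <- function(genes, path, source = "prokmethylome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    type <- ifelse(genes$feature_type == "RNA", "tRNA", genes$feature_type)
    attrs <- paste0("ID=", genes$gene_id)
    has_prod <- !is.na(genes$product) & nzchar(genes$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              genes$product[has_prod])
    has_cog <- !is.na(genes$cog_letter) & nzchar(genes$cog_letter)
    attrs[has_cog] <- paste0(attrs[has_cog], ";cog=", genes$cog_letter[has_cog])
    writeLines(paste(genes$contig_id, source, type, genes$start, genes$end,
                     ".", genes$strand, "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a per-base kinetic track
#'
#' CSV with header `contig,position,strand,base,ipdRatio,coverage`
#' (`base` optional); `position` is 1-based; `strand` is `+`/`-`, with the
#' numeric dialect `0`/`1` of the sequencing platform's modifications.csv
#' accepted and mapped 0 to `+`, 1 to `-`. Rows with coverage 0 are dropped.
#'
#' @param path CSV file.
#' @param contig_lengths named integer vector of contig lengths; inferred
#'   from the maximum observed position per contig when `NULL`.
#' @return a [kinetic_track()].
#' @export
read_kinetics <- function(path, contig_lengths = NULL) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("contig", "position", "strand", "ipdRatio", "coverage")
  if (!all(need %in% names(df)))
    stop("kinetics CSV must have columns ", paste(need, collapse = ","))
  df$strand <- as.character(df$strand)
  map <- c("+" = "+", "-" = "-", "0" = "+", "1" = "-")
  if (!all(df$strand %in% names(map)))
    stop("unknown strand code(s): ",
         paste(unique(setdiff(df$strand, names(map))), collapse = ","))
  df$strand <- unname(map[df$strand])
  df <- df[df$coverage > 0, , drop = FALSE]
  if (nrow(df) && any(df$ipdRatio <= 0)) stop("ipdRatio <= 0 in ", path)
  key <- paste(df$contig, df$position, df$strand)
  if (anyDuplicated(key))
    stop("duplicate (contig,position,strand) rows in ", path)
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(df$position, df$contig, max)
    contig_lengths <- stats::setNames(as.integer(contig_lengths),
                                      names(contig_lengths))
  }
  track <- kinetic_track(contig_lengths)
  for (contig in unique(df$contig)) {
    for (strand in c("+", "-")) {
      sel <- df$contig == contig & df$strand == strand
      if (!any(sel)) next
      track <- track_set(track, contig, strand, df$position[sel],
                         df$ipdRatio[sel], df$coverage[sel])
    }
  }
  track
}

#' Write a kinetic track as CSV
#'
#' @param track a [kinetic_track()].
#' @param path output CSV.
#' @param genome optional named sequence vector used to fill the `base`
#'   column (forward-strand base; complemented for `-` rows). "N" when
#'   absent.
#' @export
write_kinetics <- function(track, path, genome = NULL) {
  df <- track_to_df(track)
  base <- rep("N", nrow(df))
  if (!is.null(genome) && nrow(df)) {
    for (contig in unique(df$contig)) {
      sel <- df$contig == contig
      b <- substring(genome[[contig]], df$position[sel], df$position[sel])
      neg <- df$strand[sel] == "-"
      b[neg] <- chartr("ACGTN", "TGCAN", b[neg])
      base[sel] <- b
    }
  }
  out <- data.frame(contig = df$contig, position = df$position,
                    strand = df$strand, base = base,
                    # full double precision so tracks round-trip exactly
                    ipdRatio = sprintf("%.17g", df$ipdRatio),
                    coverage = df$coverage)
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Write intervals as 6-column BED
#'
#' Internal coordinates are already 0-based half-open, so they are written
#' unchanged. For methylation-call exports the score column carries
#' ipdR x 1000 clamped to [0, 1000].
#'
#' @param intervals data.frame with `contig_id,start,end` and optional
#'   `name,score,strand` columns.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  if (!nrow(intervals)) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) {
    pmin(pmax(round(intervals$score * 1000), 0), 1000)
  } else "."
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- paste(intervals$contig_id, intervals$start, intervals$end,
                 name, score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals (e.g. TFBS predictions)
#'
#' @param path BED file (3+ columns).
#' @return data.frame with `contig_id,start,end,strand,label` (coordinates
#'   0-based half-open as in BED).
#' @export
read_bed_regions <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      label = character(), stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(
    contig_id = df[[1]], start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    strand = if (ncol(df) >= 6) df[[6]] else ".",
    label = if (ncol(df) >= 4) as.character(df[[4]]) else ".",
    stringsAsFactors = FALSE)
}

#' Read a methylated-motif list
#'
#' TSV with columns `pattern`, `meth_offset_fwd` (1-based in the file,
#' converted to 0-based internally) and `mod_type`.
#'
#' @param path TSV file.
#' @return list of motif specs (see [motif_spec()]).
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "meth_offset_fwd", "mod_type")
  if (!all(need %in% names(df)))
    stop("motif TSV must have columns ", paste(need, collapse = ","))
  lapply(seq_len(nrow(df)), function(i) {
    motif_spec(df$pattern[i], df$meth_offset_fwd[i] - 1L, df$mod_type[i])
  })
}

#' Read an MTase/REase gene table
#'
#' TSV with columns `gene_id, contig_id, start, end, strand, role`
#' (MTase/REase), `rm_type` (I/II/IIG/III/unknown), `mod_type`
#' (m6A/m4C/m5C/unknown), `specificity` (IUPAC pattern or empty).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "strand", "role")
  if (!all(need %in% names(df)))
    stop("gene table must have columns ", paste(need, collapse = ","))
  if (is.null(df$rm_type)) df$rm_type <- "unknown"
  if (is.null(df$mod_type)) df$mod_type <- "unknown"
  if (is.null(df$specificity)) df$specificity <- NA_character_
  df
}
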