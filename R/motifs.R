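# IUPAC nucleotide code machinery. N in the *genome* never matches any
# motif symbol (masked/unknown bases are not evidence); N in a *pattern*
# matches any of A/C/G/T.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern))
    stop("pattern must be a single non-empty string")
  sym <- strsplit(pattern, "")[[1]]
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ","))
  invisible(sym)
}

#' Reverse complement of an IUPAC pattern
#'
#' Ambiguity codes complement as R-Y, S-S, W-W, K-M, B-V, D-H, N-N.
#'
#' @param pattern IUPAC string.
#' @return reverse-complemented pattern.
#' @export
revcomp_iupac <- function(pattern) {
  check_iupac(pattern)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Is a motif palindromic?
#'
#' True iff the pattern equals its own reverse complement under IUPAC
#' symbol complementation (e.g. GATC, RAATTY).
#'
#' @param pattern IUPAC string.
#' @return logical.
#' @export
is_palindrome <- function(pattern) {
  identical(revcomp_iupac(pattern), pattern)
}

#' Canonical strand of a pattern
#'
#' The lexicographically smaller of a pattern and its reverse complement;
#' used when comparing predicted MTase specificities to motifs.
#'
#' @param pattern IUPAC string.
#' @return canonicalized pattern.
#' @export
canonical_pattern <- function(pattern) {
  rc <- revcomp_iupac(pattern)
  if (rc < pattern) rc else pattern
}

#' Construct a motif specification
#'
#' @param pattern IUPAC recognition sequence (length >= 2).
#' @param meth_offset_fwd 0-based index into `pattern` of the methylated
#'   base on the strand the pattern is written on.
#' @param mod_type one of `m6A`, `m4C`, `m5C`.
#' @return a `motif_spec` list with fields `pattern`, `meth_offset_fwd`,
#'   `mod_type`, and `meth_offset_rev` (0-based index of the
#'   complementary-strand methylated base; present only for palindromic
#'   double-strand motifs, where it is `length - 1 - meth_offset_fwd`).
#' @export
motif_spec <- function(pattern, meth_offset_fwd, mod_type) {
  sym <- check_iupac(pattern)
  L <- length(sym)
  if (L < 2) stop("pattern length must be >= 2")
  if (!mod_type %in% c("m6A", "m4C", "m5C"))
    stop("mod_type must be m6A, m4C or m5C")
  off <- as.integer(meth_offset_fwd)
  if (is.na(off) || off < 0 || off >= L)
    stop("meth_offset_fwd out of range")
  meth_base <- if (mod_type == "m6A") "A" else "C"
  if (!meth_base %in% IUPAC_SETS[[sym[off + 1]]])
    stop("base at meth_offset_fwd (", sym[off + 1],
         ") is incompatible with ", mod_type)
  spec <- list(pattern = pattern, meth_offset_fwd = off, mod_type = mod_type,
               meth_offset_rev = NULL)
  if (is_palindrome(pattern)) {
    rev_off <- L - 1L - off
    # complementary-strand methylated base sits opposite; its pattern
    # symbol must complement-match the methylatable base
    if (meth_base %in% IUPAC_SETS[[chartr("ACGTRYSWKMBDHVN",
                                          "TGCAYRSWMKVHDBN",
                                          sym[rev_off + 1])]])
      spec$meth_offset_rev <- rev_off
  }
  structure(spec, class = "motif_spec")
}

#' Methylatable nucleotide of a motif
#'
#' @param motif a [motif_spec()].
#' @return "A" for m6A motifs, "C" for m4C/m5C.
#' @export
meth_base <- function(motif) {
  if (motif$mod_type == "m6A") "A" else "C"
}

# Match starts (0-based) of an IUPAC pattern on a forward-strand sequence.
# Biostrings does the ambiguity-aware scan; windows containing N are then
# removed (genome N matches nothing).
scan_forward <- function(seq, pattern) {
  L <- nchar(pattern)
  if (L > nchar(seq)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                   fixed = FALSE)
  starts0 <- IRanges::start(IRanges::ranges(hits)) - 1L
  if (!length(starts0)) return(integer(0))
  win <- substring(seq, starts0 + 1L, starts0 + L)
  starts0[!grepl("N", win, fixed = TRUE)]
}

#' Locate all instances of a motif in a genome
#'
#' Scans both strands exhaustively, reporting overlapping occurrences.
#' Palindromic double-strand motifs are reported once per genomic site with
#' both strands' methylatable-base coordinates populated; non-palindromic
#' motifs yield separate `+` and `-` strand instances. All coordinates are
#' 0-based half-open on the forward strand. Motifs spanning the junction of
#' a circular genome are not detected (the scan is linear).
#'
#' @param genome named character vector of contig sequences.
#' @param motif a [motif_spec()].
#' @return data.frame with columns `contig_id,start,end,strand_of_match,
#'   meth_pos_fwd,meth_pos_rev,seq` ordered by contig then ascending start.
#' @export
find_motif_instances <- function(genome, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  L <- nchar(motif$pattern)
  rows <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    if (!is.null(motif$meth_offset_rev)) {
      s <- scan_forward(seq, motif$pattern)
      if (length(s)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig, start = s, end = s + L, strand_of_match = "+",
          meth_pos_fwd = s + motif$meth_offset_fwd,
          meth_pos_rev = s + motif$meth_offset_rev,
          seq = substring(seq, s + 1L, s + L), stringsAsFactors = FALSE)
      }
    } else {
      sf <- scan_forward(seq, motif$pattern)
      rc <- revcomp_iupac(motif$pattern)
      sr <- scan_forward(seq, rc)
      if (is_palindrome(motif$pattern)) sr <- integer(0)  # same hit set
      df <- NULL
      if (length(sf)) {
        df <- data.frame(
          contig_id = contig, start = sf, end = sf + L, strand_of_match = "+",
          meth_pos_fwd = sf + motif$meth_offset_fwd,
          meth_pos_rev = NA_integer_,
          seq = substring(seq, sf + 1L, sf + L), stringsAsFactors = FALSE)
      }
      if (length(sr)) {
        dr <- data.frame(
          contig_id = contig, start = sr, end = sr + L, strand_of_match = "-",
          meth_pos_fwd = NA_integer_,
          meth_pos_rev = sr + (L - 1L - motif$meth_offset_fwd),
          seq = substring(seq, sr + 1L, sr + L), stringsAsFactors = FALSE)
        df <- if (is.null(df)) dr else rbind(df, dr)
      }
      if (!is.null(df)) rows[[length(rows) + 1L]] <- df
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand_of_match = character(),
                      meth_pos_fwd = integer(), meth_pos_rev = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$start, out$strand_of_match), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a motif by restriction-modification system architecture
#'
#' Bipartite patterns (an internal run of >= 3 Ns separating two specific
#' sub-motifs) are Type I. Palindromic double-strand motifs are Type II.
#' Otherwise, motifs with at most 5 specific (non-N) positions are
#' Type III-like, and longer recognition sequences (6+ specific positions)
#' Type IIG-like. Degenerate symbols such as R/Y count as specific
#' positions, so RAATTY is a 6-position motif.
#'
#' @param motif a [motif_spec()].
#' @return list with `category` (one of `TypeI_bipartite`,
#'   `TypeII_palindromic`, `TypeIII_like`, `TypeIIG_like`) and `rationale`.
#' @export
classify_motif <- function(motif) {
  stopifnot(inherits(motif, "motif_spec"))
  sym <- strsplit(motif$pattern, "")[[1]]
  runs <- rle(sym == "N")
  internal <- which(runs$values)
  internal <- internal[internal > 1 & internal < length(runs$values)]
  if (any(runs$lengths[internal] >= 3)) {
    return(list(category = "TypeI_bipartite",
                rationale = "internal N-spacer >= 3 between specific halves"))
  }
  if (is_palindrome(motif$pattern) && !is.null(motif$meth_offset_rev)) {
    return(list(category = "TypeII_palindromic",
                rationale = "palindrome methylatable on both strands"))
  }
  n_specific <- sum(sym != "N")
  if (n_specific <= 5) {
    list(category = "TypeIII_like",
         rationale = sprintf("%d specific positions (<= 5)", n_specific))
  } else {
    list(category = "TypeIIG_like",
         rationale = sprintf("%d specific positions (>= 6), non-palindromic",
                             n_specific))
  }
}

#' Genome-wide mean distance between successive motif instances
#'
#' Arithmetic mean of start-to-start distances along the position-ordered
#' instance list, computed per contig.
#'
#' @param instances instance table from [find_motif_instances()].
#' @return named numeric vector, one mean per contig.
#' @export
mean_intermotif_distance <- function(instances) {
  if (nrow(instances) < 2) stop("need >= 2 instances")
  out <- vapply(split(instances$start, instances$contig_id), function(s) {
    if (length(s) < 2) stop("need >= 2 instances per contig")
    mean(diff(sort(s)))
  }, numeric(1))
  out
}
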