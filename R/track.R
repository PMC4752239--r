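#' Kinetic track container
#'
#' A kinetic track holds per-contig, per-strand vectors of ipdR
#' (inter-pulse duration ratio) and read coverage, indexed by genome
#' position. Positions without data are `NA` (explicitly absent), never zero.
#'
#' @param contig_lengths named integer vector, one entry per contig.
#' @return an empty `kinetic_track` object.
#' @export
kinetic_track <- function(contig_lengths) {
  stopifnot(length(contig_lengths) > 0, !is.null(names(contig_lengths)),
            !anyDuplicated(names(contig_lengths)), all(contig_lengths > 0))
  data <- lapply(contig_lengths, function(len) {
    list(
      "+" = list(ipdR = rep(NA_real_, len), cov = rep(NA_integer_, len)),
      "-" = list(ipdR = rep(NA_real_, len), cov = rep(NA_integer_, len))
    )
  })
  structure(list(contig_lengths = contig_lengths, data = data),
            class = "kinetic_track")
}

#' Set kinetic values on a track
#'
#' @param track a `kinetic_track`.
#' @param contig contig id.
#' @param strand `"+"` or `"-"`.
#' @param pos 1-based positions.
#' @param ipdR,cov values to store (recycled to `length(pos)`).
#' @return the modified track.
#' @export
track_set <- function(track, contig, strand, pos, ipdR, cov) {
  stopifnot(inherits(track, "kinetic_track"),
            contig %in% names(track$data), strand %in% c("+", "-"))
  len <- track$contig_lengths[[contig]]
  stopifnot(all(pos >= 1), all(pos <= len))
  track$data[[contig]][[strand]]$ipdR[pos] <- ipdR
  track$data[[contig]][[strand]]$cov[pos] <- as.integer(cov)
  track
}

#' Look up ipdR and coverage at positions
#'
#' @inheritParams track_set
#' @param pos0 0-based genome coordinates.
#' @return data.frame with columns `ipdR` and `cov`; `NA` where absent.
#' @export
track_get <- function(track, contig, strand, pos0) {
  stopifnot(inherits(track, "kinetic_track"), strand %in% c("+", "-"))
  ch <- track$data[[contig]][[strand]]
  if (is.null(ch)) stop("unknown contig: ", contig)
  idx <- pos0 + 1L
  ok <- idx >= 1L & idx <= track$contig_lengths[[contig]]
  ipdR <- rep(NA_real_, length(pos0)); cov <- rep(NA_integer_, length(pos0))
  ipdR[ok] <- ch$ipdR[idx[ok]]
  cov[ok] <- ch$cov[idx[ok]]
  data.frame(ipdR = ipdR, cov = cov)
}

#' Flatten a track to a long data.frame
#'
#' One row per position with data, columns
#' `contig,position,strand,ipdRatio,coverage` (position 1-based), the same
#' schema [read_kinetics()] accepts.
#'
#' @param track a `kinetic_track`.
#' @return data.frame.
#' @export
track_to_df <- function(track) {
  out <- list()
  for (contig in names(track$data)) {
    for (strand in c("+", "-")) {
      ch <- track$data[[contig]][[strand]]
      pos <- which(!is.na(ch$cov))
      if (!length(pos)) next
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, position = pos, strand = strand,
        ipdRatio = ch$ipdR[pos], coverage = ch$cov[pos],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), position = integer(),
                      strand = character(), ipdRatio = numeric(),
                      coverage = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$position, df$strand), , drop = FALSE]
}
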