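# Interval arithmetic helpers. All package-facing coordinates are 0-based
# half-open (BED convention); GRanges used internally are 1-based closed, so
# conversion is start + 1 on the way in and start - 1 on the way out.

#' Convert a 0-based half-open interval data.frame to GRanges
#' @param df data.frame with chrom, start, end (and any extra columns kept as
#'   metadata).
#' @param seqlevels Optional character vector of sequence levels to impose
#'   (so paired GRanges share a seqinfo and comparisons stay silent).
#' @return A \code{GRanges}.
#' @keywords internal
intervals_to_gr <- function(df, seqlevels = NULL) {
  seqnames <- if (is.null(seqlevels)) df$chrom else
    factor(df$chrom, levels = seqlevels)
  gr <- GenomicRanges::GRanges(
    seqnames = seqnames,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(colnames(df), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- df[extra]
  }
  gr
}

#' Convert GRanges back to a 0-based half-open data.frame
#' @param gr A \code{GRanges}.
#' @return data.frame with chrom, start, end plus metadata columns.
#' @keywords internal
gr_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Which query intervals overlap any subject interval by >= 1 bp
#' @param query,subject data.frames of 0-based half-open intervals.
#' @return logical vector over query rows.
#' @keywords internal
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical())
  lev <- union(query$chrom, subject$chrom)
  GenomicRanges::countOverlaps(intervals_to_gr(query, lev),
                               intervals_to_gr(subject, lev)) > 0L
}

#' Minimum gap between each query interval and the nearest subject interval
#'
#' Gap is 0 for overlapping or abutting intervals and Inf when the subject is
#' empty or on another chromosome.
#' @param query,subject data.frames of 0-based half-open intervals.
#' @return numeric vector over query rows.
#' @keywords internal
min_gap <- function(query, subject) {
  out <- rep(Inf, nrow(query))
  if (nrow(subject) == 0L || nrow(query) == 0L) return(out)
  lev <- union(query$chrom, subject$chrom)
  qgr <- intervals_to_gr(query, lev)
  sgr <- intervals_to_gr(subject, lev)
  hits <- GenomicRanges::distanceToNearest(qgr, sgr)
  out[S4Vectors::queryHits(hits)] <- as.numeric(S4Vectors::mcols(hits)$distance)
  out
}
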