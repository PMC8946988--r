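# Super-enhancer calling in the ROSE style: stitch active enhancer peaks
# within a fixed distance, rank stitched regions by total signal, and place
# the hockey-stick cutoff where the slope of the scaled rank/signal curve
# reaches 1.

#' Stitch enhancer peaks into regions
#'
#' Peaks on the same chromosome separated by at most \code{stitch_dist} bp
#' are merged transitively. Peaks falling fully inside a TSS-exclusion
#' window (e.g. promoters) are removed before stitching. Each stitched
#' region carries the summed signal of its member peaks and a unique rank
#' (1 = highest total signal).
#'
#' @param peaks A \code{peak_set} (typically active-mark peaks intersected
#'   with accessibility, via [intersect_peak_sets()]).
#' @param stitch_dist Maximum gap merged, in bp (default 12500).
#' @param tss_exclusion Optional \code{promoter_table}; member peaks fully
#'   contained in any window are dropped first.
#' @return A \code{stitched_regions} data.frame: chrom, start, end,
#'   total_signal, rank, is_super (NA until [call_super()]).
#' @export
stitch <- function(peaks, stitch_dist = 12500, tss_exclusion = NULL) {
  if (stitch_dist < 0) stop("stitch_dist must be >= 0")
  iv <- peaks$intervals
  if (!is.null(tss_exclusion) && nrow(iv) > 0L) {
    lev <- union(iv$chrom, tss_exclusion$chrom)
    gr <- intervals_to_gr(iv, lev)
    ex <- intervals_to_gr(tss_exclusion, lev)
    inside <- IRanges::overlapsAny(gr, ex, type = "within")
    iv <- iv[!inside, , drop = FALSE]
  }
  if (nrow(iv) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      total_signal = numeric(), rank = integer(),
                      is_super = logical())
    class(out) <- c("stitched_regions", "data.frame")
    return(out)
  }
  gr <- intervals_to_gr(iv)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = stitch_dist + 1)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  total <- numeric(length(merged))
  agg <- tapply(iv$signal[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
  total[as.integer(names(agg))] <- agg
  out <- gr_to_intervals(merged)
  out$total_signal <- total
  out$rank <- as.integer(rank(-total, ties.method = "first"))
  out$is_super <- NA
  class(out) <- c("stitched_regions", "data.frame")
  out
}

#' Call super-enhancers with the tangent (hockey-stick) cutoff
#'
#' Regions are sorted by ascending total signal; ranks and signals are
#' scaled to [0, 1] and the cutoff is placed at the point where the slope of
#' the scaled curve reaches 1 (the tangent point, i.e. the last minimum of
#' scaled signal minus scaled rank). Regions with signal strictly above the
#' cutoff are super-enhancers.
#'
#' @param regions A \code{stitched_regions} table with >= 3 rows.
#' @param method Only "tangent" is implemented.
#' @return The table with \code{is_super} filled in.
#' @export
call_super <- function(regions, method = "tangent") {
  method <- match.arg(method, "tangent")
  if (nrow(regions) < 3) stop("need >= 3 stitched regions")
  s <- sort(regions$total_signal)
  rng <- s[length(s)] - s[1]
  if (rng <= 0) {
    warning("all stitched regions have equal signal; no super-enhancers")
    regions$is_super <- FALSE
    return(regions)
  }
  x <- (seq_along(s) - 1) / (length(s) - 1)
  y <- (s - s[1]) / rng
  d <- y - x
  j <- max(which(d <= min(d) + 1e-12))
  cutoff <- s[j]
  regions$is_super <- regions$total_signal > cutoff
  regions
}

#' Associate genes with super-enhancers
#'
#' Three modes: \code{inside} (promoter overlaps a super-enhancer by >= 1
#' bp), \code{within50kb} (gap between promoter and nearest super-enhancer
#' <= 50 kb), and \code{linked} (enhancer-gene link rows with score strictly
#' greater than \code{link_min_score} whose enhancer interval overlaps a
#' super-enhancer).
#'
#' @param supers A \code{stitched_regions} table after [call_super()] (only
#'   rows with \code{is_super} are used).
#' @param promoters A \code{promoter_table}.
#' @param links An \code{enhancer_links} table (required for
#'   \code{mode = "linked"}).
#' @param mode One of "inside", "within50kb", "linked".
#' @param link_min_score Strict lower bound on the link score (default 1).
#' @param max_dist Distance bound for \code{within50kb} (default 50000).
#' @return Sorted character vector of gene symbols.
#' @export
associate_genes <- function(supers, promoters, links = NULL,
                            mode = c("inside", "within50kb", "linked"),
                            link_min_score = 1, max_dist = 50000) {
  mode <- match.arg(mode)
  se <- supers[which(supers$is_super), , drop = FALSE]
  if (mode == "linked") {
    if (is.null(links)) stop("mode 'linked' requires an enhancer link table")
    keep <- links$score > link_min_score
    lk <- links[keep, , drop = FALSE]
    if (nrow(lk) == 0L || nrow(se) == 0L) return(character())
    hit <- overlaps_any(lk, se)
    return(sort(unique(lk$gene[hit])))
  }
  if (nrow(se) == 0L) return(character())
  if (mode == "inside") {
    hit <- overlaps_any(promoters, se)
  } else {
    hit <- min_gap(promoters, se) <= max_dist
  }
  sort(unique(promoters$gene[hit]))
}

#' Enrichment of a DE gene set for super-enhancer-associated genes
#'
#' Delegates to [hypergeometric_enrichment()] over the active-gene universe.
#'
#' @param de_genes,se_genes Character vectors within \code{active_universe}.
#' @param active_universe Character vector of active genes.
#' @return An \code{enrichment_stat}.
#' @export
se_gene_enrichment <- function(de_genes, se_genes, active_universe) {
  hypergeometric_enrichment(de_genes, se_genes, active_universe)
}
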