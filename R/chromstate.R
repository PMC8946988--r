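# Promoter windows, replicate-consensus peaks, bivalency classification and
# the association statistics used throughout the chromatin analyses.

#' Build promoter windows around primary TSSs
#'
#' Symmetric \code{width} bp windows centered on the TSS regardless of
#' strand, clipped at position 0 (0-based half-open).
#'
#' @param annotation A \code{gene_annotation}.
#' @param width Total window width in bp; must be even and positive
#'   (default 3000).
#' @return A \code{promoter_table} data.frame: gene, chrom, start, end.
#' @export
make_promoters <- function(annotation, width = 3000) {
  if (width <= 0 || width %% 2 != 0) stop("width must be positive and even")
  half <- width %/% 2
  df <- data.frame(
    gene = annotation$gene, chrom = annotation$chrom,
    start = pmax(0L, annotation$tss - half),
    end = annotation$tss + half,
    stringsAsFactors = FALSE
  )
  class(df) <- c("promoter_table", "data.frame")
  df
}

#' Replicate-consensus peaks
#'
#' For each replicate-1 peak overlapping (>= 1 bp) any replicate-2 peak, the
#' union interval of the overlapping pair is emitted; resulting overlaps are
#' merged. The rule is symmetric in effect after merging. The consensus
#' signal of a merged interval is the mean of the summed member signals of
#' the two replicates.
#'
#' @param rep1,rep2 \code{peak_set}s of the same mark.
#' @return A consensus \code{peak_set} (replicate NA).
#' @export
consensus_peaks <- function(rep1, rep2) {
  if (!identical(rep1$mark, rep2$mark)) {
    stop("replicate peak sets have different marks: ",
         rep1$mark, " vs ", rep2$mark)
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), signal = numeric())
  if (nrow(rep1$intervals) == 0L || nrow(rep2$intervals) == 0L) {
    return(peak_set(empty, mark = rep1$mark))
  }
  lev <- union(rep1$intervals$chrom, rep2$intervals$chrom)
  gr1 <- intervals_to_gr(rep1$intervals, lev)
  gr2 <- intervals_to_gr(rep2$intervals, lev)
  hits <- GenomicRanges::findOverlaps(gr1, gr2)
  if (length(hits) == 0L) return(peak_set(empty, mark = rep1$mark))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  unions <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr1)[q],
    ranges = IRanges::IRanges(
      start = pmin(GenomicRanges::start(gr1)[q], GenomicRanges::start(gr2)[s]),
      end = pmax(GenomicRanges::end(gr1)[q], GenomicRanges::end(gr2)[s])
    )
  )
  merged <- GenomicRanges::reduce(unions)
  df <- gr_to_intervals(merged)
  # signal: mean over replicates of the summed member signals per interval
  sig_for <- function(gr, signal) {
    ov <- GenomicRanges::findOverlaps(merged, gr)
    out <- numeric(length(merged))
    agg <- tapply(signal[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  df$signal <- (sig_for(gr1, rep1$intervals$signal) +
                  sig_for(gr2, rep2$intervals$signal)) / 2
  peak_set(df, mark = rep1$mark)
}

#' Intersect two peak sets (mark-pair intersection)
#'
#' Returns the peaks of \code{a} that overlap any peak of \code{b} by >= 1
#' bp, keeping \code{a}'s coordinates and signal. Used to restrict active
#' enhancer peaks to accessible chromatin before stitching.
#'
#' @param a,b \code{peak_set}s.
#' @return A \code{peak_set} with mark \code{"<a>+<b>"}.
#' @export
intersect_peak_sets <- function(a, b) {
  keep <- overlaps_any(a$intervals, b$intervals)
  peak_set(a$intervals[keep, , drop = FALSE],
           mark = paste0(a$mark, "+", b$mark))
}

#' Flag promoters overlapping any peak
#'
#' True iff the promoter window shares >= 1 bp with any peak (half-open
#' convention: a peak starting exactly at the promoter end does not count).
#'
#' @param promoters A \code{promoter_table}.
#' @param peaks A \code{peak_set}.
#' @return Named logical vector over genes.
#' @export
flag_promoter_overlap <- function(promoters, peaks) {
  out <- overlaps_any(promoters, peaks$intervals)
  names(out) <- promoters$gene
  out
}

#' Classify promoter chromatin states
#'
#' Partitions genes into bivalent (both marks), K4-only, K27-only and
#' neither, and reports the bivalent fraction among all H3K4me3-marked
#' promoters.
#'
#' @param has_k4,has_k27 Named logical vectors over the same gene universe.
#' @param universe Optional character vector restricting the universe (e.g.
#'   expressed genes); defaults to the names of \code{has_k4}.
#' @param arid1a_bound Optional named logical vector of promoter binding.
#' @return List with \code{table} (gene, has_k4, has_k27, arid1a_bound,
#'   state), \code{counts} (named 4-vector summing to the universe size) and
#'   \code{bivalent_fraction_of_k4}.
#' @export
classify_states <- function(has_k4, has_k27, universe = NULL,
                            arid1a_bound = NULL) {
  if (is.null(universe)) universe <- names(has_k4)
  if (is.null(universe)) stop("has_k4 must be named or a universe supplied")
  k4 <- unname(has_k4[universe]); k27 <- unname(has_k27[universe])
  if (any(is.na(k4)) || any(is.na(k27))) {
    stop("mark flags must cover the whole universe")
  }
  state <- ifelse(k4 & k27, "bivalent",
                  ifelse(k4, "K4-only", ifelse(k27, "K27-only", "neither")))
  bound <- if (is.null(arid1a_bound)) rep(NA, length(universe)) else
    unname(arid1a_bound[universe])
  table <- data.frame(gene = universe, has_k4 = k4, has_k27 = k27,
                      arid1a_bound = bound, state = state,
                      stringsAsFactors = FALSE)
  counts <- vapply(CHROMATIN_STATES, function(s) sum(state == s), 0L)
  n_k4_marked <- sum(k4)
  list(table = table, counts = counts,
       bivalent_fraction_of_k4 =
         if (n_k4_marked > 0) counts[["bivalent"]] / n_k4_marked else NA_real_)
}

#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail probability of observing at least the seen overlap between two
#' gene sets drawn from a finite universe.
#'
#' @param setA,setB Character vectors, both subsets of \code{universe}.
#' @param universe Character vector of all eligible genes.
#' @return An \code{enrichment_stat} list: \code{overlap}, \code{expected}
#'   (\code{|A||B|/|U|}), \code{p_hyper}, set sizes.
#' @export
hypergeometric_enrichment <- function(setA, setB, universe) {
  setA <- unique(toupper(setA)); setB <- unique(toupper(setB))
  universe <- unique(toupper(universe))
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe))) {
    stop("sets must be subsets of the universe")
  }
  overlap <- length(intersect(setA, setB))
  nU <- length(universe); nA <- length(setA); nB <- length(setB)
  p <- stats::phyper(overlap - 1, nA, nU - nA, nB, lower.tail = FALSE)
  structure(list(overlap = overlap, expected = nA * nB / nU,
                 p_hyper = p, n_a = nA, n_b = nB, n_universe = nU),
            class = "enrichment_stat")
}

#' Two-sided Fisher exact association between two binary flags
#'
#' Exact two-sided p by summing, over the conditional (hypergeometric)
#' distribution of the 2x2 table with fixed margins, the probabilities of
#' all tables no more likely than the observed one. The odds ratio is
#' computed from the table, with a 0.5 Haldane correction applied (and
#' flagged) only when a cell is zero.
#'
#' @param flagX,flagY Logical vectors of equal positive length.
#' @return An \code{enrichment_stat} list: \code{table}, \code{odds_ratio},
#'   \code{or_corrected}, \code{p_fisher}.
#' @export
fisher_association <- function(flagX, flagY) {
  if (length(flagX) == 0L || length(flagX) != length(flagY)) {
    stop("flags must be non-empty and of equal length")
  }
  tab <- table(factor(flagX, c(TRUE, FALSE)), factor(flagY, c(TRUE, FALSE)))
  p <- stats::fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(tab == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  structure(list(table = tab, odds_ratio = unname(or),
                 or_corrected = corrected, p_fisher = min(p, 1)),
            class = "enrichment_stat")
}

#' Compare expression between chromatin-state groups
#'
#' Unpaired two-sided Wilcoxon rank-sum tests between requested pairs of
#' states, with group medians. Pairs where either group has fewer than 3
#' genes yield \code{NA} with a warning.
#'
#' @param expression Named numeric vector of per-gene expression.
#' @param states Classification from [classify_states()] (or its
#'   \code{table}).
#' @param pairs List of length-2 character vectors of state names; default
#'   all pairs among the states present.
#' @return data.frame: group1, group2, n1, n2, median1, median2, statistic,
#'   pvalue.
#' @export
expression_by_state <- function(expression, states, pairs = NULL) {
  table <- if (is.data.frame(states)) states else states$table
  if (is.null(pairs)) {
    present <- intersect(CHROMATIN_STATES, unique(table$state))
    pairs <- utils::combn(present, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    g1 <- table$gene[table$state == pr[1]]
    g2 <- table$gene[table$state == pr[2]]
    x1 <- expression[g1]; x2 <- expression[g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 3 || length(x2) < 3) {
      warning("fewer than 3 genes in group '",
              pr[which.min(c(length(x1), length(x2)))], "'; p set to NA")
      W <- NA_real_; p <- NA_real_
    } else {
      wt <- stats::wilcox.test(x1, x2, alternative = "two.sided", exact = FALSE)
      W <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x1), n2 = length(x2),
               median1 = if (length(x1)) stats::median(x1) else NA_real_,
               median2 = if (length(x2)) stats::median(x2) else NA_real_,
               statistic = W, pvalue = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-sample promoter-mark versus expression test
#'
#' Binarizes each sample of a panel by the presence of any peak within the
#' window around the target TSS, then compares expression between marked and
#' unmarked samples with a two-sided Wilcoxon rank-sum test. Group means are
#' reported with t-based 95 percent confidence intervals.
#'
#' @param panel List with \code{expression} (numeric) and \code{peaks}
#'   (list of \code{peak_set}, one per sample), e.g. from
#'   [generate_crosssample_panel()].
#' @param target_chrom,target_tss Target gene location (taken from the panel
#'   when omitted).
#' @param window Total window width in bp centered on the TSS (default 6000,
#'   i.e. within 3 kb of the TSS on either side).
#' @return List with \code{marked} (logical per sample), \code{group_stats}
#'   (data.frame with n, mean, ci_lo, ci_hi per group), \code{statistic} and
#'   \code{pvalue}.
#' @export
promoter_mark_vs_expression <- function(panel, target_chrom = NULL,
                                        target_tss = NULL, window = 6000) {
  if (is.null(target_chrom)) target_chrom <- panel$target_chrom
  if (is.null(target_tss)) target_tss <- panel$target_tss
  half <- window / 2
  win <- data.frame(chrom = target_chrom,
                    start = max(0, target_tss - half), end = target_tss + half)
  marked <- vapply(panel$peaks, function(ps) {
    any(overlaps_any(ps$intervals, win))
  }, logical(1))
  for (grp in c("marked", "unmarked")) {
    n <- if (grp == "marked") sum(marked) else sum(!marked)
    if (n < 2) stop("group '", grp, "' has fewer than 2 samples")
  }
  ci <- function(x) {
    m <- mean(x)
    half_w <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    c(mean = m, ci_lo = m - half_w, ci_hi = m + half_w)
  }
  x_m <- panel$expression[marked]; x_u <- panel$expression[!marked]
  wt <- stats::wilcox.test(x_m, x_u, alternative = "two.sided", exact = FALSE)
  group_stats <- data.frame(
    group = c("marked", "unmarked"), n = c(length(x_m), length(x_u)),
    rbind(ci(x_m), ci(x_u)), stringsAsFactors = FALSE
  )
  rownames(group_stats) <- NULL
  list(marked = marked, group_stats = group_stats,
       statistic = unname(wt$statistic), pvalue = wt$p.value)
}
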