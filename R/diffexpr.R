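# Negative-binomial differential expression for the 2x2 factorial design.
# Per-gene NB log-linear model with median-of-ratios size factors,
# method-of-moments dispersion shrunk toward a fitted mean-dispersion trend,
# Wald tests on linear contrasts of the factorial coefficients, and
# covariate-weighted BH for the false discovery rate.

CONTRASTS <- c("e2_vs_ctrl", "kd_vs_ctrl", "kd+e2_vs_kd", "kd+e2_vs_e2",
               "interaction")

# contrast vectors over coefficients (intercept, e2, kd, e2:kd)
.contrast_vector <- function(contrast) {
  switch(contrast,
    "e2_vs_ctrl"   = c(0, 1, 0, 0),
    "kd_vs_ctrl"   = c(0, 0, 1, 0),
    "kd+e2_vs_kd"  = c(0, 1, 0, 1),
    "kd+e2_vs_e2"  = c(0, 0, 1, 1),
    "interaction"  = c(0, 0, 0, 1),
    stop("unknown contrast '", contrast, "'; must be one of: ",
         paste(CONTRASTS, collapse = ", "))
  )
}

#' Filter genes with low counts
#'
#' Retains genes averaging at least \code{min_mean} counts per sample, i.e.
#' total count >= \code{min_mean * n_samples} (inclusive boundary).
#'
#' @param expt A \code{count_experiment}.
#' @param min_mean Minimum mean count per sample (default 1).
#' @return Filtered \code{count_experiment}.
#' @export
filter_low_counts <- function(expt, min_mean = 1) {
  keep <- rowSums(expt$counts) >= min_mean * ncol(expt$counts)
  count_experiment(expt$counts[keep, , drop = FALSE], expt$design)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of the
#' sample's count to the gene's geometric mean, rescaled so the size factors
#' have geometric mean 1.
#'
#' @param expt A \code{count_experiment} (or a bare count matrix).
#' @return Named positive numeric vector, geometric mean 1.
#' @export
size_factors <- function(expt) {
  counts <- if (inherits(expt, "count_experiment")) expt$counts else expt
  use <- rowSums(counts == 0) == 0
  if (!any(use)) {
    stop("no gene has nonzero counts in every sample; ",
         "cannot form the median-of-ratios reference")
  }
  loggeo <- rowMeans(log(counts[use, , drop = FALSE]))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

# Method-of-moments dispersion per gene from within-cell moments of
# normalized counts, shrunk 50/50 toward a fitted trend alpha(mu) = a0 + a1/mu.
.estimate_dispersions <- function(norm_counts, cell) {
  cells <- unique(cell)
  cell_means <- vapply(cells, function(cl) {
    rowMeans(norm_counts[, cell == cl, drop = FALSE])
  }, numeric(nrow(norm_counts)))
  cell_vars <- vapply(cells, function(cl) {
    apply(norm_counts[, cell == cl, drop = FALSE], 1, stats::var)
  }, numeric(nrow(norm_counts)))
  # per-cell alpha estimates (var - mean) / mean^2, averaged over cells
  a_cell <- (cell_vars - cell_means) / pmax(cell_means, 1e-8)^2
  a_cell[cell_means <= 0] <- NA
  alpha_mom <- pmax(0, rowMeans(a_cell, na.rm = TRUE))
  alpha_mom[!is.finite(alpha_mom)] <- 0
  mu <- rowMeans(norm_counts)

  # trend fit on genes with informative estimates
  use <- alpha_mom > 0 & mu > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(alpha_mom[use] ~ I(1 / mu[use]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(mean(alpha_mom[use]), 0.01)
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  alpha <- pmin(pmax(0.5 * alpha_mom + 0.5 * trend, 1e-8), 10)
  list(alpha = alpha, trend = c(a0 = a0, a1 = a1), mu = mu)
}

#' Fit the full-factorial NB model to every gene
#'
#' Fits, per gene, a negative-binomial log-linear model with design
#' \code{~ e2 * kd} and offset \code{log(size factor)}, holding the gene's
#' dispersion fixed at the trend-shrunken method-of-moments estimate.
#'
#' @param expt A filtered \code{count_experiment} with >= 2 replicates per
#'   design cell.
#' @param sf Size factors (computed with [size_factors()] if NULL).
#' @return Object of class \code{factorial_fit}: per-gene coefficients (log2),
#'   their covariance matrices, dispersions and base means.
#' @export
fit_factorial <- function(expt, sf = NULL) {
  design <- expt$design
  cell <- paste(design$knockdown, design$treatment, sep = ".")
  if (any(table(cell) < 2)) stop("every design cell needs >= 2 replicates")
  if (is.null(sf)) sf <- size_factors(expt)
  counts <- expt$counts
  norm_counts <- sweep(counts, 2, sf, "/")
  disp <- .estimate_dispersions(norm_counts, cell)

  x_e2 <- as.numeric(design$treatment == "e2")
  x_kd <- as.numeric(design$knockdown == "kd")
  X <- cbind(intercept = 1, e2 = x_e2, kd = x_kd, e2kd = x_e2 * x_kd)
  off <- log(sf)

  n_genes <- nrow(counts)
  beta <- matrix(NA_real_, n_genes, 4,
                 dimnames = list(rownames(counts), colnames(X)))
  vcovs <- array(NA_real_, c(n_genes, 4, 4))
  ok <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, family = MASS::negative.binomial(theta = 1 / disp$alpha[g]),
        offset = off
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || any(!is.finite(fit$coefficients))) next
    # observed-information covariance of the natural-log coefficients
    w <- fit$weights
    XtWX <- crossprod(X * w, X)
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V))) next
    beta[g, ] <- fit$coefficients / log(2)
    vcovs[g, , ] <- V / log(2)^2
    ok[g] <- TRUE
  }
  structure(list(beta = beta, vcov = vcovs, ok = ok,
                 dispersion = disp$alpha, trend = disp$trend,
                 base_mean = rowMeans(norm_counts), sf = sf,
                 genes = rownames(counts)),
            class = "factorial_fit")
}

#' Wald test for a named contrast of the factorial model
#'
#' @param expt A filtered \code{count_experiment}, or a \code{factorial_fit}
#'   from [fit_factorial()] (cheaper when testing several contrasts).
#' @param contrast One of \code{"e2_vs_ctrl"}, \code{"kd_vs_ctrl"},
#'   \code{"kd+e2_vs_kd"}, \code{"kd+e2_vs_e2"}, \code{"interaction"}.
#' @param sf Size factors (ignored when a fit is supplied).
#' @param fdr_bins Covariate bins for [weighted_fdr()] on the base mean
#'   (1 gives plain Benjamini-Hochberg).
#' @param fdr_alpha Target level used by the weight search.
#' @return A \code{de_result} data.frame: gene, base_mean, log2fc, se, stat,
#'   pvalue, qvalue; the contrast name is kept in attribute
#'   \code{"contrast"}.
#' @export
fit_contrast <- function(expt, contrast, sf = NULL, fdr_bins = 5,
                         fdr_alpha = 1e-4) {
  cvec <- .contrast_vector(contrast)
  fit <- if (inherits(expt, "factorial_fit")) expt else fit_factorial(expt, sf)
  lfc <- as.numeric(fit$beta %*% cvec)
  se <- vapply(seq_along(lfc), function(g) {
    sqrt(max(c(cvec %*% fit$vcov[g, , ] %*% cvec), 0))
  }, 0.0)
  stat <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  # genes where the GLM failed carry no evidence
  bad <- !fit$ok | !is.finite(pvalue)
  lfc[bad] <- 0; se[bad] <- NA; stat[bad] <- 0; pvalue[bad] <- 1
  qvalue <- weighted_fdr(pvalue, fit$base_mean, n_bins = fdr_bins,
                         alpha = fdr_alpha)
  res <- data.frame(gene = fit$genes, base_mean = fit$base_mean,
                    log2fc = lfc, se = se, stat = stat,
                    pvalue = pvalue, qvalue = qvalue,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' Covariate-weighted Benjamini-Hochberg correction
#'
#' Approximates independent hypothesis weighting: hypotheses are binned by
#' covariate quantiles, non-negative bin weights with mean 1 are selected
#' from a grid to maximize rejections at level \code{alpha}, and BH step-up
#' is applied globally to \code{p / w}. With \code{n_bins = 1} this is
#' exactly plain BH. The uniform weight vector is always a grid candidate,
#' so the procedure never rejects fewer hypotheses than plain BH at
#' \code{alpha}.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @param covariate Finite covariate (e.g. base mean), same length.
#' @param n_bins Number of quantile bins (default 5).
#' @param alpha Target level the weight search optimizes (default 0.05).
#' @return Adjusted q-values, same length as \code{pvalues}.
#' @export
weighted_fdr <- function(pvalues, covariate, n_bins = 5, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || any(is.na(pvalues))) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  if (length(covariate) != length(pvalues) || any(!is.finite(covariate))) {
    stop("covariate must be finite and match the p-values in length")
  }
  if (n_bins < 1) stop("n_bins must be >= 1")
  breaks <- unique(stats::quantile(covariate, probs = seq(0, 1,
                                                          length.out = n_bins + 1)))
  if (length(breaks) < 2) {
    bin <- rep(1L, length(pvalues))
  } else {
    bin <- as.integer(cut(covariate, breaks, include.lowest = TRUE))
  }
  k <- max(bin)
  if (k == 1L) return(stats::p.adjust(pvalues, method = "BH"))

  grid_vals <- c(0, 0.5, 1, 1.5, 2)
  cand <- as.matrix(expand.grid(rep(list(grid_vals), k)))
  cand <- cand[abs(rowMeans(cand) - 1) < 1e-9, , drop = FALSE]
  uniform <- matrix(1, 1, k)
  cand <- rbind(uniform, cand[rowSums(cand != 1) > 0, , drop = FALSE])

  n <- length(pvalues)
  rejections <- apply(cand, 1, function(w) {
    pw <- ifelse(w[bin] > 0, pmin(pvalues / w[bin], 1), 1)
    sum(stats::p.adjust(pw, method = "BH") <= alpha)
  })
  w_best <- cand[which.max(rejections), ]
  pw <- ifelse(w_best[bin] > 0, pmin(pvalues / w_best[bin], 1), 1)
  stats::p.adjust(pw, method = "BH")
}

#' Pseudocount log2 transform of normalized counts
#'
#' \code{log2(count / sf + 4)}: a fixed-pseudocount stand-in for a shrinkage
#' regularized-log transform, adequate for variance ranking, clustering and
#' heatmaps (its only uses here). A zero count maps to exactly 2.
#'
#' @param expt A \code{count_experiment}.
#' @param sf Size factors (computed if NULL).
#' @param pseudocount Added inside the log (default 4).
#' @return Numeric gene x sample matrix.
#' @export
rlog_like <- function(expt, sf = NULL, pseudocount = 4) {
  if (is.null(sf)) sf <- size_factors(expt)
  log2(sweep(expt$counts, 2, sf, "/") + pseudocount)
}

#' Select variable genes by row variance
#'
#' Exactly one of the two modes must be chosen: a strict variance threshold
#' (\code{min_variance}), or the top \code{top_n} genes by variance.
#'
#' @param mat Numeric gene x sample matrix with rownames.
#' @param min_variance Strict lower variance bound (threshold mode).
#' @param top_n Number of genes to keep (top-N mode), variance-sorted.
#' @return Character vector of gene names.
#' @export
select_variable_genes <- function(mat, min_variance = NULL, top_n = NULL) {
  if (is.null(min_variance) == is.null(top_n)) {
    stop("set exactly one of min_variance or top_n")
  }
  if (any(!is.finite(mat))) stop("matrix must be finite")
  v <- apply(mat, 1, stats::var)
  if (!is.null(min_variance)) {
    names(v)[v > min_variance]
  } else {
    names(sort(v, decreasing = TRUE))[seq_len(min(top_n, length(v)))]
  }
}

#' Principal component analysis of samples
#'
#' Projects samples on the principal components of the \code{top_n} most
#' variable genes (rows centered).
#'
#' @param mat Numeric gene x sample matrix (e.g. from [rlog_like()]).
#' @param top_n Number of top-variance genes used (default 500).
#' @return List with \code{coords} (sample x PC matrix) and
#'   \code{explained} (non-increasing variance fractions summing to <= 1).
#' @export
pca_samples <- function(mat, top_n = 500) {
  if (ncol(mat) < 2) stop("need >= 2 samples")
  if (nrow(mat) < 2) stop("need >= 2 genes")
  genes <- select_variable_genes(mat, top_n = top_n)
  sub <- mat[genes, , drop = FALSE]
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, explained = explained)
}
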