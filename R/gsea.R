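# Gene-set enrichment: weighted Kolmogorov-Smirnov-style running-sum
# enrichment scores with gene-set permutation nulls and sign-matched
# normalization (NES). Gene-set (label) permutation is used rather than
# phenotype permutation: with 3 replicates per condition only 20 distinct
# phenotype relabelings exist, too few for a usable null.

#' Rank genes by a differential-expression statistic
#'
#' Descending order; ties are broken by gene symbol so the ranking is fully
#' deterministic.
#'
#' @param de A \code{de_result}.
#' @param stat "wald" (default) or "log2fc".
#' @return A \code{ranked_list} data.frame: gene, stat.
#' @export
rank_genes <- function(de, stat = c("wald", "log2fc")) {
  stat <- match.arg(stat)
  values <- if (stat == "wald") de$stat else de$log2fc
  if (any(!is.finite(values))) stop("ranking statistic must be finite")
  if (anyDuplicated(de$gene)) stop("duplicate gene symbols")
  ord <- order(-values, de$gene)
  out <- data.frame(gene = de$gene[ord], stat = values[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Fast enrichment score from sorted hit indices. The running sum is
# piecewise linear with constant miss decrement, so its extrema occur just
# after a hit (candidates for the maximum) or just before a hit / at the end
# (candidates for the minimum).
.es_from_hits <- function(w_abs, hit_idx, N) {
  k <- length(hit_idx)
  hw <- w_abs[hit_idx]
  NR <- sum(hw)
  inc <- if (NR > 0) cumsum(hw) / NR else cumsum(rep(1 / k, k))
  miss_dec <- if (N > k) 1 / (N - k) else 0
  at_hit <- inc - (hit_idx - seq_len(k)) * miss_dec
  before_hit <- c(0, inc[-k]) - (hit_idx - seq_len(k)) * miss_dec
  pos <- max(at_hit, 0)
  neg <- min(before_hit, 0)
  if (pos >= -neg) pos else neg
}

#' Running-sum enrichment score
#'
#' Classic weighted KS-style statistic: walking down the ranked list, set
#' members increment the running sum proportionally to
#' \code{|stat|^p} (normalized over members) and non-members decrement it by
#' \code{1 / (N - n_set)}; the score is the signed maximum deviation from
#' zero (positive deviation wins ties).
#'
#' @param ranked A \code{ranked_list}.
#' @param gene_set Character vector of member symbols.
#' @param p Weighting exponent (default 1; 0 gives the unweighted KS walk).
#' @return List with \code{es}, \code{running} (length-N walk), and
#'   \code{hits} (logical over the ranking).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hits <- ranked$gene %in% toupper(gene_set)
  if (!any(hits)) stop("no gene-set member present in the ranked list")
  N <- nrow(ranked)
  k <- sum(hits)
  w <- abs(ranked$stat)^p
  NR <- sum(w[hits])
  inc <- numeric(N)
  inc[hits] <- if (NR > 0) w[hits] / NR else 1 / k
  inc[!hits] <- if (N > k) -1 / (N - k) else 0
  running <- cumsum(inc)
  pos <- max(running, 0)
  neg <- min(running, 0)
  es <- if (pos >= -neg) pos else neg
  list(es = es, running = running, hits = hits)
}

#' Gene-set enrichment with permutation-normalized scores
#'
#' For each set, the enrichment score is compared against a null of random
#' same-size gene sets. NES is the score divided by the mean magnitude of
#' sign-matched null scores; the empirical p-value is the sign-matched tail
#' fraction (with the +1 continuity correction), and q-values are BH across
#' sets.
#'
#' @param ranked A \code{ranked_list}.
#' @param collection A \code{gene_set_collection}.
#' @param n_perm Number of gene-set permutations (>= 100; default 1000).
#' @param p Weighting exponent passed to the score.
#' @param seed Integer seed (fixed seed gives identical output).
#' @return data.frame: set, size, es, nes, pvalue, qvalue.
#' @export
gsea_nes <- function(ranked, collection, n_perm = 1000, p = 1, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- nrow(ranked)
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), 0L)
  if (any(lengths(collection) > N)) stop("gene set larger than the universe")
  if (any(sizes == 0L)) {
    stop("gene set(s) with no member in the ranked list: ",
         paste(names(collection)[sizes == 0L], collapse = ", "))
  }
  set.seed(seed)
  w_abs <- abs(ranked$stat)^p

  es_obs <- vapply(collection, function(s) {
    enrichment_score(ranked, s, p = p)$es
  }, 0.0)

  # one null per distinct set size, shared across sets of that size
  nulls <- lapply(unique(sizes), function(k) {
    vapply(seq_len(n_perm), function(i) {
      idx <- sort(sample.int(N, k))
      .es_from_hits(w_abs, idx, N)
    }, 0.0)
  })
  names(nulls) <- as.character(unique(sizes))

  nes <- pvalue <- numeric(length(collection))
  for (i in seq_along(collection)) {
    null_es <- nulls[[as.character(sizes[i])]]
    same <- null_es[sign(null_es) == sign(es_obs[i])]
    if (length(same) == 0L) {
      nes[i] <- NA_real_; pvalue[i] <- 1 / (n_perm + 1)
    } else {
      nes[i] <- es_obs[i] / mean(abs(same))
      pvalue[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    }
  }
  data.frame(set = names(collection), size = sizes, es = es_obs, nes = nes,
             pvalue = pvalue,
             qvalue = stats::p.adjust(pvalue, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}
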