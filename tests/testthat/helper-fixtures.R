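# Fixture builders and independent brute-force oracles used across tests.

# minimal de_result with just the fields the classifiers consume
make_de <- function(genes, log2fc, qvalue) {
  df <- data.frame(gene = genes, base_mean = 100, log2fc = log2fc,
                   se = 0.1, stat = log2fc / 0.1, pvalue = qvalue,
                   qvalue = qvalue, stringsAsFactors = FALSE)
  class(df) <- c("de_result", "data.frame")
  df
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                             max_w = 500) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_w, n, replace = TRUE),
             signal = runif(n, 0.5, 5), stringsAsFactors = FALSE)
}

# O(n*m) all-pairs overlap oracle for 0-based half-open intervals
brute_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# brute-force consensus: for each rep1 peak, union with every overlapping
# rep2 peak, then merge overlapping unions by sort-and-scan
brute_consensus <- function(iv1, iv2) {
  unions <- list()
  for (i in seq_len(nrow(iv1))) {
    for (j in seq_len(nrow(iv2))) {
      if (iv1$chrom[i] == iv2$chrom[j] &&
          iv1$start[i] < iv2$end[j] && iv1$end[i] > iv2$start[j]) {
        unions[[length(unions) + 1]] <- data.frame(
          chrom = iv1$chrom[i],
          start = min(iv1$start[i], iv2$start[j]),
          end = max(iv1$end[i], iv2$end[j]))
      }
    }
  }
  if (!length(unions)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  merge_sorted(do.call(rbind, unions), gap = 0)
}

# merge intervals whose gap is <= gap (transitive closure by sort-and-scan)
merge_sorted <- function(df, gap) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- df[1, c("chrom", "start", "end")]
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      k <- nrow(out)
      if (df$chrom[i] == out$chrom[k] && df$start[i] - out$end[k] <= gap) {
        out$end[k] <- max(out$end[k], df$end[i])
      } else {
        out <- rbind(out, df[i, c("chrom", "start", "end")])
      }
    }
  }
  rownames(out) <- NULL
  out
}

# plain O(N) re-walk of the enrichment running sum
brute_es <- function(stats, hits, p = 1) {
  N <- length(stats)
  k <- sum(hits)
  w <- abs(stats)^p
  nr <- sum(w[hits])
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) w[i] / nr else -1 / (N - k)
    if (abs(run) > abs(best) ||
        (abs(run) == abs(best) && run > best)) best <- run
  }
  best
}

# exact hypergeometric upper tail by direct enumeration
brute_hyper_p <- function(overlap, nA, nB, nU) {
  ks <- max(0, nA + nB - nU):min(nA, nB)
  probs <- choose(nA, ks) * choose(nU - nA, nB - ks) / choose(nU, nB)
  sum(probs[ks >= overlap])
}

# exact two-sided Fisher p: sum of conditional table probabilities no more
# likely than the observed table
brute_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  as <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(as, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
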