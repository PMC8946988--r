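test_that("promoter windows are symmetric, clipped and validated", {
  ann <- as_annotation(data.frame(gene = c("A", "B"), chrom = "chr1",
                                  strand = c("+", "-"), tss = c(1000, 500)))
  prom <- make_promoters(ann, width = 3000)
  expect_equal(prom$start, c(0, 0))    # clipped at 0
  expect_equal(prom$end, c(2500, 2000))
  prom2 <- make_promoters(ann, width = 200)
  expect_equal(prom2$end - prom2$start, c(200, 200))
  expect_error(make_promoters(ann, width = 301), "even")
  expect_error(make_promoters(ann, width = 0), "positive")
})

test_that("overlap flags obey the half-open boundary convention", {
  prom <- structure(data.frame(gene = "A", chrom = "chr1",
                               start = 1000, end = 2000),
                    class = c("promoter_table", "data.frame"))
  touch_end <- peak_set(data.frame(chrom = "chr1", start = 2000, end = 2100,
                                   signal = 1), "X")
  one_bp <- peak_set(data.frame(chrom = "chr1", start = 1999, end = 2100,
                                signal = 1), "X")
  other_chrom <- peak_set(data.frame(chrom = "chr2", start = 1500, end = 1600,
                                     signal = 1), "X")
  expect_false(flag_promoter_overlap(prom, touch_end)[["A"]])
  expect_true(flag_promoter_overlap(prom, one_bp)[["A"]])
  expect_false(flag_promoter_overlap(prom, other_chrom)[["A"]])
})

test_that("overlap detection matches a brute-force oracle on random data", {
  set.seed(61)
  for (rep in 1:100) {
    q <- random_intervals(sample(1:20, 1))
    s <- random_intervals(sample(1:20, 1))
    expect_identical(overlaps_any(q, s), brute_overlaps_any(q, s))
  }
})

test_that("consensus peaks match a hand-worked example and signal rule", {
  r1 <- peak_set(data.frame(chrom = "chr1", start = 100, end = 300,
                            signal = 4), "H3K4me3", 1)
  r2 <- peak_set(data.frame(chrom = "chr1", start = 250, end = 400,
                            signal = 6), "H3K4me3", 2)
  cons <- consensus_peaks(r1, r2)
  expect_equal(cons$intervals$start, 100)
  expect_equal(cons$intervals$end, 400)     # union of the overlapping pair
  expect_equal(cons$intervals$signal, 5)    # mean of 4 and 6

  # replicate-only peaks (decoys) are dropped
  r1b <- peak_set(rbind(r1$intervals,
                        data.frame(chrom = "chr2", start = 1, end = 50,
                                   signal = 9)), "H3K4me3", 1)
  expect_equal(nrow(consensus_peaks(r1b, r2)$intervals), 1)

  # disjoint replicates and empty inputs yield an empty consensus
  far <- peak_set(data.frame(chrom = "chr1", start = 5000, end = 5100,
                             signal = 1), "H3K4me3", 2)
  expect_equal(nrow(consensus_peaks(r1, far)$intervals), 0)
  empty <- peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), signal = numeric()), "H3K4me3")
  expect_equal(nrow(consensus_peaks(r1, empty)$intervals), 0)

  expect_error(consensus_peaks(r1, peak_set(r2$intervals, "ATAC")),
               "different marks")
})

test_that("consensus coordinates match the brute-force oracle on random sets", {
  set.seed(62)
  for (rep in 1:100) {
    iv1 <- random_intervals(sample(2:15, 1))
    iv2 <- random_intervals(sample(2:15, 1))
    cons <- consensus_peaks(peak_set(iv1, "M", 1), peak_set(iv2, "M", 2))
    oracle <- brute_consensus(iv1, iv2)
    got <- cons$intervals[, c("chrom", "start", "end")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("peak-set intersection keeps a's coordinates and labels the mark", {
  a <- peak_set(data.frame(chrom = "chr1", start = c(0, 1000),
                           end = c(100, 1100), signal = c(2, 3)), "H3K27ac")
  b <- peak_set(data.frame(chrom = "chr1", start = 50, end = 60, signal = 1),
                "ATAC")
  inter <- intersect_peak_sets(a, b)
  expect_equal(nrow(inter$intervals), 1)
  expect_equal(inter$intervals$start, 0)  # a's own coordinates, not clipped
  expect_equal(inter$intervals$signal, 2)
  expect_equal(inter$mark, "H3K27ac+ATAC")
})

test_that("state classification partitions the universe with exact counts", {
  k4 <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = TRUE)
  k27 <- c(A = TRUE, B = FALSE, C = TRUE, D = FALSE, E = FALSE)
  st <- classify_states(k4, k27)
  expect_equal(unname(st$counts[c("bivalent", "K4-only", "K27-only",
                                  "neither")]), c(1, 2, 1, 1))
  expect_equal(sum(st$counts), 5)
  expect_equal(st$bivalent_fraction_of_k4, 1 / 3)
  expect_equal(st$table$state[st$table$gene == "C"], "K27-only")

  # restricted universe reorders and subsets by name
  st2 <- classify_states(k4, k27, universe = c("C", "A"))
  expect_equal(st2$table$gene, c("C", "A"))
  expect_equal(sum(st2$counts), 2)
  expect_error(classify_states(k4, k27, universe = c("A", "ZZ")), "cover")
  # no K4-marked genes -> NA fraction, not division by zero
  st3 <- classify_states(c(A = FALSE), c(A = TRUE))
  expect_true(is.na(st3$bivalent_fraction_of_k4))
})

test_that("hypergeometric p matches direct enumeration on small universes", {
  u <- paste0("G", 1:10)
  A <- u[1:5]; B <- u[4:7]
  res <- hypergeometric_enrichment(A, B, u)
  expect_equal(res$overlap, 2)
  expect_equal(res$expected, 2)
  expect_equal(res$p_hyper, brute_hyper_p(2, 5, 4, 10), tolerance = 1e-12)
  # hand-worked oracle: P(X >= 2 | 5, 5, draw 4 of 10) style check with
  # a disjoint-leaning configuration
  res2 <- hypergeometric_enrichment(u[1:2], u[1:2], u)
  expect_equal(res2$p_hyper, brute_hyper_p(2, 2, 2, 10), tolerance = 1e-12)
  expect_equal(res2$p_hyper, 1 / choose(10, 2) * 1, tolerance = 1e-12)
  expect_error(hypergeometric_enrichment(c("G1", "ZZ"), B, u), "subsets")
})

test_that("Fisher association matches the exact enumeration oracle", {
  # [[2,0],[0,2]]: two-sided p = 1/3 by hand
  res <- fisher_association(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p_fisher, 1 / 3, tolerance = 1e-12)
  expect_true(res$or_corrected)  # zero cells -> Haldane correction
  expect_equal(res$odds_ratio, (2.5 * 2.5) / (0.5 * 0.5))

  set.seed(63)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(c(TRUE, FALSE), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tab <- table(factor(x, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
    res <- fisher_association(x, y)
    expect_equal(res$p_fisher,
                 brute_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
    if (all(tab > 0)) {
      expect_equal(res$odds_ratio,
                   tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
      expect_false(res$or_corrected)
    }
  }
  expect_error(fisher_association(logical(0), logical(0)), "non-empty")
})

test_that("expression-by-state compares groups with Wilcoxon and guards size", {
  expr <- c(setNames(rnorm(20, 10), paste0("B", 1:20)),
            setNames(rnorm(20, 0), paste0("N", 1:20)))
  tab <- data.frame(gene = names(expr),
                    state = rep(c("bivalent", "neither"), each = 20),
                    stringsAsFactors = FALSE)
  res <- expression_by_state(expr, tab,
                             pairs = list(c("bivalent", "neither")))
  expect_equal(res$n1, 20)
  expect_lt(res$pvalue, 1e-5)
  expect_gt(res$median1, res$median2)
  ref <- wilcox.test(expr[1:20], expr[21:40], exact = FALSE)
  expect_equal(res$pvalue, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))

  tiny <- data.frame(gene = names(expr)[1:22],
                     state = c(rep("bivalent", 2), rep("neither", 20)),
                     stringsAsFactors = FALSE)
  expect_warning(res2 <- expression_by_state(expr, tiny,
                                             pairs = list(c("bivalent",
                                                            "neither"))),
                 "fewer than 3")
  expect_true(is.na(res2$pvalue))
})

test_that("cross-sample promoter test flags samples and reports CIs", {
  panel <- generate_crosssample_panel(n_samples = 40, n_marked = 15,
                                      expression_ratio = 0.2, seed = 64)
  res <- promoter_mark_vs_expression(panel)
  expect_identical(res$marked, panel$marked)
  expect_lt(res$pvalue, 0.01)
  gs <- res$group_stats
  expect_equal(gs$n, c(15, 25))
  expect_true(all(gs$ci_lo < gs$mean & gs$mean < gs$ci_hi))
  # marked samples express less (silenced target)
  expect_lt(gs$mean[gs$group == "marked"], gs$mean[gs$group == "unmarked"])
  ref <- wilcox.test(panel$expression[panel$marked],
                     panel$expression[!panel$marked], exact = FALSE)
  expect_equal(res$pvalue, ref$p.value)
})
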