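make_expt <- function(counts) {
  n <- ncol(counts)
  reps <- n / 4
  design <- data.frame(
    sample_id = colnames(counts),
    knockdown = rep(c("ctrl", "kd"), each = n / 2),
    treatment = rep(rep(c("veh", "e2"), each = reps), 2),
    replicate = rep(seq_len(reps), 4))
  count_experiment(counts, design)
}

test_that("low-count filtering uses an inclusive mean-1 boundary", {
  counts <- matrix(0L, 4, 12,
                   dimnames = list(paste0("G", 1:4), paste0("s", 1:12)))
  counts[2, ] <- 1L           # mean exactly 1 -> retained
  counts[3, 1] <- 11L         # total 11 over 12 samples -> removed
  counts[4, ] <- 5L
  colnames(counts) <- paste0("s", 1:12)
  expt <- make_expt(counts)
  kept <- rownames(filter_low_counts(expt)$counts)
  expect_identical(kept, c("G2", "G4"))
})

test_that("size factors reproduce the median-of-ratios oracle", {
  # identical samples
  counts <- matrix(rep(c(10L, 20L, 40L), 4), 3, 4,
                   dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(counts)), rep(1, 4))

  # sample 2 is exactly twice sample 1: hand-computed factors 1/sqrt(2), sqrt(2)
  counts2 <- cbind(s1 = c(10L, 30L, 100L), s2 = c(20L, 60L, 200L))
  rownames(counts2) <- paste0("G", 1:3)
  expect_equal(unname(size_factors(counts2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  counts2[, 1] <- 0L
  expect_error(size_factors(counts2), "nonzero")
})

test_that("size factors are gene-order invariant and scaling equivariant", {
  gt <- generate_truth(n_genes = 300, seed = 4)
  expt <- filter_low_counts(generate_counts(gt$truth, n_reps = 3, seed = 5))
  sf <- size_factors(expt)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  perm <- sample(nrow(expt$counts))
  expect_equal(size_factors(expt$counts[perm, ]), sf)
  # doubling one library doubles its factor relative to the rest
  scaled <- expt$counts
  scaled[, 1] <- scaled[, 1] * 2L
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[1] / sf[1]) / unname(sf2[2] / sf[2]), 2,
               tolerance = 1e-9)
})

test_that("weighted FDR reduces to BH and never loses rejections to it", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- weighted_fdr(p, covariate = c(1, 2, 3, 4), n_bins = 1)
  expect_equal(q, rep(0.04, 4))  # BH step-up by hand
  expect_equal(q, p.adjust(p, "BH"))

  expect_error(weighted_fdr(c(0.5, 1.2), c(1, 2)), "\\[0, 1\\]")

  # effects concentrated in the high-covariate bin: weighted >= plain BH
  set.seed(31)
  n <- 2000
  cov <- exp(rnorm(n, 5, 1))
  p <- runif(n)
  hi <- cov > quantile(cov, 0.8)
  p[hi] <- rbeta(sum(hi), 0.1, 8)
  q_w <- weighted_fdr(p, cov, n_bins = 5, alpha = 0.05)
  q_bh <- p.adjust(p, "BH")
  expect_gte(sum(q_w <= 0.05), sum(q_bh <= 0.05))

  # uniform null: rejection fraction stays near zero
  set.seed(32)
  p0 <- runif(n)
  q0 <- weighted_fdr(p0, cov, n_bins = 5, alpha = 0.05)
  expect_lte(mean(q0 <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the pseudocount log transform behaves as documented", {
  counts <- rbind(G1 = c(0L, 4L), G2 = c(1000L, 2000L))
  colnames(counts) <- c("s1", "s2")
  design <- data.frame(sample_id = c("s1", "s2"),
                       knockdown = "ctrl", treatment = c("veh", "e2"),
                       replicate = 1)
  expt <- count_experiment(counts, design)
  m <- rlog_like(expt, sf = c(s1 = 1, s2 = 1))
  expect_equal(m["G1", "s1"], 2)              # log2(0 + 4)
  expect_equal(m["G2", "s2"] - m["G2", "s1"], 1, tolerance = 0.01)
  expect_true(all(diff(m[order(m[, 1]), 1]) >= 0))
})

test_that("variable-gene selection has two exclusive, boundary-strict modes", {
  set.seed(2)
  mat <- matrix(rnorm(2000 * 6), 2000, 6,
                dimnames = list(sprintf("G%04d", 1:2000), paste0("s", 1:6)))
  mat[1, ] <- 5  # constant gene
  top <- select_variable_genes(mat, top_n = 500)
  expect_length(top, 500)
  v <- apply(mat, 1, var)
  expect_identical(top, names(sort(v, decreasing = TRUE))[1:500])
  expect_false("G0001" %in% select_variable_genes(mat, min_variance = 1e-9))
  # strict >: a gene exactly at the threshold is excluded
  thr <- v[["G0002"]]
  expect_false("G0002" %in% select_variable_genes(mat, min_variance = thr))
  expect_error(select_variable_genes(mat), "exactly one")
  expect_error(select_variable_genes(mat, min_variance = 1, top_n = 5),
               "exactly one")
})

test_that("sample PCA separates the design cells under strong effects", {
  gt <- generate_truth(n_genes = 1000, seed = 17)
  tr <- gt$truth
  # strengthen effects so the four cells separate cleanly
  de <- tr$effect_class != "null"
  tr$lfc_e2[de] <- sign(tr$lfc_e2[de]) * 2.5
  tr$lfc_kd[de] <- sign(tr$lfc_kd[de]) * 2.5
  expt <- filter_low_counts(generate_counts(tr, n_reps = 3, seed = 18))
  pca <- pca_samples(rlog_like(expt), top_n = 500)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-9)
  cell <- as.integer(factor(paste(expt$design$knockdown,
                                  expt$design$treatment)))
  sil <- cluster::silhouette(cell, dist(pca$coords[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  two <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                dimnames = list(paste0("G", 1:3), c("a", "b")))
  coords <- pca_samples(two, top_n = 3)$coords
  expect_equal(coords["a", ], coords["b", ])  # identical samples coincide
})

test_that("contrast fitting handles degenerate genes and unknown names", {
  counts <- matrix(50L, 5, 8, dimnames = list(paste0("G", 1:5),
                                              paste0("s", 1:8)))
  expt <- make_expt(counts)
  de <- fit_contrast(expt, "e2_vs_ctrl")
  expect_equal(de$log2fc, rep(0, 5))
  expect_equal(de$pvalue, rep(1, 5))
  expect_error(fit_contrast(expt, "bogus"), "unknown contrast")
})

test_that("the Wald statistic is log2fc over its standard error", {
  gt <- generate_truth(n_genes = 200, seed = 19)
  expt <- filter_low_counts(generate_counts(gt$truth, n_reps = 3, seed = 20))
  de <- fit_contrast(expt, "interaction")
  ok <- !is.na(de$se) & de$se > 0
  expect_true(any(ok))
  expect_equal(de$stat[ok], de$log2fc[ok] / de$se[ok])
  expect_true(all(de$pvalue >= 0 & de$pvalue <= 1))
})

test_that("linear contrasts reproduce planted effects in every direction", {
  gt <- generate_truth(n_genes = 1200, class_fractions =
                         c("dependent-induction" = 0.1), seed = 23)
  tr <- gt$truth
  dep <- tr$effect_class == "dependent-induction"
  tr$base_mean[dep] <- 500
  expt <- filter_low_counts(generate_counts(tr, n_reps = 3, seed = 24))
  fit <- fit_factorial(expt)
  de_e2 <- fit_contrast(fit, "e2_vs_ctrl")
  de_delta <- fit_contrast(fit, "kd+e2_vs_kd")
  de_int <- fit_contrast(fit, "interaction")
  g <- match(tr$gene[dep], de_e2$gene)
  g <- g[!is.na(g)]
  planted <- match(de_e2$gene[g], tr$gene)
  # delta contrast estimates lfc_e2 + lfc_interaction
  expect_equal(median(de_delta$log2fc[g] -
                        (tr$lfc_e2[planted] + tr$lfc_interaction[planted])),
               0, tolerance = 0.25)
  expect_equal(median(de_int$log2fc[g] - tr$lfc_interaction[planted]),
               0, tolerance = 0.25)
  expect_equal(median(de_e2$log2fc[g] - tr$lfc_e2[planted]),
               0, tolerance = 0.25)
})
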