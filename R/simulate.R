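# Synthetic data with planted ground truth. The generator emulates the
# statistical structure of a 2x2 perturbation transcriptome (estrogen
# stimulation x remodeler knockdown) together with promoter chromatin states
# and enhancer architecture, so that every downstream stage of the pipeline
# can be validated against known labels.

EFFECT_CLASSES <- c("null", "coop-up", "coop-down", "antag-up", "antag-down",
                    "dependent-induction")
CHROMATIN_STATES <- c("bivalent", "K4-only", "K27-only", "neither")
SE_MODES <- c("inside", "within50kb", "linked", "none")

#' Default planted class fractions
#'
#' Cooperative classes (opposite-signed estrogen and knockdown effects)
#' outnumber antagonistic ones roughly 64:36 among non-null genes, mirroring
#' the co-regulation structure the pipeline is designed to detect.
#' @return Named numeric vector of fractions (remainder is null).
#' @export
default_class_fractions <- function() {
  c("coop-up" = 0.05, "coop-down" = 0.05,
    "antag-up" = 0.032, "antag-down" = 0.024,
    "dependent-induction" = 0.03)
}

#' Generate per-gene ground truth and a synthetic annotation
#'
#' Plants an effect class (log2 fold changes for the two factors and their
#' interaction), an NB dispersion inversely related to the mean, a promoter
#' chromatin state, promoter binding of the remodeler, and a super-enhancer
#' association mode for each gene. Genes are laid out on four synthetic
#' chromosomes with 150 kb TSS spacing so promoter windows and enhancer
#' clusters of neighboring genes cannot collide.
#'
#' @param n_genes Number of genes (>= 50).
#' @param class_fractions Named fractions over non-null effect classes;
#'   must sum to <= 1 (remainder null). Allocation is exact:
#'   \code{round(fraction * n_genes)} genes per class.
#' @param state_fractions Named fractions for chromatin states bivalent /
#'   K4-only / K27-only (remainder neither).
#' @param bound_fraction Fraction of genes with planted remodeler promoter
#'   binding.
#' @param se_fractions Named fractions for super-enhancer modes inside /
#'   within50kb / linked (remainder none).
#' @param se_bias_to_de Sampling weight multiplier that biases super-enhancer
#'   modes toward genes with a non-null effect class (1 = independent).
#' @param seed Integer seed; the full truth is reproducible from it.
#' @return List with \code{truth} (data.frame, one row per gene) and
#'   \code{annotation} (a \code{gene_annotation}).
#' @export
generate_truth <- function(n_genes = 2000,
                           class_fractions = default_class_fractions(),
                           state_fractions = c("bivalent" = 0.05,
                                               "K4-only" = 0.55,
                                               "K27-only" = 0.08),
                           bound_fraction = 0.2,
                           se_fractions = c("inside" = 0.02,
                                            "within50kb" = 0.03,
                                            "linked" = 0.05),
                           se_bias_to_de = 1,
                           seed = 1) {
  if (n_genes < 50) stop("n_genes must be >= 50")
  if (sum(class_fractions) > 1 + 1e-12) stop("class fractions sum to > 1")
  if (sum(state_fractions) > 1 + 1e-12) stop("state fractions sum to > 1")
  if (sum(se_fractions) > 1 + 1e-12) stop("se fractions sum to > 1")
  bad <- setdiff(names(class_fractions), setdiff(EFFECT_CLASSES, "null"))
  if (length(bad)) stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  set.seed(seed)

  gene <- sprintf("SYNG%05d", seq_len(n_genes))
  chrom <- paste0("chrS", ((seq_len(n_genes) - 1L) %% 4L) + 1L)
  idx_on_chrom <- ((seq_len(n_genes) - 1L) %/% 4L)
  tss <- as.integer(200000L + idx_on_chrom * 150000L)
  strand <- rep(c("+", "-"), length.out = n_genes)
  annotation <- as_annotation(data.frame(gene = gene, chrom = chrom,
                                         strand = strand, tss = tss))

  # effect classes: exact allocation in index blocks (genes are exchangeable;
  # base means and states are drawn independently of position)
  n_per_class <- round(class_fractions * n_genes)
  if (sum(n_per_class) > n_genes) stop("class fractions sum to > 1")
  effect_class <- rep("null", n_genes)
  pos <- 1L
  for (cl in names(n_per_class)) {
    k <- n_per_class[[cl]]
    if (k > 0) effect_class[pos:(pos + k - 1L)] <- cl
    pos <- pos + k
  }

  base_mean <- stats::rlnorm(n_genes, meanlog = 5, sdlog = 1.5)
  dispersion <- pmin(0.4, 0.05 + 10 / base_mean)

  mag <- function(n) stats::runif(n, 1, 2)
  lfc_e2 <- numeric(n_genes)
  lfc_kd <- numeric(n_genes)
  lfc_interaction <- numeric(n_genes)
  for (cl in setdiff(EFFECT_CLASSES, "null")) {
    i <- which(effect_class == cl)
    if (!length(i)) next
    switch(cl,
      "coop-up"   = { lfc_e2[i] <-  mag(length(i)); lfc_kd[i] <- -mag(length(i)) },
      "coop-down" = { lfc_e2[i] <- -mag(length(i)); lfc_kd[i] <-  mag(length(i)) },
      "antag-up"  = { lfc_e2[i] <-  mag(length(i)); lfc_kd[i] <-  mag(length(i)) },
      "antag-down"= { lfc_e2[i] <- -mag(length(i)); lfc_kd[i] <- -mag(length(i)) },
      "dependent-induction" = {
        lfc_e2[i] <- mag(length(i))
        lfc_interaction[i] <- -mag(length(i))
      })
  }

  # chromatin states and binding, independent of effect class
  chromatin_state <- sample(CHROMATIN_STATES, n_genes, replace = TRUE,
                            prob = c(state_fractions,
                                     1 - sum(state_fractions)))
  arid1a_bound <- stats::runif(n_genes) < bound_fraction

  # super-enhancer modes, optionally biased toward DE genes
  w <- ifelse(effect_class != "null", se_bias_to_de, 1)
  se_mode <- rep("none", n_genes)
  for (mode in names(se_fractions)) {
    k <- round(se_fractions[[mode]] * n_genes)
    free <- which(se_mode == "none")
    if (k > 0 && length(free)) {
      pick <- sample(free, min(k, length(free)), prob = w[free])
      se_mode[pick] <- mode
    }
  }

  truth <- data.frame(
    gene = gene, effect_class = effect_class,
    base_mean = base_mean, dispersion = dispersion,
    lfc_e2 = lfc_e2, lfc_kd = lfc_kd, lfc_interaction = lfc_interaction,
    chromatin_state = chromatin_state, arid1a_bound = arid1a_bound,
    se_mode = se_mode, stringsAsFactors = FALSE
  )
  list(truth = truth, annotation = annotation)
}

#' Simulate a 2x2 factorial count experiment from planted truth
#'
#' Counts are negative binomial with mean
#' \code{base_mean * lib_size * 2^(x_e2 lfc_e2 + x_kd lfc_kd +
#' x_e2 x_kd lfc_interaction)} and per-gene dispersion from the truth table.
#'
#' @param truth Truth data.frame from [generate_truth()].
#' @param n_reps Replicates per design cell (>= 2).
#' @param lib_sizes Relative library size factor per sample (length
#'   \code{4 * n_reps}, default all 1; must be positive).
#' @param seed Integer seed.
#' @return A \code{count_experiment}.
#' @export
generate_counts <- function(truth, n_reps = 3, lib_sizes = NULL, seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  n_samples <- 4L * n_reps
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples) {
    stop("lib_sizes must have length 4 * n_reps")
  }
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  set.seed(seed)

  cells <- expand.grid(replicate = seq_len(n_reps),
                       treatment = c("veh", "e2"),
                       knockdown = c("ctrl", "kd"),
                       stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = paste(cells$knockdown, cells$treatment, cells$replicate,
                      sep = "_"),
    knockdown = cells$knockdown, treatment = cells$treatment,
    replicate = cells$replicate, stringsAsFactors = FALSE
  )
  x_e2 <- as.numeric(design$treatment == "e2")
  x_kd <- as.numeric(design$knockdown == "kd")

  n_genes <- nrow(truth)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(truth$gene, design$sample_id))
  log2mu <- outer(truth$lfc_e2, x_e2) + outer(truth$lfc_kd, x_kd) +
    outer(truth$lfc_interaction, x_e2 * x_kd)
  mu <- truth$base_mean * t(lib_sizes * t(2^log2mu))
  size <- 1 / pmax(truth$dispersion, 1e-12)
  for (j in seq_len(n_samples)) {
    counts[, j] <- stats::rnbinom(n_genes, mu = mu[, j], size = size)
  }
  count_experiment(counts, design)
}

# peak construction constants (bp)
.PK <- list(k4_half = 750L, k27_half = 1500L, arid1a_half = 500L,
            se_peak_w = 1000L, se_gap = 2000L, se_n = 4L,
            se_inside_offset = -2000L, se_within_offset = 20000L,
            se_linked_offset = 80000L, jitter = 200L,
            se_signal = 50, bg_signal = 2, decoy_w = 800L)

.se_cluster <- function(tss, offset) {
  starts <- tss + offset + (seq_len(.PK$se_n) - 1L) * (.PK$se_peak_w + .PK$se_gap)
  data.frame(start = starts, end = starts + .PK$se_peak_w)
}

#' Simulate replicated peak calls consistent with planted chromatin states
#'
#' Every planted promoter mark yields peaks overlapping the gene's 3 kb
#' promoter window in both replicates (replicate positions are jittered but
#' always cover the TSS). Genes with a super-enhancer mode receive a
#' high-signal cluster of H3K27ac and ATAC peaks positioned by mode: inside
#' the promoter window, 20 kb from the TSS (within 50 kb), or 80 kb away and
#' connected only through an enhancer-gene link row with score 2. A
#' configurable fraction of decoy peaks present in a single replicate is
#' added per mark.
#'
#' @param truth,annotation From [generate_truth()].
#' @param seed Integer seed.
#' @param decoy_frac Decoy single-replicate peaks per mark, as a fraction of
#'   the gene count (0 disables decoys).
#' @return List with \code{peaks} (named list: mark -> list of 2
#'   \code{peak_set} replicates for H3K4me3, H3K27me3, ARID1A, H3K27ac, ATAC)
#'   and \code{links} (an \code{enhancer_links} table for linked-mode genes).
#' @export
generate_peaks <- function(truth, annotation, seed = 1, decoy_frac = 0.1) {
  if (!identical(truth$gene, annotation$gene)) {
    stop("truth and annotation must list the same genes in the same order")
  }
  set.seed(seed)
  n <- nrow(truth)
  tss <- annotation$tss
  chrom <- annotation$chrom

  promoter_peak <- function(sel, half) {
    data.frame(chrom = chrom[sel], start = tss[sel] - half,
               end = tss[sel] + half, signal = .PK$bg_signal * 5,
               stringsAsFactors = FALSE)
  }
  jitter_rep <- function(df) {
    if (!nrow(df)) return(df)
    df$start <- df$start + sample(-.PK$jitter:.PK$jitter, nrow(df), TRUE)
    df$end <- df$end + sample(-.PK$jitter:.PK$jitter, nrow(df), TRUE)
    df$start <- pmax(0L, df$start)
    df
  }
  add_decoys <- function(df) {
    k <- round(decoy_frac * n)
    if (k == 0) return(df)
    dchrom <- sample(unique(chrom), k, TRUE)
    dstart <- sample(seq(1000L, max(tss) + 100000L, by = 997L), k, TRUE)
    rbind(df, data.frame(chrom = dchrom, start = dstart,
                         end = dstart + .PK$decoy_w, signal = .PK$bg_signal,
                         stringsAsFactors = FALSE))
  }

  base <- list(
    H3K4me3 = promoter_peak(truth$chromatin_state %in% c("bivalent", "K4-only"),
                            .PK$k4_half),
    H3K27me3 = promoter_peak(truth$chromatin_state %in% c("bivalent", "K27-only"),
                             .PK$k27_half),
    ARID1A = promoter_peak(truth$arid1a_bound, .PK$arid1a_half)
  )

  # super-enhancer clusters shared by H3K27ac and ATAC
  se_rows <- data.frame(chrom = character(), start = integer(),
                        end = integer(), signal = numeric())
  links <- data.frame(chrom = character(), start = integer(), end = integer(),
                      gene = character(), score = numeric())
  offsets <- c(inside = .PK$se_inside_offset, within50kb = .PK$se_within_offset,
               linked = .PK$se_linked_offset)
  for (mode in names(offsets)) {
    sel <- which(truth$se_mode == mode)
    for (i in sel) {
      cl <- .se_cluster(tss[i], offsets[[mode]])
      se_rows <- rbind(se_rows, data.frame(chrom = chrom[i], start = cl$start,
                                           end = cl$end, signal = .PK$se_signal,
                                           stringsAsFactors = FALSE))
      if (mode == "linked") {
        links <- rbind(links, data.frame(chrom = chrom[i],
                                         start = min(cl$start),
                                         end = max(cl$end),
                                         gene = truth$gene[i], score = 2,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  # low-signal background enhancer peaks (both replicates) at a subset of
  # unassociated genes, so stitched-region signals form a hockey stick with
  # the planted clusters as outliers
  bg_sel <- which(truth$se_mode == "none")
  bg_sel <- bg_sel[stats::runif(length(bg_sel)) < 0.3]
  bg_rows <- data.frame(chrom = chrom[bg_sel], start = tss[bg_sel] + 10000L,
                        end = tss[bg_sel] + 11000L,
                        signal = .PK$bg_signal * stats::runif(length(bg_sel), 0.5, 1.5),
                        stringsAsFactors = FALSE)
  base$H3K27ac <- rbind(se_rows, bg_rows)
  base$ATAC <- rbind(se_rows, bg_rows)

  peaks <- lapply(names(base), function(mark) {
    lapply(1:2, function(rep_i) {
      df <- jitter_rep(base[[mark]])
      if (rep_i == 1L) df <- add_decoys(df)
      peak_set(df, mark = mark, replicate = rep_i)
    })
  })
  names(peaks) <- names(base)
  list(peaks = peaks, links = enhancer_links(links))
}

#' Simulate a multi-sample expression + promoter-mark panel
#'
#' Emulates a cross-tissue panel in which each sample carries an expression
#' value (RPKM-like, log-normal) for one target gene plus a per-sample peak
#' set. In marked samples a repressive peak overlaps the target promoter
#' window and expression is down-scaled by \code{expression_ratio}; unmarked
#' samples carry only a distant peak.
#'
#' @param n_samples Total samples (default 56).
#' @param n_marked Samples with the promoter mark (0 < n_marked < n_samples).
#' @param expression_ratio Multiplicative expression scaling in marked
#'   samples (> 0; 1 plants no group difference).
#' @param seed Integer seed.
#' @param target_chrom,target_tss Location of the target gene.
#' @return List with \code{expression}, logical \code{marked} (the planted
#'   truth), \code{peaks} (list of \code{peak_set} per sample),
#'   \code{target_chrom}, \code{target_tss}.
#' @export
generate_crosssample_panel <- function(n_samples = 56, n_marked = 20,
                                       expression_ratio = 0.2, seed = 1,
                                       target_chrom = "chrP",
                                       target_tss = 1000000L) {
  if (expression_ratio <= 0) stop("expression_ratio must be > 0")
  if (n_marked <= 0 || n_marked >= n_samples) {
    stop("n_marked must satisfy 0 < n_marked < n_samples")
  }
  set.seed(seed)
  marked <- rep(FALSE, n_samples)
  marked[sample.int(n_samples, n_marked)] <- TRUE
  expression <- stats::rlnorm(n_samples, meanlog = log(20), sdlog = 0.75)
  expression[marked] <- expression[marked] * expression_ratio
  peaks <- lapply(seq_len(n_samples), function(i) {
    if (marked[i]) {
      df <- data.frame(chrom = target_chrom,
                       start = target_tss - 1000L + sample(-500:500, 1),
                       end = target_tss + 1000L + sample(-500:500, 1),
                       signal = 5)
    } else {
      df <- data.frame(chrom = target_chrom, start = target_tss + 100000L,
                       end = target_tss + 101000L, signal = 5)
    }
    peak_set(df, mark = "H3K27me3", replicate = 1L)
  })
  list(expression = expression, marked = marked, peaks = peaks,
       target_chrom = target_chrom, target_tss = target_tss)
}

#' Build planted gene sets for gene-set enrichment testing
#'
#' One concordant set per planted effect class (members sampled from the
#' class) plus random null sets drawn from the whole universe.
#'
#' @param truth Truth table from [generate_truth()].
#' @param n_random Number of random null sets.
#' @param set_size Size of each set.
#' @param seed Integer seed.
#' @return A \code{gene_set_collection}.
#' @export
generate_gene_sets <- function(truth, n_random = 20, set_size = 30, seed = 1) {
  set.seed(seed)
  sets <- list()
  for (cl in setdiff(EFFECT_CLASSES, "null")) {
    members <- truth$gene[truth$effect_class == cl]
    if (length(members) >= 5) {
      nm <- paste0("PLANTED_", toupper(gsub("-", "_", cl)))
      sets[[nm]] <- sample(members, min(set_size, length(members)))
    }
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_%03d", i)]] <- sample(truth$gene, set_size)
  }
  gene_set_collection(sets)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the TSV/BED/GMT files the readers in this package consume:
#' annotation, counts + design, per-mark replicate BED files, enhancer links,
#' gene sets and the truth table itself.
#'
#' @param outdir Output directory (created if needed).
#' @param n_genes,n_reps,decoy_frac,se_bias_to_de Generator parameters.
#' @param seed Integer seed driving all stages.
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_fixture <- function(outdir, n_genes = 2000, n_reps = 3,
                                    decoy_frac = 0.1, se_bias_to_de = 1,
                                    seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_truth(n_genes = n_genes, seed = seed,
                       se_bias_to_de = se_bias_to_de)
  expt <- generate_counts(gt$truth, n_reps = n_reps, seed = seed + 1L)
  pk <- generate_peaks(gt$truth, gt$annotation, seed = seed + 2L,
                       decoy_frac = decoy_frac)
  sets <- generate_gene_sets(gt$truth, seed = seed + 3L)

  paths <- list()
  paths$annotation <- file.path(outdir, "annotation.tsv")
  write.table(as.data.frame(gt$annotation), paths$annotation, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(outdir, "truth.tsv")
  write.table(gt$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$counts <- file.path(outdir, "counts.tsv")
  paths$design <- file.path(outdir, "design.tsv")
  write_counts(expt, paths$counts, paths$design)
  for (mark in names(pk$peaks)) {
    for (r in 1:2) {
      key <- paste0(tolower(mark), "_rep", r)
      paths[[key]] <- file.path(outdir, paste0(key, ".bed"))
      write_peaks_bed(pk$peaks[[mark]][[r]], paths[[key]])
    }
  }
  paths$links <- file.path(outdir, "links.tsv")
  write.table(as.data.frame(pk$links), paths$links, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$gmt <- file.path(outdir, "sets.gmt")
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, ""), paths$gmt)
  invisible(paths)
}
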