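# Config-driven orchestration: run every stage of the pipeline on either a
# simulated fixture or user-supplied files, writing one TSV per stage with a
# commented provenance header. All randomness flows from the single seed in
# the config, so reruns are byte-identical.

.default_config <- list(
  alpha = 1e-4, promoter_width = 3000, roadmap_window = 6000,
  stitch_dist = 12500, n_perm = 500, seed = 1,
  simulate = list(n_genes = 2000, n_reps = 3, decoy_frac = 0.1,
                  se_bias_to_de = 1)
)

#' Read and validate a pipeline run configuration
#'
#' YAML with optional keys \code{alpha}, \code{promoter_width},
#' \code{roadmap_window}, \code{stitch_dist}, \code{n_perm}, \code{seed},
#' \code{outdir}, and either a \code{simulate} block (generator parameters)
#' or an \code{inputs} block of file paths (counts, design, annotation,
#' per-mark replicate BEDs, links, gmt). Unset keys take package defaults.
#'
#' @param path YAML path, or a list to validate directly.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  out <- utils::modifyList(.default_config, cfg)
  if (!is.numeric(out$alpha) || out$alpha <= 0 || out$alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.null(cfg$inputs)) {
    out$simulate <- NULL
    paths <- unlist(cfg$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
    }
  }
  out
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- utils::modifyList(.default_config$simulate, cfg$simulate)
    gt <- generate_truth(n_genes = sim$n_genes, seed = cfg$seed,
                         se_bias_to_de = sim$se_bias_to_de)
    expt <- generate_counts(gt$truth, n_reps = sim$n_reps,
                            seed = cfg$seed + 1L)
    pk <- generate_peaks(gt$truth, gt$annotation, seed = cfg$seed + 2L,
                         decoy_frac = sim$decoy_frac)
    sets <- generate_gene_sets(gt$truth, seed = cfg$seed + 3L)
    list(annotation = gt$annotation, expt = expt, peaks = pk$peaks,
         links = pk$links, sets = sets, truth = gt$truth)
  } else {
    ip <- cfg$inputs
    read_pair <- function(key, mark) {
      lapply(seq_along(ip[[key]]), function(r) {
        read_peaks_bed(ip[[key]][[r]], mark = mark, replicate = r)
      })
    }
    list(
      annotation = read_annotation(ip$annotation),
      expt = read_counts(ip$counts, ip$design),
      peaks = list(H3K4me3 = read_pair("k4", "H3K4me3"),
                   H3K27me3 = read_pair("k27", "H3K27me3"),
                   ARID1A = read_pair("arid1a", "ARID1A"),
                   H3K27ac = read_pair("k27ac", "H3K27ac"),
                   ATAC = read_pair("atac", "ATAC")),
      links = if (!is.null(ip$links)) read_enhancer_links(ip$links) else NULL,
      sets = if (!is.null(ip$gmt)) read_gmt(ip$gmt) else NULL,
      truth = NULL
    )
  }
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs (or the simulated fixture)
#' and writes the report bundle to the output directory: DE tables for the
#' five factorial contrasts, the joint regulation classification,
#' remodeler-dependent induction genes, promoter chromatin states,
#' enrichment statistics, expression-by-state comparisons, super-enhancer
#' gene lists per association mode, gene-set enrichment, the cross-sample
#' promoter-mark test, and a run log. Every table is reproducible
#' byte-identically for a fixed config and seed.
#'
#' @param config Config list or YAML path (see [read_run_config()]).
#' @param outdir Output directory; overrides \code{config$outdir}.
#' @return Invisibly, a named list of written paths plus key in-memory
#'   results.
#' @export
run_all <- function(config, outdir = NULL) {
  cfg <- read_run_config(config)
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(package = paste0("bivalint ",
                             as.character(utils::packageVersion("bivalint"))),
            seed = cfg$seed, config = .config_hash(cfg))
  paths <- list()
  emit <- function(df, name) {
    paths[[name]] <<- .write_report(df, file.path(outdir, name), meta)
  }

  inp <- .load_inputs(cfg)

  # differential expression over the filtered (expressed) universe
  expt <- filter_low_counts(inp$expt)
  sf <- size_factors(expt)
  fit <- fit_factorial(expt, sf)
  de <- lapply(CONTRASTS, function(ct) fit_contrast(fit, ct,
                                                    fdr_alpha = cfg$alpha))
  names(de) <- CONTRASTS
  for (ct in CONTRASTS) {
    emit(de[[ct]], paste0("de_", gsub("[+]", "", ct), ".tsv"))
  }
  expressed <- rownames(expt$counts)

  # joint regulation classes and dependent induction
  cls <- classify_joint(de$e2_vs_ctrl, de$kd_vs_ctrl, alpha = cfg$alpha)
  emit(cls$table, "classes.tsv")
  dep <- dependent_induction_genes(de$e2_vs_ctrl,
                                   de_interaction = de$interaction,
                                   mode = "interaction", alpha = cfg$alpha)
  writeLines(dep, file.path(outdir, "dependent_induction.txt"))
  paths$dependent_induction.txt <- file.path(outdir, "dependent_induction.txt")

  # promoter chromatin states over the expressed universe
  ann_expr <- inp$annotation[inp$annotation$gene %in% expressed, ]
  promoters <- make_promoters(ann_expr, width = cfg$promoter_width)
  cons <- lapply(inp$peaks, function(reps) consensus_peaks(reps[[1]], reps[[2]]))
  has_k4 <- flag_promoter_overlap(promoters, cons$H3K4me3)
  has_k27 <- flag_promoter_overlap(promoters, cons$H3K27me3)
  bound <- flag_promoter_overlap(promoters, cons$ARID1A)
  states <- classify_states(has_k4, has_k27, arid1a_bound = bound)
  emit(states$table, "chromatin_states.tsv")

  # association statistics
  k4_genes <- states$table$gene[states$table$has_k4]
  k27_genes <- states$table$gene[states$table$has_k27]
  hyp <- hypergeometric_enrichment(k4_genes, k27_genes, states$table$gene)
  fis <- fisher_association(states$table$state == "bivalent",
                            states$table$arid1a_bound)
  enr <- data.frame(
    comparison = c("k4_vs_k27_overlap", "bivalent_vs_bound"),
    overlap = c(hyp$overlap, fis$table[1, 1]),
    expected = c(hyp$expected, NA),
    odds_ratio = c(NA, fis$odds_ratio),
    pvalue = c(hyp$p_hyper, fis$p_fisher), stringsAsFactors = FALSE
  )

  norm_mean <- rowMeans(sweep(expt$counts, 2, sf, "/"))
  ebs <- expression_by_state(norm_mean, states)
  emit(ebs, "expression_by_state.tsv")

  # super-enhancers
  active <- intersect_peak_sets(cons$H3K27ac, cons$ATAC)
  regions <- stitch(active, stitch_dist = cfg$stitch_dist,
                    tss_exclusion = promoters)
  se_genes <- list()
  if (nrow(regions) >= 3) {
    regions <- call_super(regions)
    emit(regions, "stitched_regions.tsv")
    de_any <- union(de$e2_vs_ctrl$gene[de$e2_vs_ctrl$qvalue < cfg$alpha],
                    de$kd_vs_ctrl$gene[de$kd_vs_ctrl$qvalue < cfg$alpha])
    for (mode in c("inside", "within50kb", "linked")) {
      genes <- tryCatch(
        associate_genes(regions, promoters, links = inp$links, mode = mode),
        error = function(e) character()
      )
      genes <- intersect(genes, expressed)
      se_genes[[mode]] <- genes
      fn <- paste0("se_genes_", mode, ".txt")
      writeLines(genes, file.path(outdir, fn))
      paths[[fn]] <- file.path(outdir, fn)
      if (length(genes)) {
        st <- se_gene_enrichment(intersect(de_any, expressed), genes,
                                 expressed)
        enr <- rbind(enr, data.frame(
          comparison = paste0("de_vs_se_", mode), overlap = st$overlap,
          expected = st$expected, odds_ratio = NA, pvalue = st$p_hyper
        ))
      }
    }
  }
  emit(enr, "enrichment_stats.tsv")

  # gene-set enrichment on the estrogen contrast
  if (!is.null(inp$sets)) {
    usable <- Filter(function(s) any(expressed %in% s), inp$sets)
    ranked <- rank_genes(de$e2_vs_ctrl, stat = "wald")
    gsea <- gsea_nes(ranked, gene_set_collection(usable),
                     n_perm = cfg$n_perm, seed = cfg$seed + 4L)
    emit(gsea, "gsea.tsv")
  }

  # cross-sample promoter-mark vs expression panel (simulated fixture only)
  if (!is.null(cfg$simulate)) {
    panel <- generate_crosssample_panel(seed = cfg$seed + 5L)
    rm_res <- promoter_mark_vs_expression(panel, window = cfg$roadmap_window)
    rm_tab <- cbind(rm_res$group_stats,
                    statistic = rm_res$statistic, pvalue = rm_res$pvalue)
    emit(rm_tab, "roadmap.tsv")
  }

  log_lines <- c(
    sprintf("package: %s", meta[["package"]]),
    sprintf("seed: %s", meta[["seed"]]),
    sprintf("config: %s", meta[["config"]]),
    sprintf("outputs: %s", paste(sort(names(paths)), collapse = ", "))
  )
  writeLines(log_lines, file.path(outdir, "run.log"))
  paths$run.log <- file.path(outdir, "run.log")

  invisible(list(paths = paths, de = de, classes = cls, states = states,
                 se_genes = se_genes, dependent_induction = dep))
}

#' Overlap report for two gene lists
#'
#' Uppercases and deduplicates both lists and reports sizes plus the sorted
#' intersection.
#'
#' @param listA,listB Character vectors of gene symbols.
#' @return List with \code{n_a}, \code{n_b}, \code{n_overlap},
#'   \code{overlap}.
#' @export
overlap_report <- function(listA, listB) {
  a <- unique(toupper(listA)); b <- unique(toupper(listB))
  ov <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = length(ov),
       overlap = ov)
}

#' Curated bivalent-promoter gene lists
#'
#' The two published lists of bivalent-promoter genes responsive to estrogen
#' stimulation (in 12Z-ESR1 cells) or to ARID1A knockdown (in 12Z cells),
#' shipped with the package as plain-text fixtures. Their 16-gene overlap,
#' which includes PGR, motivates the bivalency analyses in this package.
#'
#' @return List with character vectors \code{e2} (n = 53) and
#'   \code{arid1a} (n = 36).
#' @export
bivalent_gene_lists <- function() {
  read_list <- function(fn) {
    path <- system.file("extdata", fn, package = "bivalint", mustWork = TRUE)
    toupper(readLines(path))
  }
  list(e2 = read_list("bivalent_e2_responsive_genes.txt"),
       arid1a = read_list("bivalent_arid1a_responsive_genes.txt"))
}
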