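# Joint classification of genes by their estrogen response and their
# response to remodeler knockdown. "Cooperative" means the two perturbations
# move a gene in opposite directions (normal remodeler function works with
# estrogen); "antagonistic" means they move it the same way.

JOINT_CLASSES <- c("coop-e2up", "coop-e2down", "antag-up", "antag-down",
                   "e2-only", "kd-only", "neither")

.check_universe <- function(a, b) {
  if (!identical(sort(a$gene), sort(b$gene))) {
    stop("DE results cover different gene universes")
  }
}

#' Classify genes by joint estrogen / knockdown regulation
#'
#' A gene significant in both contrasts is cooperative when the two log2
#' fold changes have opposite signs and antagonistic when they share a sign.
#' Genes significant in only one contrast are "e2-only"/"kd-only"; the rest
#' "neither". A zero log2 fold change yields direction "ns" and such genes
#' are not assigned a cooperative/antagonistic class.
#'
#' @param de_e2,de_kd \code{de_result} tables over the same gene universe.
#' @param alpha Significance threshold on the q-value (strict \code{<};
#'   default 1e-4).
#' @return List with \code{table} (per-gene sig/dir flags and
#'   \code{joint_class}) and \code{summary} (number of doubly-significant
#'   genes and the cooperative/antagonistic fractions among them).
#' @export
classify_joint <- function(de_e2, de_kd, alpha = 1e-4) {
  .check_universe(de_e2, de_kd)
  de_kd <- de_kd[match(de_e2$gene, de_kd$gene), ]
  sig_e2 <- de_e2$qvalue < alpha
  sig_kd <- de_kd$qvalue < alpha
  dirn <- function(lfc, sig) {
    ifelse(!sig | lfc == 0, "ns", ifelse(lfc > 0, "up", "down"))
  }
  dir_e2 <- dirn(de_e2$log2fc, sig_e2)
  dir_kd <- dirn(de_kd$log2fc, sig_kd)

  both <- sig_e2 & sig_kd & dir_e2 != "ns" & dir_kd != "ns"
  joint <- rep("neither", nrow(de_e2))
  joint[both & dir_e2 == "up" & dir_kd == "down"] <- "coop-e2up"
  joint[both & dir_e2 == "down" & dir_kd == "up"] <- "coop-e2down"
  joint[both & dir_e2 == "up" & dir_kd == "up"] <- "antag-up"
  joint[both & dir_e2 == "down" & dir_kd == "down"] <- "antag-down"
  joint[joint == "neither" & sig_e2 & !sig_kd] <- "e2-only"
  joint[joint == "neither" & !sig_e2 & sig_kd] <- "kd-only"

  table <- data.frame(gene = de_e2$gene, sig_e2 = sig_e2, sig_kd = sig_kd,
                      dir_e2 = dir_e2, dir_kd = dir_kd, joint_class = joint,
                      stringsAsFactors = FALSE)
  n_both <- sum(both)
  n_coop <- sum(joint %in% c("coop-e2up", "coop-e2down"))
  n_antag <- sum(joint %in% c("antag-up", "antag-down"))
  summary <- list(
    n_sig_e2 = sum(sig_e2), n_sig_kd = sum(sig_kd), n_both = n_both,
    frac_cooperative = if (n_both > 0) n_coop / n_both else NA_real_,
    frac_antagonistic = if (n_both > 0) n_antag / n_both else NA_real_
  )
  list(table = table, summary = summary)
}

#' Genes whose estrogen induction depends on the remodeler
#'
#' Selects genes significantly up-regulated by estrogen whose induction is
#' significantly weaker after knockdown, either through a significant
#' negative interaction term (\code{mode = "interaction"}, the default) or
#' through a significant knockdown-context induction ("delta" contrast:
#' knockdown+estrogen vs knockdown) smaller than the estrogen effect
#' (\code{mode = "delta"}). Optionally intersected with the union of named
#' gene sets (e.g. hormone-response pathways).
#'
#' @param de_e2 \code{de_result} for the estrogen contrast.
#' @param de_delta \code{de_result} for the knockdown-context estrogen
#'   contrast (used by \code{mode = "delta"}).
#' @param de_interaction \code{de_result} for the interaction term.
#' @param gene_sets Optional \code{gene_set_collection} to intersect with.
#' @param mode "interaction" or "delta".
#' @param alpha Significance threshold (default 1e-4).
#' @return Character vector of gene symbols.
#' @export
dependent_induction_genes <- function(de_e2, de_delta = NULL,
                                      de_interaction = NULL,
                                      gene_sets = NULL,
                                      mode = c("interaction", "delta"),
                                      alpha = 1e-4) {
  mode <- match.arg(mode)
  up_e2 <- de_e2$qvalue < alpha & de_e2$log2fc > 0
  if (mode == "interaction") {
    if (is.null(de_interaction)) stop("interaction mode needs de_interaction")
    .check_universe(de_e2, de_interaction)
    de_interaction <- de_interaction[match(de_e2$gene, de_interaction$gene), ]
    hit <- up_e2 & de_interaction$qvalue < alpha & de_interaction$log2fc < 0
  } else {
    if (is.null(de_delta)) stop("delta mode needs de_delta")
    .check_universe(de_e2, de_delta)
    de_delta <- de_delta[match(de_e2$gene, de_delta$gene), ]
    hit <- up_e2 & de_delta$qvalue < alpha & de_delta$log2fc < de_e2$log2fc
  }
  genes <- de_e2$gene[hit]
  if (!is.null(gene_sets)) {
    genes <- intersect(genes, unique(unlist(gene_sets)))
  }
  sort(genes)
}

#' Three-way intersection of two DE gene sets with a bound-gene set
#'
#' Computes all seven exclusive Euler regions for (significant in the
#' estrogen contrast, significant in the knockdown contrast, promoter-bound)
#' and returns the central intersection gene list.
#'
#' @param de_e2,de_kd \code{de_result} tables.
#' @param bound_genes Character vector of promoter-bound gene symbols.
#' @param alpha Significance threshold (default 1e-4).
#' @return List with \code{counts} (named 7-vector: e2_only, kd_only,
#'   bound_only, e2_kd, e2_bound, kd_bound, central) , \code{n} (set sizes)
#'   and \code{central} (sorted gene vector).
#' @export
intersect_de_with_binding <- function(de_e2, de_kd, bound_genes,
                                      alpha = 1e-4) {
  A <- de_e2$gene[de_e2$qvalue < alpha]
  B <- de_kd$gene[de_kd$qvalue < alpha]
  C <- unique(toupper(bound_genes))
  u <- unique(c(A, B, C))
  a <- u %in% A; b <- u %in% B; cc <- u %in% C
  counts <- c(
    e2_only = sum(a & !b & !cc), kd_only = sum(!a & b & !cc),
    bound_only = sum(!a & !b & cc), e2_kd = sum(a & b & !cc),
    e2_bound = sum(a & !b & cc), kd_bound = sum(!a & b & cc),
    central = sum(a & b & cc)
  )
  list(counts = counts,
       n = c(e2 = length(A), kd = length(B), bound = length(C)),
       central = sort(u[a & b & cc]))
}

#' Segregate doubly-significant genes into four direction groups
#'
#' @param table Classification table from [classify_joint()].
#' @return Named list of gene vectors: \code{e2up_kdup}, \code{e2up_kddown},
#'   \code{e2down_kdup}, \code{e2down_kddown}.
#' @export
four_group_segregation <- function(table) {
  both <- table$sig_e2 & table$sig_kd & table$dir_e2 != "ns" &
    table$dir_kd != "ns"
  grp <- function(d1, d2) {
    sort(table$gene[both & table$dir_e2 == d1 & table$dir_kd == d2])
  }
  list(e2up_kdup = grp("up", "up"), e2up_kddown = grp("up", "down"),
       e2down_kdup = grp("down", "up"), e2down_kddown = grp("down", "down"))
}
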