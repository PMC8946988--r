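#' Read a gene annotation table
#'
#' Reads a tab-separated annotation with one row per gene giving the gene
#' symbol, chromosome, strand and the 0-based position of the primary
#' transcription start site (TSS). Symbols are uppercased and must be unique
#' after uppercasing; each gene carries exactly one TSS (choosing the primary
#' TSS among transcripts is deferred to annotation preparation).
#'
#' @param path Path to a TSV file with header columns
#'   \code{gene}, \code{chrom}, \code{strand}, \code{tss}.
#' @return A \code{data.frame} with columns \code{gene} (uppercase character),
#'   \code{chrom}, \code{strand} (\code{"+"} or \code{"-"}) and integer
#'   \code{tss}, of class \code{c("gene_annotation", "data.frame")}.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  as_annotation(df)
}

#' Build a validated gene annotation from a data frame
#'
#' @param df data.frame with columns gene, chrom, strand, tss.
#' @return Validated annotation (see [read_annotation()]).
#' @export
as_annotation <- function(df) {
  df$gene <- toupper(as.character(df$gene))
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("invalid strand at row(s) ", paste(which(bad_strand), collapse = ", "),
         ": must be '+' or '-'")
  }
  tss <- suppressWarnings(as.numeric(df$tss))
  if (any(is.na(tss)) || any(tss < 0) || any(tss != floor(tss))) {
    stop("tss must be a non-negative integer; offending row(s): ",
         paste(which(is.na(tss) | tss < 0 | tss != floor(tss)), collapse = ", "))
  }
  df$tss <- as.integer(tss)
  dup <- duplicated(df$gene)
  if (any(dup)) {
    stop("duplicate gene symbol(s) after uppercasing: ",
         paste(unique(df$gene[dup]), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a count matrix and its sample design
#'
#' The counts file is a TSV with a \code{gene} column followed by one integer
#' column per sample; the design file is a TSV with columns
#' \code{sample_id}, \code{knockdown} (\code{ctrl}/\code{kd}),
#' \code{treatment} (\code{veh}/\code{e2}) and \code{replicate}. Sample
#' columns are reordered to match the design order.
#'
#' @param counts_path,design_path TSV paths.
#' @return A \code{count_experiment}: list with integer matrix \code{counts}
#'   (genes x samples) and data.frame \code{design}.
#' @export
read_counts <- function(counts_path, design_path) {
  counts <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(counts)[1] != "gene") stop("first counts column must be 'gene'")
  design <- read.delim(design_path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- toupper(counts$gene)
  mat <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  count_experiment(mat, design)
}

#' Construct a validated count experiment
#'
#' @param counts numeric gene x sample matrix of non-negative integers with
#'   gene symbols as rownames and sample ids as colnames.
#' @param design data.frame with columns sample_id, knockdown, treatment,
#'   replicate.
#' @return Object of class \code{count_experiment}.
#' @export
count_experiment <- function(counts, design) {
  need <- c("sample_id", "knockdown", "treatment", "replicate")
  missing_cols <- setdiff(need, colnames(design))
  if (length(missing_cols) > 0L) {
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(design$knockdown %in% c("ctrl", "kd"))) {
    stop("design knockdown must be 'ctrl' or 'kd'")
  }
  if (!all(design$treatment %in% c("veh", "e2"))) {
    stop("design treatment must be 'veh' or 'e2'")
  }
  extra <- setdiff(colnames(counts), design$sample_id)
  absent <- setdiff(design$sample_id, colnames(counts))
  if (length(extra) || length(absent)) {
    stop("counts/design sample mismatch; not in design: ",
         paste(extra, collapse = ", "), "; not in counts: ",
         paste(absent, collapse = ", "))
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols in counts")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("count_experiment:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("design cells:\n")
  print(table(x$design$knockdown, x$design$treatment))
  invisible(x)
}

#' Read a BED file of peak calls
#'
#' Accepts BED3 and wider dialects (narrowPeak included): column 5 is taken
#' as the peak signal when present and numeric, columns beyond 5 are ignored,
#' and \code{track}/\code{browser} lines are skipped. Intervals are stored
#' 0-based half-open and sorted within chromosome.
#'
#' @param path BED path.
#' @param mark Name of the assayed mark or factor (e.g. "H3K4me3").
#' @param replicate Integer replicate index.
#' @return A \code{peak_set}: list with \code{mark}, \code{replicate} and a
#'   data.frame \code{intervals} (chrom, start, end, signal).
#' @export
read_peaks_bed <- function(path, mark, replicate = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), signal = numeric()),
                    mark = mark, replicate = replicate))
  }
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1], " has fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric coordinate at BED line ",
         which(is.na(start) | is.na(end))[1])
  }
  signal <- rep(1.0, length(lines))
  has5 <- nf >= 5L
  if (any(has5)) {
    s5 <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
    signal[has5][!is.na(s5)] <- s5[!is.na(s5)]
  }
  peak_set(data.frame(chrom = chrom, start = start, end = end, signal = signal,
                      stringsAsFactors = FALSE),
           mark = mark, replicate = replicate)
}

#' Construct a validated peak set
#'
#' @param intervals data.frame with chrom, start, end and optional signal
#'   (0-based half-open coordinates).
#' @param mark Mark name.
#' @param replicate Replicate index (NA for consensus sets).
#' @return Object of class \code{peak_set}.
#' @export
peak_set <- function(intervals, mark, replicate = NA_integer_) {
  if (is.null(intervals$signal)) intervals$signal <- 1.0
  intervals <- intervals[c("chrom", "start", "end", "signal")]
  if (any(intervals$start != floor(intervals$start)) ||
      any(intervals$end != floor(intervals$end))) {
    stop("peak coordinates must be integers")
  }
  if (any(intervals$start < 0)) stop("peak start < 0")
  if (any(intervals$start >= intervals$end)) {
    stop("empty or inverted interval (start >= end) at row ",
         which(intervals$start >= intervals$end)[1])
  }
  if (any(!is.finite(intervals$signal)) || any(intervals$signal < 0)) {
    stop("peak signal must be finite and non-negative")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  structure(list(mark = mark, replicate = replicate, intervals = intervals),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", x$mark,
      if (is.na(x$replicate)) "(consensus)" else paste0("rep", x$replicate),
      "-", nrow(x$intervals), "intervals\n")
  invisible(x)
}

#' Write a peak set to BED5
#'
#' @param ps A \code{peak_set}.
#' @param path Output path.
#' @export
write_peaks_bed <- function(ps, path) {
  df <- ps$intervals
  out <- data.frame(df$chrom, df$start, df$end,
                    name = paste0(ps$mark, "_", seq_len(nrow(df))),
                    score = df$signal)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a count experiment to counts + design TSVs
#'
#' @param expt A \code{count_experiment}.
#' @param counts_path,design_path Output paths.
#' @export
write_counts <- function(expt, counts_path, design_path) {
  df <- data.frame(gene = rownames(expt$counts), expt$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expt$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited, one set per line: name, description, member symbols.
#' Members are uppercased and deduplicated; empty sets are rejected.
#'
#' @param path GMT path.
#' @return Named list of uppercase character vectors, class
#'   \code{gene_set_collection}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  sets <- lapply(fields, function(f) {
    if (length(f) < 3L) return(character())
    unique(toupper(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  })
  names(sets) <- vapply(fields, `[`, "", 1L)
  gene_set_collection(sets)
}

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return \code{gene_set_collection} (named list of uppercase symbol vectors).
#' @export
gene_set_collection <- function(sets) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  structure(sets, class = "gene_set_collection")
}

#' Read an enhancer-to-gene link table
#'
#' TSV with header columns \code{chrom}, \code{start}, \code{end},
#' \code{gene}, \code{score}: one putative enhancer interval linked to a gene
#' with a confidence score (GeneHancer-style).
#'
#' @param path TSV path.
#' @return data.frame with validated intervals and uppercase gene symbols,
#'   class \code{c("enhancer_links", "data.frame")}.
#' @export
read_enhancer_links <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "gene", "score")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("enhancer link file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  enhancer_links(df[need])
}

#' Construct a validated enhancer-link table
#'
#' @param df data.frame with chrom, start, end, gene, score.
#' @return Validated \code{enhancer_links} data.frame.
#' @export
enhancer_links <- function(df) {
  if (any(df$start >= df$end)) stop("enhancer interval with start >= end")
  if (any(!is.finite(df$score))) stop("enhancer link score must be finite")
  df$gene <- toupper(df$gene)
  rownames(df) <- NULL
  class(df) <- c("enhancer_links", "data.frame")
  df
}
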