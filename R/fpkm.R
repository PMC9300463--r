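#' Assemble a gene-level counts container
#'
#' Bundles a counts matrix with per-gene transcript lengths and the
#' sample-to-tissue design, validating the pieces against each other.
#'
#' @param counts genes x samples matrix of non-negative integers with gene
#'   ids as rownames and sample ids as colnames.
#' @param gene_lengths named vector of transcript lengths in bp (> 0), one
#'   per gene.
#' @param design data.frame with columns `sample` and `tissue` covering every
#'   column of `counts`.
#' @return an object of class `counts_matrix`.
#' @export
counts_matrix <- function(counts, gene_lengths, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("every gene needs a length > 0")
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample), c("sample", "tissue")]
  structure(list(counts = counts, gene_lengths = gene_lengths, design = design),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$tissue), collapse = "/")))
  invisible(x)
}

#' Convert counts to FPKM
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (gene_length[g] * column_sum[s])`,
#' i.e. fragments per kilobase of transcript per million mapped reads, with
#' the per-sample mapped-read total taken as the column sum of the supplied
#' gene-level counts.
#'
#' @param counts a [counts_matrix()].
#' @return an object of class `expression_matrix`: list with `fpkm`
#'   (genes x samples) and the `design` carried over from the counts.
#' @examples
#' cm <- counts_matrix(
#'   matrix(c(100, 0), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'   c(a = 1000, b = 500),
#'   data.frame(sample = "s1", tissue = "root"))
#' compute_fpkm(cm)$fpkm
#' @export
compute_fpkm <- function(counts) {
  stopifnot(inherits(counts, "counts_matrix"))
  totals <- colSums(counts$counts)
  if (any(totals == 0))
    stop("zero mapped reads in sample(s): ",
         paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  fpkm <- counts$counts * 1e9 /
    (counts$gene_lengths %o% totals)
  structure(list(fpkm = fpkm, design = counts$design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, FPKM range [%.3g, %.3g]\n",
              nrow(x$fpkm), ncol(x$fpkm), min(x$fpkm), max(x$fpkm)))
  invisible(x)
}

.check_tissue <- function(expr, tissue) {
  if (!tissue %in% expr$design$tissue)
    stop("unknown tissue: ", tissue)
}

#' Per-gene mean FPKM in one tissue
#'
#' Arithmetic mean over the tissue's replicate columns.
#'
#' @param expr an `expression_matrix`.
#' @param tissue tissue label present in the design.
#' @return named numeric vector, one mean per gene.
#' @export
tissue_mean <- function(expr, tissue) {
  stopifnot(inherits(expr, "expression_matrix"))
  .check_tissue(expr, tissue)
  cols <- expr$design$sample[expr$design$tissue == tissue]
  rowMeans(expr$fpkm[, cols, drop = FALSE])
}

#' Genes expressed above an FPKM threshold in a tissue
#'
#' The comparison is inclusive (`>=`), so a gene whose tissue mean equals the
#' threshold is retained.
#'
#' @inheritParams tissue_mean
#' @param min_fpkm threshold (>= 0).
#' @return character vector of gene ids, in input row order.
#' @export
filter_expressed <- function(expr, tissue, min_fpkm) {
  stopifnot(min_fpkm >= 0)
  m <- tissue_mean(expr, tissue)
  names(m)[m >= min_fpkm]
}
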