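#' Pearson product-moment correlation
#'
#' Thin wrapper around the sample Pearson correlation that refuses constant
#' input instead of silently returning `NA` or 0: a gene with a flat profile
#' carries no co-expression information and must be excluded explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two vectors of equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y)
}

# Expression values on the configured correlation scale.
.coexpr_values <- function(expr, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  if (transform == "log2") log2(expr$fpkm + 1) else expr$fpkm
}

.pass <- function(r, threshold, mode) {
  if (mode == "strict") r >= threshold else r > threshold
}

#' Bait-anchored co-expression set
#'
#' Correlates every gene against one bait gene across all samples and
#' returns the genes passing the threshold.  Correlations are computed on
#' `log2(FPKM + 1)` by default, which stabilises the high dynamic range of
#' tissue panels; `transform = "raw"` correlates FPKM directly.  Genes with
#' constant profiles have no defined correlation and are excluded with a
#' warning.  The bait always belongs to its own set with `r = 1`.
#'
#' @param expr an `expression_matrix`.
#' @param bait bait gene id.
#' @param threshold correlation cutoff.
#' @param mode `"strict"` applies `r >= threshold`, `"open"` applies
#'   `r > threshold` (both usages occur in practice, e.g. r >= 0.95 for a
#'   single-bait screen and r > 0.6 for a multi-bait screen).
#' @param transform correlation scale, `"log2"` (default) or `"raw"`.
#' @param samples optional subset of sample ids to correlate over.
#' @return object of class `coexpression_result`: `bait_ids`, `r_values`
#'   (genes x baits matrix of correlations, `NA` for undefined), `threshold`,
#'   `mode`, and `members` (gene ids passing against every bait).
#' @export
bait_set <- function(expr, bait, threshold, mode = c("strict", "open"),
                     transform = c("log2", "raw"), samples = NULL) {
  multi_bait_set(expr, bait, threshold, mode, transform, samples)
}

#' Multi-bait co-expression intersection
#'
#' A gene is a member only if it passes the threshold against *every* bait
#' (intersection semantics); with a single bait this reduces to [bait_set()].
#'
#' @inheritParams bait_set
#' @param baits character vector of bait gene ids (non-empty).
#' @export
multi_bait_set <- function(expr, baits, threshold, mode = c("strict", "open"),
                           transform = c("log2", "raw"), samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  mode <- match.arg(mode)
  if (length(baits) == 0L) stop("empty bait list")
  vals <- .coexpr_values(expr, transform)
  if (!is.null(samples)) {
    stopifnot(all(samples %in% colnames(vals)))
    vals <- vals[, samples, drop = FALSE]
  }
  if (ncol(vals) < 3L) stop("need >= 3 samples to correlate")
  missing <- setdiff(baits, rownames(vals))
  if (length(missing))
    stop("bait(s) not in expression matrix: ", paste(missing, collapse = ", "))

  sds <- apply(vals, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant[baits]))
    stop("bait(s) with constant profile: ",
         paste(baits[constant[baits]], collapse = ", "))
  if (any(constant))
    warning(sum(constant), " gene(s) with constant profiles excluded ",
            "(undefined correlation)")

  r <- matrix(NA_real_, nrow(vals), length(baits),
              dimnames = list(rownames(vals), baits))
  ok <- !constant
  r[ok, ] <- stats::cor(t(vals[ok, , drop = FALSE]),
                        t(vals[baits, , drop = FALSE]))
  for (b in baits) r[b, b] <- 1   # self-correlation defined as exactly 1

  # A bait passes its own screen via its unit self-correlation, so a single
  # bait is always a member of its own set; under several baits each bait
  # must still pass against the others (intersection semantics).
  passing <- ok & apply(.pass(r, threshold, mode), 1L, function(z) all(!is.na(z) & z))
  members <- rownames(vals)[passing]

  structure(list(bait_ids = baits, r_values = r, threshold = threshold,
                 mode = mode, transform = match.arg(transform),
                 members = members),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  op <- if (x$mode == "strict") ">=" else ">"
  cat(sprintf("coexpression_result: %d member(s) at r %s %g against bait(s) %s\n",
              length(x$members), op, x$threshold,
              paste(x$bait_ids, collapse = ", ")))
  invisible(x)
}

#' Write a co-expression result as TSV
#'
#' One row per gene with its correlation against each bait and a pass flag.
#'
#' @param result a `coexpression_result`.
#' @param path output file.
#' @export
write_coexpression <- function(result, path) {
  df <- data.frame(gene_id = rownames(result$r_values),
                   result$r_values,
                   pass = rownames(result$r_values) %in% result$members,
                   check.names = FALSE)
  colnames(df)[seq_along(result$bait_ids) + 1L] <-
    paste0("r_", result$bait_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
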