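# BLOSUM62 over the 20 canonical residues, with the ambiguity code X scored 0
# against everything (tolerated but uninformative).
.blosum62 <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m20 <- matrix(v, 20, 20, byrow = TRUE, dimnames = list(aa, aa))
  m <- matrix(0, 21, 21, dimnames = list(c(aa, "X"), c(aa, "X")))
  m[aa, aa] <- m20
  m
})

#' Alignment parameters
#'
#' @param matrix substitution matrix: `"BLOSUM62"` (embedded; the ambiguity
#'   code `X` scores 0 against everything) or a symmetric numeric matrix
#'   with residue dimnames.
#' @param gap_open gap opening penalty (>= 0); a gap of length L costs
#'   `gap_open + gap_extend * L`.  Defaults 11/1, the standard protein
#'   BLAST values.
#' @param gap_extend gap extension penalty (>= 0).
#' @param identity_denominator denominator of percent identity:
#'   `"alignment_columns"` (default; internal gap columns count, terminal
#'   overhangs do not), `"shorter_sequence"` or `"longer_sequence"`.
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1,
                             identity_denominator = c("alignment_columns",
                                                      "shorter_sequence",
                                                      "longer_sequence")) {
  if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62"))
      stop("unknown substitution matrix: ", matrix)
    sub <- .blosum62
  } else {
    sub <- as.matrix(matrix)
    if (!isSymmetric(unname(sub)))
      stop("substitution matrix must be symmetric")
  }
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(sub = sub, gap_open = gap_open, gap_extend = gap_extend,
                 identity_denominator = match.arg(identity_denominator)),
            class = "alignment_params")
}

.aa_codes <- function(seq, alphabet) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, alphabet)
  if (anyNA(codes))
    stop("illegal residue(s): ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  codes - 1L  # 0-based for the C++ kernels
}

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch alignment under affine gap penalties, with a
#' deterministic traceback (ties resolved diagonal, then up, then left).
#'
#' @param a,b protein sequences (strings over the 20-letter alphabet; `X`
#'   tolerated and scored 0).
#' @param params an [alignment_params()] object.
#' @param id_a,id_b sequence identifiers carried into the result.
#' @return an `ortholog_pair`: `id_a`, `id_b`, gapped `aligned_a` /
#'   `aligned_b`, `score`, `percent_identity` (under `params`) and `rbh`
#'   (`NA` until set by [reciprocal_best_hits()]).
#' @examples
#' global_align("MKLV", "MKIV")
#' @export
global_align <- function(a, b, params = alignment_params(),
                         id_a = "seq_a", id_b = "seq_b") {
  stopifnot(inherits(params, "alignment_params"))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  alphabet <- rownames(params$sub)
  ca <- .aa_codes(a, alphabet)
  cb <- .aa_codes(b, alphabet)
  res <- nw_align_cpp(ca, cb, params$sub, params$gap_open, params$gap_extend)
  chars_a <- c("-", strsplit(toupper(a), "")[[1]])
  chars_b <- c("-", strsplit(toupper(b), "")[[1]])
  pair <- structure(list(
    id_a = id_a, id_b = id_b,
    aligned_a = paste(chars_a[res$path_a + 1L], collapse = ""),
    aligned_b = paste(chars_b[res$path_b + 1L], collapse = ""),
    score = res$score,
    percent_identity = NA_real_,
    rbh = NA
  ), class = "ortholog_pair")
  pair$percent_identity <- percent_identity(pair, params)
  pair
}

#' @export
print.ortholog_pair <- function(x, ...) {
  cat(sprintf("ortholog_pair %s / %s: score %.1f, identity %.1f%%%s\n",
              x$id_a, x$id_b, x$score, x$percent_identity,
              if (isTRUE(x$rbh)) ", RBH" else ""))
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' Counts columns where both sequences carry the same residue, divided by
#' the configured denominator.  With the default `"alignment_columns"`
#' denominator, terminal gap overhangs (leading/trailing columns before
#' both sequences have started / after one has ended) are excluded while
#' internal gap columns count against identity.
#'
#' @param pair an `ortholog_pair` from [global_align()].
#' @param params an [alignment_params()] object.
#' @return identity as a percentage in `[0, 100]`.
#' @export
percent_identity <- function(pair, params = alignment_params()) {
  a <- strsplit(pair$aligned_a, "")[[1]]
  b <- strsplit(pair$aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  res_a <- a != "-"
  res_b <- b != "-"
  ident <- sum(res_a & res_b & a == b)
  both <- which(res_a & res_b)
  denom <- switch(params$identity_denominator,
    alignment_columns = if (length(both)) max(both) - min(both) + 1L else 0L,
    shorter_sequence = min(sum(res_a), sum(res_b)),
    longer_sequence = max(sum(res_a), sum(res_b)))
  if (denom == 0L) return(0)
  100 * ident / denom
}

.as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L)
    stop("proteome must be a non-empty named character vector of sequences")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  x
}

#' Reciprocal-best-hit orthologue mapping
#'
#' Aligns every sequence of proteome A against every sequence of proteome B
#' and reports the pairs that are each other's unique top-scoring partner.
#' Genes whose top score is tied between several partners get no RBH call
#' (reported via a message), as a tie cannot identify an orthologue.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences (or `Biostrings::AAStringSet`).
#' @param params an [alignment_params()] object.
#' @return list of `ortholog_pair` objects with `rbh = TRUE`; see
#'   [rbh_table()] for a tabular view.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  proteome_a <- .as_seq_vector(proteome_a)
  proteome_b <- .as_seq_vector(proteome_b)
  alphabet <- rownames(params$sub)
  ca <- lapply(proteome_a, .aa_codes, alphabet = alphabet)
  cb <- lapply(proteome_b, .aa_codes, alphabet = alphabet)
  sc <- nw_score_matrix_cpp(ca, cb, params$sub, params$gap_open,
                            params$gap_extend)
  dimnames(sc) <- list(names(proteome_a), names(proteome_b))

  best_unique <- function(v) {
    top <- max(v)
    hits <- which(v == top)
    if (length(hits) == 1L) hits else NA_integer_
  }
  best_b <- apply(sc, 1L, best_unique)   # per A gene
  best_a <- apply(sc, 2L, best_unique)   # per B gene
  tied <- c(rownames(sc)[is.na(best_b)], colnames(sc)[is.na(best_a)])
  if (length(tied))
    message("tied top scores, no RBH call for: ", paste(tied, collapse = ", "))

  pairs <- list()
  for (i in seq_len(nrow(sc))) {
    j <- best_b[i]
    if (!is.na(j) && !is.na(best_a[j]) && best_a[j] == i) {
      p <- global_align(proteome_a[[i]], proteome_b[[j]], params,
                        id_a = names(proteome_a)[i],
                        id_b = names(proteome_b)[j])
      p$rbh <- TRUE
      pairs[[length(pairs) + 1L]] <- p
    }
  }
  pairs
}

#' Tabulate ortholog pairs
#'
#' @param pairs list of `ortholog_pair` objects.
#' @return data.frame with `id_a`, `id_b`, `score`, `percent_identity`,
#'   `rbh`.
#' @export
rbh_table <- function(pairs) {
  if (length(pairs) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), percent_identity = numeric(),
                      rbh = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(pairs, function(p)
    data.frame(id_a = p$id_a, id_b = p$id_b, score = p$score,
               percent_identity = p$percent_identity,
               rbh = isTRUE(p$rbh), stringsAsFactors = FALSE)))
}

#' All-against-all percent identity within one sequence set
#'
#' Convenience for tree building: global alignment identity for every pair
#' of taxa.
#'
#' @param seqs named character vector of protein sequences.
#' @param params an [alignment_params()] object.
#' @return symmetric matrix of identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, params = alignment_params()) {
  seqs <- .as_seq_vector(seqs)
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      p <- global_align(seqs[[i]], seqs[[j]], params,
                        id_a = names(seqs)[i], id_b = names(seqs)[j])
      m[i, j] <- m[j, i] <- p$percent_identity
    }
  }
  m
}
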