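#' Distance matrix from percent identities
#'
#' `d = 1 - identity / 100`: a simple p-distance-style dissimilarity, which
#' is all a topology-level clade test needs.
#'
#' @param x either a symmetric identity matrix (as from
#'   [identity_matrix()]) or a list of `ortholog_pair` objects covering all
#'   pairs of the taxon set.
#' @return symmetric non-negative distance matrix with zero diagonal
#'   (class `dist_matrix`).
#' @export
distance_from_identity <- function(x) {
  if (is.matrix(x)) {
    idm <- x
  } else {
    tab <- rbh_table(x)
    taxa <- sort(unique(c(tab$id_a, tab$id_b)))
    idm <- matrix(NA_real_, length(taxa), length(taxa),
                  dimnames = list(taxa, taxa))
    diag(idm) <- 100
    for (r in seq_len(nrow(tab))) {
      idm[tab$id_a[r], tab$id_b[r]] <- tab$percent_identity[r]
      idm[tab$id_b[r], tab$id_a[r]] <- tab$percent_identity[r]
    }
    if (anyNA(idm)) {
      miss <- which(is.na(idm), arr.ind = TRUE)[1, ]
      stop("missing pairwise identity for taxa ",
           rownames(idm)[miss[1]], " / ", colnames(idm)[miss[2]])
    }
  }
  stopifnot(isSymmetric(unname(idm)))
  d <- 1 - idm / 100
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix (via `ape::nj`).
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with a message, the usual practice before topology
#' interpretation.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- unclass(dm)
  stopifnot(is.matrix(dm), isSymmetric(unname(dm)))
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa")
  tree <- ape::nj(as.dist(dm))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Test whether a taxon set forms a clade
#'
#' Roots the tree on the designated outgroup and asks whether the subset is
#' monophyletic under that rooting -- the form in which clade claims such as
#' "the producer and non-producer acyltransferases cluster together, apart
#' from canonical malonyltransferases" are asserted.
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa_subset tip labels claimed to form a clade (must not contain
#'   the outgroup).
#' @param outgroup tip label used for rooting.
#' @return `TRUE` iff the subset is monophyletic after rooting.
#' @export
is_monophyletic <- function(tree, taxa_subset, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(c(taxa_subset, outgroup), tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (outgroup %in% taxa_subset)
    stop("outgroup must not be part of the tested subset")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa_subset)
}

#' Read/write Newick trees
#'
#' Thin wrappers over `ape` so that pipeline outputs round-trip through
#' plain text.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` its `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
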