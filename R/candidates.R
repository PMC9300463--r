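GENE_FAMILIES <- c("P450", "ABH", "MDR", "BAHD", "OMT", "other")

#' Validate a gene annotation table
#'
#' Annotations are an input (from external domain annotation in real use,
#' from the generator in tests): `gene_id`, protein `family` from the
#' controlled vocabulary (P450, ABH, MDR, BAHD, OMT, other) and a
#' `full_length` flag.
#'
#' @param df data.frame with columns `gene_id`, `family`, `full_length`.
#' @return the validated data.frame (class `gene_annotations`).
#' @export
gene_annotations <- function(df) {
  stopifnot(all(c("gene_id", "family", "full_length") %in% names(df)))
  bad <- setdiff(unique(df$family), GENE_FAMILIES)
  if (length(bad))
    stop("family labels outside controlled vocabulary: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in annotations")
  df$full_length <- as.logical(df$full_length)
  class(df) <- c("gene_annotations", "data.frame")
  df
}

#' Select pathway gene candidates by the three discovery criteria
#'
#' Applies, in order: (1) expression in the target tissue at or above
#' `min_fpkm`; (2) co-expression with every bait at the chosen threshold;
#' (3) membership of the requested protein family (full-length entries
#' only), the codifiable part of "catalytic function consistent with the
#' pathway's chemical logic".  Rows are ranked by the minimum correlation
#' over baits (descending), ties broken by tissue-mean FPKM (descending)
#' then gene id, so that output order is reproducible.
#'
#' @param expr an `expression_matrix`.
#' @param annotations a [gene_annotations()] table.
#' @param baits bait gene id(s).
#' @param family family label to screen, or `"all"` for every family.
#' @param min_fpkm tissue-expression threshold (default 20).
#' @param r_threshold correlation threshold.
#' @param mode `"strict"` (`>=`) or `"open"` (`>`).
#' @param tissue tissue for criterion (1), default `"root"`.
#' @param transform correlation scale passed to [multi_bait_set()].
#' @return a `candidate_table` data.frame with columns `gene_id`, `family`,
#'   `root_mean_fpkm`, one `r_<bait>` column per bait, `min_r` and `passes`.
#' @export
select_candidates <- function(expr, annotations, baits, family = "all",
                              min_fpkm = 20, r_threshold = 0.95,
                              mode = c("strict", "open"), tissue = "root",
                              transform = c("log2", "raw")) {
  mode <- match.arg(mode)
  annotations <- gene_annotations(as.data.frame(annotations))
  if (!identical(family, "all") && !family %in% GENE_FAMILIES)
    stop("unknown family: ", family)

  expressed <- filter_expressed(expr, tissue, min_fpkm)
  coex <- multi_bait_set(expr, baits, r_threshold, mode, transform)

  keep <- annotations$full_length &
    (identical(family, "all") | annotations$family == family) &
    annotations$gene_id %in% intersect(expressed, coex$members)
  ids <- annotations$gene_id[keep]
  if (length(ids) == 0L) {
    message("no candidate of family '", family, "' survives the screen")
  }

  tm <- tissue_mean(expr, tissue)[ids]
  r <- coex$r_values[ids, , drop = FALSE]
  min_r <- if (length(ids)) apply(r, 1L, min) else numeric(0)
  out <- data.frame(gene_id = ids,
                    family = annotations$family[keep],
                    root_mean_fpkm = unname(tm),
                    r, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (length(baits))
    colnames(out)[seq_along(baits) + 3L] <- paste0("r_", coex$bait_ids)
  out$min_r <- unname(min_r)
  out$passes <- rep(TRUE, length(ids))
  out <- out[order(-out$min_r, -out$root_mean_fpkm, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Producer/non-producer comparative presence of candidates
#'
#' Joins a candidate table to the reciprocal-best-hit orthologue map of a
#' second (e.g. non-producing) species; candidates without an RBH partner
#' are flagged absent.  Shared early-pathway candidates are expected to have
#' high-identity partners, while lineage-specific late steps may not.
#'
#' @param producer_candidates a `candidate_table`.
#' @param ortholog_map list of `ortholog_pair` objects (or the data.frame
#'   from [rbh_table()]) with `rbh = TRUE` entries mapping producer ids to
#'   partner ids.
#' @return data.frame with `gene_id`, `ortholog` (`NA` if absent),
#'   `percent_identity` and `absent`.
#' @export
comparative_presence <- function(producer_candidates, ortholog_map) {
  map <- if (is.data.frame(ortholog_map)) ortholog_map else rbh_table(ortholog_map)
  map <- map[map$rbh, , drop = FALSE]
  idx <- match(producer_candidates$gene_id, map$id_a)
  data.frame(
    gene_id = producer_candidates$gene_id,
    ortholog = map$id_b[idx],
    percent_identity = map$percent_identity[idx],
    absent = is.na(idx),
    stringsAsFactors = FALSE
  )
}
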