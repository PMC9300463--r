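#' Write a synthetic dataset to a directory
#'
#' Emits `counts.tsv` (gene_id, length, one column per sample),
#' `design.tsv` (sample, tissue), `truth.json` (planted module and bait) and
#' `proteins.faa` / `kinetics.tsv` when the companion pieces are supplied.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(gene_id = rownames(dataset$counts),
                       length = unname(dataset$gene_lengths),
                       dataset$counts, check.names = FALSE)
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(truth_module = dataset$truth_module,
                            bait_id = dataset$bait_id,
                            seed = dataset$config$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a counts TSV plus design TSV
#'
#' Inverse of [write_dataset()]: `counts.tsv` must have `gene_id` and
#' `length` columns followed by one column per sample; `design.tsv` maps
#' samples to tissues.
#'
#' @param counts_path path to the counts TSV.
#' @param design_path path to the design TSV.
#' @return a [counts_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  stopifnot(all(c("gene_id", "length") %in% names(df)))
  design <- utils::read.delim(design_path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length")), drop = FALSE])
  rownames(m) <- df$gene_id
  counts_matrix(m, stats::setNames(df$length, df$gene_id), design)
}

#' Write an FPKM matrix as TSV
#'
#' @param expr an `expression_matrix`.
#' @param path output file.
#' @export
write_fpkm <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write protein FASTA
#'
#' Wrappers around `Biostrings` returning plain named character vectors;
#' sequences are written wrapped at 60 columns and description lines are
#' preserved as names.
#'
#' @param path FASTA file.
#' @param seqs named character vector of protein sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Columns `gene_id`, `family`, `full_length`.
#'
#' @param path TSV file.
#' @return a [gene_annotations()] table.
#' @export
read_annotations <- function(path) {
  gene_annotations(utils::read.delim(path, check.names = FALSE))
}

#' Write a candidate table as TSV
#'
#' @param table a `candidate_table`.
#' @param path output file.
#' @export
write_candidates <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
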