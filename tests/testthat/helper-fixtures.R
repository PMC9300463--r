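# Small in-code fixtures shared across test files.

# Expression matrix built directly from an FPKM matrix and tissue labels.
toy_expr <- function(fpkm, tissues) {
  if (is.null(rownames(fpkm)))
    rownames(fpkm) <- paste0("g", seq_len(nrow(fpkm)))
  if (is.null(colnames(fpkm)))
    colnames(fpkm) <- paste0("s", seq_len(ncol(fpkm)))
  structure(list(fpkm = fpkm,
                 design = data.frame(sample = colnames(fpkm),
                                     tissue = tissues,
                                     stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

# An FPKM matrix whose log2(FPKM + 1) rows are exact affine transforms of a
# shared profile (perfect co-expression) on top of random background rows.
noiseless_module_expr <- function(n_bg = 20, n_mod = 4, seed = 42) {
  set.seed(seed)
  # integer log2 profile: all downstream arithmetic is exact, so module rows
  # correlate at exactly 1.0 on the log2(FPKM + 1) scale
  profile <- c(10, 9, 3, 4, 2, 3)           # root-elevated
  mod <- t(vapply(seq_len(n_mod), function(i) 2^(profile + i) - 1,
                  numeric(length(profile))))
  bg <- matrix(2^stats::runif(n_bg * length(profile), 1, 10) - 1,
               n_bg, length(profile))
  fpkm <- rbind(mod, bg)
  rownames(fpkm) <- c(paste0("mod", seq_len(n_mod)),
                      paste0("bg", seq_len(n_bg)))
  colnames(fpkm) <- paste0("s", seq_len(length(profile)))
  toy_expr(fpkm, rep(c("root", "stem", "leaf"), each = 2))
}

random_protein <- function(len) {
  paste(sample(baitminer:::AA_ALPHABET20, len, replace = TRUE),
        collapse = "")
}

default_sim <- function(seed = 1, ...) {
  simulate_transcriptome(sim_config(n_genes = 300, pathway_size = 6,
                                    seed = seed, ...))
}

expr_of <- function(dataset) {
  compute_fpkm(counts_matrix(dataset$counts, dataset$gene_lengths,
                             dataset$design))
}
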