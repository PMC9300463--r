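#' Pipeline configuration
#'
#' A single configuration object drives the whole discovery chain so that
#' every threshold is auditable.  Defaults mirror the discovery screen the
#' package codifies: tissue filter FPKM >= 20 in root, r >= 0.95 for the
#' single-bait screen, r > 0.6 for the multi-bait screen and r > 0.7 for
#' family-wide screens.
#'
#' @param counts,design,annotations paths to the counts/design/annotation
#'   TSVs ([read_counts()], [read_annotations()]).
#' @param proteome_a,proteome_b optional producer / non-producer protein
#'   FASTA paths for the orthology and comparative stages.
#' @param kinetics optional kinetics TSV path ([read_kinetics()]).
#' @param baits character vector of bait gene ids (non-empty).
#' @param tissue tissue for the expression filter (default `"root"`).
#' @param min_fpkm expression threshold, default 20.
#' @param r_threshold correlation threshold, default 0.95.
#' @param mode `"strict"` (`>=`, default) or `"open"` (`>`).
#' @param family candidate family to screen, default `"all"`.
#' @param transform correlation scale, `"log2"` or `"raw"`.
#' @param out_dir output directory.
#' @param seed integer seed stamped into outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, design, annotations,
                            proteome_a = NULL, proteome_b = NULL,
                            kinetics = NULL,
                            baits, tissue = "root", min_fpkm = 20,
                            r_threshold = 0.95,
                            mode = c("strict", "open"),
                            family = "all",
                            transform = c("log2", "raw"),
                            out_dir = "baitminer_out", seed = 1L) {
  cfg <- list(counts = counts, design = design, annotations = annotations,
              proteome_a = proteome_a, proteome_b = proteome_b,
              kinetics = kinetics, baits = baits, tissue = tissue,
              min_fpkm = min_fpkm, r_threshold = r_threshold,
              mode = match.arg(mode), family = family,
              transform = match.arg(transform),
              out_dir = out_dir, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$baits) == 0L || !all(nzchar(cfg$baits)))
    stop("validation error: bait list must be non-empty")
  if (cfg$min_fpkm < 0)
    stop("validation error: min_fpkm must be >= 0")
  if (cfg$r_threshold < -1 || cfg$r_threshold > 1)
    stop("validation error: r_threshold must lie in [-1, 1]")
  for (f in c("counts", "design", "annotations",
              "proteome_a", "proteome_b", "kinetics")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("validation error: ", f, " file not found: ", p)
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments; `baits`
#' may be a YAML list.  Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  for (f in c("counts", "design", "annotations", "proteome_a", "proteome_b",
              "kinetics"))
    y[[f]] <- rel(y[[f]])
  y$baits <- unlist(y$baits)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end discovery pipeline
#'
#' Chains quantification (counts to FPKM), tissue filtering, bait-anchored
#' co-expression, family-stratified candidate selection and, when proteomes
#' and kinetics data are configured, reciprocal-best-hit orthologue mapping
#' with a neighbor-joining tree and a Michaelis-Menten fit.  All stage
#' outputs are written under `config$out_dir` together with a JSON summary
#' stamped with the configuration hash and seed; a rerun with the same
#' configuration reproduces the outputs byte for byte.
#'
#' @param config a `pipeline_config`.
#' @return the summary list, invisibly (also written to `summary.json`).
#' @export
run_discovery <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)  # truncate

  counts <- .stage("read_counts",
                   read_counts(config$counts, config$design))
  logf("counts: %d genes x %d samples", nrow(counts$counts),
       ncol(counts$counts))

  expr <- .stage("fpkm", compute_fpkm(counts))
  write_fpkm(expr, file.path(config$out_dir, "fpkm.tsv"))

  expressed <- .stage("tissue_filter",
                      filter_expressed(expr, config$tissue, config$min_fpkm))
  logf("tissue filter: %d genes with %s mean FPKM >= %g",
       length(expressed), config$tissue, config$min_fpkm)

  coex <- .stage("coexpression",
                 multi_bait_set(expr, config$baits, config$r_threshold,
                                config$mode, config$transform))
  write_coexpression(coex, file.path(config$out_dir, "coexpression.tsv"))
  logf("coexpression: %d genes pass r %s %g against %d bait(s)",
       length(coex$members), if (config$mode == "strict") ">=" else ">",
       config$r_threshold, length(config$baits))

  annotations <- .stage("annotations", read_annotations(config$annotations))
  candidates <- .stage("candidate_selection",
                       select_candidates(expr, annotations, config$baits,
                                         family = config$family,
                                         min_fpkm = config$min_fpkm,
                                         r_threshold = config$r_threshold,
                                         mode = config$mode,
                                         tissue = config$tissue,
                                         transform = config$transform))
  write_candidates(candidates, file.path(config$out_dir, "candidates.tsv"))
  logf("candidates: %d rows", nrow(candidates))

  summary <- list(
    config_hash = unname(tools::md5sum(config$counts)),
    seed = config$seed,
    thresholds = list(min_fpkm = config$min_fpkm,
                      r_threshold = config$r_threshold, mode = config$mode),
    n_genes = nrow(counts$counts),
    n_expressed = length(expressed),
    n_coexpressed = length(coex$members),
    candidates_per_family = as.list(table(candidates$family)),
    top_candidates = utils::head(candidates$gene_id, 20L)
  )

  if (!is.null(config$proteome_a) && !is.null(config$proteome_b)) {
    pa <- .stage("orthology", read_fasta(config$proteome_a))
    pb <- .stage("orthology", read_fasta(config$proteome_b))
    pairs <- .stage("orthology", reciprocal_best_hits(pa, pb))
    tab <- rbh_table(pairs)
    utils::write.table(tab, file.path(config$out_dir, "orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("orthology: %d RBH pairs over %d x %d proteins",
         nrow(tab), length(pa), length(pb))
    presence <- comparative_presence(candidates, tab)
    utils::write.table(presence,
                       file.path(config$out_dir, "comparative_presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$rbh_pairs <- nrow(tab)
    summary$rbh_coverage <- if (nrow(candidates))
      mean(!presence$absent) else NA
    if (length(pa) + length(pb) >= 3L) {
      idm <- .stage("tree", identity_matrix(c(pa, pb)))
      tree <- .stage("tree", neighbor_joining(distance_from_identity(idm)))
      write_newick(tree, file.path(config$out_dir, "tree.nwk"))
      summary$tree_taxa <- length(tree$tip.label)
    }
  }

  if (!is.null(config$kinetics)) {
    fit <- .stage("kinetics", fit_mm(read_kinetics(config$kinetics)))
    summary$kinetics <- list(kcat = fit$kcat, km = fit$km,
                             efficiency = fit$efficiency,
                             converged = fit$converged)
    logf("kinetics: kcat/Km = %.4g min^-1 uM^-1", fit$efficiency)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
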