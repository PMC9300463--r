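#' Simulation configuration for a planted-module transcriptome
#'
#' Describes a replicated multi-tissue bulk RNA-seq experiment containing a
#' single co-regulated pathway module preferentially expressed in one tissue
#' (by default the root, mirroring the tissue distribution of alkaloid
#' pathway genes), embedded in a background of mutually independent genes.
#'
#' @param n_genes total number of genes.
#' @param pathway_size number of planted pathway genes (must be `< n_genes`).
#' @param n_tissues number of tissues; the default 3 is labelled
#'   `root`/`stem`/`leaf`.
#' @param n_replicates_per_tissue biological replicates per tissue (default 2,
#'   i.e. two sample sets per organ).
#' @param pathway_tissue tissue in which the module is enriched.
#' @param module_correlation target expected pairwise Pearson correlation of
#'   `log2(FPKM + 1)` between module genes, in `[0, 1]`.
#' @param fold_root_enrichment fold elevation of module expression in
#'   `pathway_tissue` relative to the other tissues (>= 1).
#' @param nb_dispersion negative-binomial dispersion `phi` with
#'   `Var = mu + mu^2 / phi`; `phi = 100` corresponds to a biological
#'   coefficient of variation of 0.1, appropriate for repeated harvests from
#'   the same individuals.  `Inf` yields deterministic expected counts (the
#'   noise-free limit used for sanity checks).
#' @param baseline_mean expected baseline count per gene (location of the
#'   per-gene abundance distribution).
#' @param gene_length_range transcript length interval in bp.
#' @param library_size_range per-sample sequencing depth interval (read pairs).
#' @param tissues optional character vector of tissue labels (length
#'   `n_tissues`).
#' @param seed integer seed; every random draw in the generator flows from it.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_transcriptome()]
#' @export
sim_config <- function(n_genes,
                       pathway_size,
                       n_tissues = 3L,
                       n_replicates_per_tissue = 2L,
                       pathway_tissue = "root",
                       module_correlation = 0.97,
                       fold_root_enrichment = 20,
                       nb_dispersion = 100,
                       baseline_mean = 500,
                       gene_length_range = c(500, 3000),
                       library_size_range = c(8e5, 1.2e6),
                       tissues = NULL,
                       seed = 1L) {
  if (is.null(tissues)) {
    tissues <- if (n_tissues == 3L) c("root", "stem", "leaf") else
      paste0("tissue", seq_len(n_tissues))
  }
  stopifnot(length(tissues) == n_tissues)
  cfg <- list(
    n_genes = as.integer(n_genes),
    pathway_size = as.integer(pathway_size),
    n_tissues = as.integer(n_tissues),
    n_replicates_per_tissue = as.integer(n_replicates_per_tissue),
    pathway_tissue = pathway_tissue,
    module_correlation = module_correlation,
    fold_root_enrichment = fold_root_enrichment,
    nb_dispersion = nb_dispersion,
    baseline_mean = baseline_mean,
    gene_length_range = gene_length_range,
    library_size_range = library_size_range,
    tissues = tissues,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$pathway_size >= cfg$n_genes)
    stop("configuration error: pathway_size must be smaller than n_genes")
  if (cfg$n_genes < 1L || cfg$n_tissues < 1L || cfg$n_replicates_per_tissue < 1L)
    stop("configuration error: all counts must be >= 1")
  if (cfg$module_correlation < 0 || cfg$module_correlation > 1)
    stop("configuration error: module_correlation must lie in [0, 1]")
  if (cfg$fold_root_enrichment < 1)
    stop("configuration error: fold_root_enrichment must be >= 1")
  if (!is.infinite(cfg$nb_dispersion) && cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be > 0")
  if (cfg$baseline_mean <= 0)
    stop("configuration error: baseline_mean must be > 0")
  if (!cfg$pathway_tissue %in% cfg$tissues)
    stop("configuration error: pathway_tissue not among tissue labels")
  invisible(cfg)
}

# Orthonormal basis of the subspace of R^S orthogonal to the intercept and to
# the centred shared profile.  Perturbation directions live here so that they
# change neither a gene's mean level nor its projection on the module signal.
.perp_basis <- function(Sc) {
  S <- length(Sc)
  anchors <- cbind(rep(1, S), if (any(Sc != 0)) Sc)
  Q <- qr.Q(qr(cbind(anchors, diag(S))))
  Q[, seq(ncol(anchors) + 1L, S), drop = FALSE]
}

# m unit vectors in R^d with low mutual coherence: exactly orthonormal when
# they fit, otherwise a fixed-step frame-potential descent spreads them as
# evenly as the dimension allows (approximately balanced: directions sum to
# ~0).  Low coherence makes realized pairwise correlations concentrate at
# the target instead of merely averaging to it.
.spread_directions <- function(m, d) {
  V <- matrix(stats::rnorm(d * m), d, m)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  if (m <= d) return(qr.Q(qr(V))[, seq_len(m), drop = FALSE])
  eta <- 0.3 / m
  for (it in seq_len(1200L)) {
    G <- crossprod(V)
    diag(G) <- 0
    V <- V - eta * (V %*% (G * abs(G)))
    V <- V - rowMeans(V)
    V <- sweep(V, 2, pmax(sqrt(colSums(V^2)), 1e-12), "/")
  }
  V
}

# k unit perturbation directions in the span of `basis`, anchored on the
# first (bait) gene: every other direction has dot exactly -1/(k-1) with the
# bait's, so each module member departs from the bait by the same amount and
# the bait correlations sit at the target rather than spreading around it;
# the residual spread lives in the bait-free pairs.
.latent_frame <- function(k, basis) {
  d <- ncol(basis)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  if (k == 1L || d < 2L) {
    V <- Q[, 1L, drop = FALSE] %*% rbind(rep_len(c(1, -1), k))
  } else {
    alpha <- 1 / (k - 1)
    W <- .spread_directions(k - 1L, d - 1L)
    V <- cbind(Q[, 1L],
               -alpha * Q[, 1L] +
                 sqrt(1 - alpha^2) * (Q[, -1L, drop = FALSE] %*% W))
  }
  basis %*% V
}

#' Simulate a replicated multi-tissue transcriptome with a planted module
#'
#' Background genes receive tissue-independent negative-binomial counts with
#' independent per-gene latent means (log-normal around `baseline_mean`).
#' The planted pathway module shares one latent expression profile, elevated
#' `fold_root_enrichment`-fold in `pathway_tissue`, plus (i) a shared
#' per-sample Gamma state that carries the module's biological overdispersion
#' -- co-regulated genes respond to the same cellular state, which is what
#' makes them co-expressed in real tissue panels -- and (ii) a per-gene
#' fixed-norm perturbation whose variance is solved from
#' `module_correlation` after subtracting the expected Poisson counting
#' noise, so that the expected pairwise Pearson correlation of
#' `log2(FPKM + 1)` within the module equals the target.  Marginally every
#' count is NB(mean, dispersion); only the module's cross-gene dependence is
#' special.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_dataset`: a list with `counts`
#'   (genes x samples integer matrix), `gene_lengths` (named bp vector),
#'   `design` (data.frame with `sample`, `tissue`), `truth_module`
#'   (planted gene ids), `bait_id` (one module gene, the designated bait)
#'   and `config`.
#' @examples
#' d <- simulate_transcriptome(sim_config(n_genes = 200, pathway_size = 5))
#' dim(d$counts)
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  k <- config$pathway_size
  tissue_of <- rep(config$tissues, each = config$n_replicates_per_tissue)
  S <- length(tissue_of)
  sample_ids <- paste0(tissue_of, "_", rep(seq_len(config$n_replicates_per_tissue),
                                           times = config$n_tissues))
  gene_ids <- sprintf("gene%05d", seq_len(n))

  gene_lengths <- round(stats::runif(n, config$gene_length_range[1],
                                     config$gene_length_range[2]))
  lib_sizes <- round(stats::runif(S, config$library_size_range[1],
                                  config$library_size_range[2]))
  log2_base <- stats::rnorm(n, log2(config$baseline_mean), 1)
  module_idx <- sort(sample.int(n, k))
  offsets <- stats::rnorm(k, 0, 0.5)

  shared <- log2(config$baseline_mean) +
    log2(config$fold_root_enrichment) * (tissue_of == config$pathway_tissue)
  phi <- config$nb_dispersion
  # Per-sample regulatory state shared by the module (Poisson-Gamma: this
  # Gamma carries the module's overdispersion, so marginal module counts are
  # still NB(mean, phi) while co-regulated genes fluctuate together).
  gamma_state <- if (is.infinite(phi)) rep(1, S) else
    stats::rgamma(S, shape = phi, rate = phi)

  # Expected counts at zero perturbation, and the shared profile as it will
  # appear on the log2-FPKM scale: FPKM divides by the per-sample count
  # total, which the module's own spike inflates in the enriched tissue, so
  # calibration must target the normalized profile, realized Gamma included.
  w0 <- matrix(2^log2_base, n, S)
  if (k > 0) w0[module_idx, ] <- 2^outer(offsets, shared, "+")
  colw0 <- colSums(w0)
  mu0 <- sweep(sweep(w0, 2, colw0, "/"), 2, lib_sizes, "*")
  mod_share <- if (k > 0)
    colSums(w0[module_idx, , drop = FALSE]) / colw0 else rep(0, S)
  pred_total <- lib_sizes * (1 + (gamma_state - 1) * mod_share)
  shared_fpkm <- shared + log2(gamma_state) - log2(colw0) - log2(pred_total)
  Sc <- shared_fpkm - mean(shared_fpkm)

  # Per-gene perturbation directions and calibrated magnitude: fixed-norm
  # directions orthogonal to the realized shared profile, with the norm
  # solved so the expected pairwise log2-FPKM correlation (Poisson counting
  # noise included) hits the target.
  U <- NULL
  cval <- 0
  if (k >= 1L && S >= 3L) U <- .latent_frame(k, .perp_basis(Sc))
  r_target <- config$module_correlation
  if (k >= 2L && sum(Sc^2) > 0 && r_target < 1) {
    sigma_n2 <- if (is.infinite(phi)) 0 else
      mean(1 / (mu0[module_idx, ] * rep(gamma_state, each = k))) / log(2)^2
    G <- crossprod(U)
    M <- mean((2 - 2 * G[upper.tri(G)]))
    c2 <- (2 * (1 - r_target) * sum(Sc^2) - 2 * (S - 2) * sigma_n2) / M
    cval <- sqrt(max(0, c2))
  }

  W <- matrix(2^log2_base, n, S)
  if (k > 0) {
    log2_mod <- outer(offsets, shared, "+")
    if (!is.null(U) && cval > 0) log2_mod <- log2_mod + cval * t(U)
    W[module_idx, ] <- 2^log2_mod
  }
  mu <- sweep(sweep(W, 2, colSums(W), "/"), 2, lib_sizes, "*")

  counts <- matrix(0L, n, S, dimnames = list(gene_ids, sample_ids))
  if (is.infinite(phi)) {
    counts[] <- as.integer(round(mu))
  } else {
    bg <- setdiff(seq_len(n), module_idx)
    counts[bg, ] <- stats::rnbinom(length(bg) * S, mu = mu[bg, ], size = phi)
    if (k > 0) {
      lambda <- sweep(mu[module_idx, , drop = FALSE], 2, gamma_state, "*")
      counts[module_idx, ] <- stats::rpois(k * S, lambda = lambda)
    }
  }
  storage.mode(counts) <- "integer"

  structure(list(
    counts = counts,
    gene_lengths = stats::setNames(gene_lengths, gene_ids),
    design = data.frame(sample = sample_ids, tissue = tissue_of,
                        stringsAsFactors = FALSE),
    truth_module = gene_ids[module_idx],
    bait_id = if (k > 0) gene_ids[module_idx[1]] else NA_character_,
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d samples (%d tissues), %d planted module genes, bait %s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$tissue)),
              length(x$truth_module), x$bait_id))
  invisible(x)
}

#' Mutate a protein sequence to a target percent identity
#'
#' Substitutes exactly `round((1 - target_identity) * nchar(parent))`
#' positions (chosen without replacement) with residues drawn uniformly from
#' the 19 alternatives.  No indels are introduced, so the realized identity
#' is exact to within one position and independent of any aligner.
#'
#' @param parent protein sequence (single string over the 20-letter alphabet).
#' @param target_identity fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return the mutated sequence (same length as `parent`).
#' @examples
#' mutate_orthologue("MKLVNNACDE", 0.8, seed = 1)
#' @export
mutate_orthologue <- function(parent, target_identity, seed = 1L) {
  if (!is.character(parent) || length(parent) != 1L || nchar(parent) == 0L)
    stop("parent must be a single non-empty protein sequence")
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  L <- nchar(parent)
  n_sub <- round((1 - target_identity) * L)
  if (n_sub == 0L) return(parent)
  set.seed(seed)
  pos <- sample.int(L, n_sub)
  chars <- strsplit(parent, "")[[1]]
  for (p in pos) {
    alt <- setdiff(AA_ALPHABET20, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Simulate a pair of orthologous proteomes
#'
#' Draws `n_proteins` random parent proteins and derives a child proteome by
#' point substitution at a controlled identity, standing in for a
#' producer/non-producer species pair.
#'
#' @param n_proteins number of proteins.
#' @param length residues per protein.
#' @param target_identity fraction in `(0, 1]` shared by all pairs, or a
#'   vector of length `n_proteins`.
#' @param seed integer seed.
#' @return object of class `synthetic_proteome`: named character vectors
#'   `parent_sequences` and `child_sequences` (ids `P001`... / `C001`...),
#'   plus `target_identity` and `realized_identity` per pair.
#' @export
simulate_proteome <- function(n_proteins = 20L, length = 300L,
                              target_identity = 0.9, seed = 1L) {
  stopifnot(n_proteins >= 1L, length >= 1L)
  target_identity <- rep_len(target_identity, n_proteins)
  set.seed(seed)
  parents <- vapply(seq_len(n_proteins), function(i)
    paste(sample(AA_ALPHABET20, length, replace = TRUE), collapse = ""), "")
  names(parents) <- sprintf("P%03d", seq_len(n_proteins))
  children <- vapply(seq_len(n_proteins), function(i)
    mutate_orthologue(parents[[i]], target_identity[i], seed = seed + i), "")
  names(children) <- sprintf("C%03d", seq_len(n_proteins))
  realized <- 1 - round((1 - target_identity) * length) / length
  structure(list(parent_sequences = parents, child_sequences = children,
                 target_identity = target_identity,
                 realized_identity = realized),
            class = "synthetic_proteome")
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' `v_i = kcat * E0 * S_i / (Km + S_i) * (1 + eps_i)` with
#' `eps_i ~ Normal(0, noise_cv)` (multiplicative error, as initial-rate
#' measurements typically scale with signal).
#'
#' @param kcat turnover number, min^-1.
#' @param km Michaelis constant, uM.
#' @param enzyme_conc total enzyme, uM.
#' @param substrate_concs vector of substrate concentrations, uM.
#' @param noise_cv coefficient of variation of the multiplicative error
#'   (0 for noiseless data).
#' @param seed integer seed.
#' @return object of class `kinetics_dataset` with `substrate_conc`,
#'   `velocity` (uM min^-1), `enzyme_conc` and the generating `truth`.
#' @examples
#' simulate_kinetics(2, 5, 0.1, c(1, 2, 5, 10, 20, 50))
#' @export
simulate_kinetics <- function(kcat, km, enzyme_conc, substrate_concs,
                              noise_cv = 0, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  stopifnot(kcat > 0, km > 0, enzyme_conc > 0,
            length(substrate_concs) >= 1L, all(substrate_concs > 0))
  v <- kcat * enzyme_conc * substrate_concs / (km + substrate_concs)
  if (noise_cv > 0) {
    set.seed(seed)
    v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  }
  structure(list(substrate_conc = substrate_concs,
                 velocity = pmax(v, 0),
                 enzyme_conc = enzyme_conc,
                 truth = list(kcat = kcat, km = km)),
            class = "kinetics_dataset")
}
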