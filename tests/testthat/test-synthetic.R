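test_that("transcriptome generator is deterministic and correctly shaped", {
  cfg <- sim_config(n_genes = 120, pathway_size = 5, seed = 11)
  d1 <- simulate_transcriptome(cfg)
  d2 <- simulate_transcriptome(cfg)
  expect_identical(d1, d2)

  expect_equal(dim(d1$counts), c(120L, 6L))
  expect_true(all(d1$counts >= 0))
  expect_true(is.integer(d1$counts))
  expect_length(d1$truth_module, 5L)
  expect_true(all(d1$truth_module %in% rownames(d1$counts)))
  expect_true(d1$bait_id %in% d1$truth_module)
  expect_setequal(unique(d1$design$tissue), c("root", "stem", "leaf"))
  expect_equal(nrow(d1$design), ncol(d1$counts))

  d3 <- simulate_transcriptome(sim_config(n_genes = 120, pathway_size = 5,
                                          seed = 12))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, pathway_size = 10), "pathway_size")
  expect_error(sim_config(100, 5, module_correlation = 1.2),
               "module_correlation")
  expect_error(sim_config(100, 5, nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(100, 5, fold_root_enrichment = 0.5),
               "fold_root_enrichment")
  expect_error(sim_config(100, 5, pathway_tissue = "petal"), "pathway_tissue")
})

test_that("noise-free limit yields perfectly correlated module profiles", {
  d <- simulate_transcriptome(sim_config(n_genes = 80, pathway_size = 4,
                                         module_correlation = 1,
                                         nb_dispersion = Inf, seed = 3))
  expr <- expr_of(d)
  lv <- log2(expr$fpkm[d$truth_module, ] + 1)
  C <- stats::cor(t(lv))
  expect_true(all(C[upper.tri(C)] > 0.999))
})

test_that("module calibration hits the target correlation in expectation", {
  # Monte-Carlo check of the generator's own calibration: the mean pairwise
  # correlation of log2(FPKM + 1) inside the planted module should sit at
  # the configured target.
  mean_r <- vapply(1:20, function(s) {
    d <- simulate_transcriptome(sim_config(n_genes = 1000, pathway_size = 10,
                                           module_correlation = 0.97,
                                           fold_root_enrichment = 20,
                                           seed = s))
    lv <- log2(expr_of(d)$fpkm[d$truth_module, ] + 1)
    C <- stats::cor(t(lv))
    mean(C[upper.tri(C)])
  }, numeric(1))
  expect_lt(abs(mean(mean_r) - 0.97), 0.05)
})

test_that("planted module is root-enriched and separable from background", {
  d <- simulate_transcriptome(sim_config(n_genes = 1000, pathway_size = 10,
                                         module_correlation = 0.97,
                                         fold_root_enrichment = 20, seed = 5))
  expr <- expr_of(d)
  expect_true(all(d$truth_module %in% filter_expressed(expr, "root", 20)))

  # background genes almost never reach r = 0.95 with the bait
  res <- suppressWarnings(bait_set(expr, d$bait_id, 0.95))
  fp <- setdiff(res$members, d$truth_module)
  expect_lt(length(fp) / (1000 - 10), 0.01)
})

test_that("mutate_orthologue substitutes exactly the contracted positions", {
  expect_identical(mutate_orthologue("MKLV", 1.0, seed = 9), "MKLV")

  parent <- random_protein(100)
  child <- mutate_orthologue(parent, 0.92, seed = 7)
  expect_equal(nchar(child), 100L)
  diffs <- sum(strsplit(parent, "")[[1]] != strsplit(child, "")[[1]])
  expect_equal(diffs, 8L)

  expect_identical(mutate_orthologue(parent, 0.74, seed = 7),
                   mutate_orthologue(parent, 0.74, seed = 7))
  expect_error(mutate_orthologue("", 0.9), "non-empty")
  expect_error(mutate_orthologue("MKLV", 0), "target_identity")
})

test_that("simulated proteomes track their target identities", {
  pr <- simulate_proteome(5, 200, target_identity = 0.88, seed = 2)
  for (i in 1:5) {
    diffs <- sum(strsplit(pr$parent_sequences[[i]], "")[[1]] !=
                   strsplit(pr$child_sequences[[i]], "")[[1]])
    expect_lte(abs(1 - diffs / 200 - 0.88), 1 / 200)
  }
})

test_that("kinetics simulator reproduces the Michaelis-Menten limits", {
  half <- simulate_kinetics(2, 5, 0.1, 5, noise_cv = 0)
  expect_equal(half$velocity, 0.1)           # S = Km: v = kcat * E0 / 2

  sat <- simulate_kinetics(2, 5, 0.1, 1e9, noise_cv = 0)
  expect_equal(sat$velocity, 0.2, tolerance = 1e-6)   # Vmax = kcat * E0

  expect_error(simulate_kinetics(2, 5, 0.1, 5, noise_cv = -0.1), "noise_cv")

  # multiplicative noise is unbiased: Monte-Carlo mean within 2 %
  S <- c(1, 5, 25)
  noiseless <- simulate_kinetics(2, 5, 0.1, S, noise_cv = 0)$velocity
  sims <- vapply(1:100, function(s)
    simulate_kinetics(2, 5, 0.1, S, noise_cv = 0.05, seed = s)$velocity,
    numeric(3))
  expect_true(all(abs(rowMeans(sims) / noiseless - 1) < 0.02))
})
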