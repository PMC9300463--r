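test_that("identity converts to distance as 1 - id/100", {
  idm <- matrix(c(100, 74, 74, 100), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  d <- distance_from_identity(idm)
  expect_equal(d["a", "b"], 0.26)
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))

  pr <- simulate_proteome(4, 80, 0.85, seed = 5)
  dm <- distance_from_identity(identity_matrix(pr$parent_sequences))
  expect_true(isSymmetric(unname(unclass(dm))))
  expect_true(all(dm >= 0))
})

test_that("missing pairwise identities are refused", {
  p1 <- global_align("MKLV", "MKIV", id_a = "a", id_b = "b")
  p1$rbh <- TRUE
  p2 <- global_align("MKLV", "MELV", id_a = "a", id_b = "c")
  p2$rbh <- TRUE
  expect_error(distance_from_identity(list(p1, p2)), "missing pairwise")
})

test_that("three taxa solve the three-point equations", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["a"]], (3 + 5 - 6) / 2)   # 1
  expect_equal(bl[["b"]], (3 + 6 - 5) / 2)   # 2
  expect_equal(bl[["c"]], (5 + 6 - 3) / 2)   # 4
})

test_that("an additive four-taxon matrix reproduces its generating tree", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  d <- ape::cophenetic.phylo(gen)
  tr <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # and branch lengths are recovered (sum of root-adjacent edges preserved)
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]),
               sort(d))
})

test_that("tight pairs in an ultrametric matrix become sister cherries", {
  taxa <- c("p1", "p2", "q1", "q2", "out")
  d <- matrix(1, 5, 5, dimnames = list(taxa, taxa))
  diag(d) <- 0
  d["p1", "p2"] <- d["p2", "p1"] <- 0.05
  d["q1", "q2"] <- d["q2", "q1"] <- 0.05
  tr <- neighbor_joining(d)
  expect_true(is_monophyletic(tr, c("p1", "p2"), "out"))
  expect_true(is_monophyletic(tr, c("q1", "q2"), "out"))
})

test_that("NJ recovers random additive topologies exactly", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.1, 1)
    tr <- neighbor_joining(ape::cophenetic.phylo(gen))
    expect_equal(ape::dist.topo(ape::unroot(gen), tr), 0, ignore_attr = TRUE)
  }
})

test_that("fewer than three taxa and negative lengths are handled", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), ">= 3 taxa")

  # non-additive matrix known to give a negative NJ branch
  taxa <- letters[1:4]
  dn <- matrix(c(0,     0.339, 0.435, 0.917,
                 0.339, 0,     0.616, 0.282,
                 0.435, 0.616, 0,     0.909,
                 0.917, 0.282, 0.909, 0), 4, 4,
               dimnames = list(taxa, taxa))
  expect_message(tr <- neighbor_joining(dn), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("clade membership is assessed after rooting on the outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,O:3);")
  expect_true(is_monophyletic(tr, c("A", "B"), "O"))
  expect_false(is_monophyletic(tr, c("A", "C"), "O"))
  expect_true(is_monophyletic(tr, "A", "O"))                  # singleton
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D"), "O"))
  expect_error(is_monophyletic(tr, c("A", "Z"), "O"), "unknown")
  expect_error(is_monophyletic(tr, c("A", "O"), "O"), "outgroup")
})

test_that("trees round-trip through Newick text", {
  gen <- ape::rtree(6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(gen, path)
  back <- read_newick(path)
  expect_setequal(back$tip.label, gen$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})
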