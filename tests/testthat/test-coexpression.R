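test_that("pearson_r matches the textbook formula and its special cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)

  set.seed(5)
  for (i in 1:20) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), num / den)
  }

  expect_error(pearson_r(1:2, 1:2), "length")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pearson_r is symmetric and invariant to positive affine maps", {
  set.seed(6)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_equal(pearson_r(2.5 * x + 3, y), pearson_r(x, y))
  expect_equal(pearson_r(-1 * x, y), -pearson_r(x, y))
})

test_that("a noiseless proportional module is exactly the r = 1 set", {
  expr <- noiseless_module_expr()
  res <- bait_set(expr, "mod1", 1.0, mode = "strict")
  expect_setequal(res$members, paste0("mod", 1:4))
  expect_equal(unname(res$r_values["mod1", "mod1"]), 1)
})

test_that("a vacuous cutoff admits every gene with a defined correlation", {
  expr <- noiseless_module_expr()
  res <- bait_set(expr, "mod1", -1, mode = "strict")
  expect_setequal(res$members, rownames(expr$fpkm))
})

test_that("constant profiles are excluded with a warning, not scored 0", {
  fp <- rbind(noiseless_module_expr(n_bg = 5)$fpkm,
              flat = rep(7, 6))
  expr <- toy_expr(fp, rep(c("root", "stem", "leaf"), each = 2))
  expect_warning(res <- bait_set(expr, "mod1", -1), "constant")
  expect_false("flat" %in% res$members)
  expect_true(is.na(res$r_values["flat", "mod1"]))
  flat_expr <- toy_expr(matrix(c(rep(1, 6), 1:6), 2, 6, byrow = TRUE),
                        rep(c("root", "stem", "leaf"), each = 2))
  expect_error(bait_set(flat_expr, "g1", 0.5), "constant")
})

test_that("multi-bait membership is the intersection of single-bait sets", {
  set.seed(7)
  fp <- matrix(2^stats::runif(120, 0, 10), 20, 6)
  expr <- toy_expr(fp, rep(c("root", "stem", "leaf"), each = 2))
  baits <- c("g1", "g4", "g9")
  th <- 0.3
  multi <- multi_bait_set(expr, baits, th, mode = "open")

  # brute-force triple filter
  lv <- log2(fp + 1)
  rownames(lv) <- rownames(expr$fpkm)
  oracle <- rownames(lv)
  for (b in baits) {
    keep <- vapply(rownames(lv), function(g) {
      r <- if (g == b) 1 else stats::cor(lv[g, ], lv[b, ])
      r > th
    }, logical(1))
    oracle <- intersect(oracle, rownames(lv)[keep])
  }
  expect_setequal(multi$members, oracle)

  # contractive: inside every single-bait set; single bait reduces to bait_set
  for (b in baits) {
    expect_true(all(multi$members %in%
                      bait_set(expr, b, th, mode = "open")$members))
  }
  expect_setequal(multi_bait_set(expr, "g1", th, mode = "open")$members,
                  bait_set(expr, "g1", th, mode = "open")$members)
  expect_error(multi_bait_set(expr, character(0), 0.5), "empty bait")
  expect_error(bait_set(expr, "nope", 0.5), "not in expression")
})

test_that("mutually uncorrelated baits cannot both be members", {
  fp <- rbind(up = 2^(1:6), down = 2^(6:1), other = 2^c(1, 3, 2, 5, 4, 6))
  expr <- toy_expr(fp, rep(c("root", "stem", "leaf"), each = 2))
  res <- multi_bait_set(expr, c("up", "down"), 0.6, mode = "open")
  expect_true(length(intersect(c("up", "down"), res$members)) < 2)
})

test_that("raising the threshold never grows the member set", {
  set.seed(9)
  fp <- matrix(2^stats::runif(90, 0, 8), 15, 6)
  expr <- toy_expr(fp, rep(c("root", "stem", "leaf"), each = 2))
  prev <- multi_bait_set(expr, "g2", -1)$members
  for (th in c(0, 0.4, 0.8, 0.95, 1)) {
    cur <- multi_bait_set(expr, "g2", th)$members
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("strict and open modes differ exactly at the threshold", {
  fp <- rbind(a = 2^(1:6) - 1, b = 2^(4:9) - 1)   # r exactly 1 on log scale
  expr <- toy_expr(fp, rep(c("root", "stem", "leaf"), each = 2))
  expect_true("b" %in% bait_set(expr, "a", 1, mode = "strict")$members)
  expect_false("b" %in% bait_set(expr, "a", 1, mode = "open")$members)
})
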