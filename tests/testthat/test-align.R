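test_that("identical and single-substitution pairs align as expected", {
  p <- global_align("MKLV", "MKLV")
  expect_equal(p$percent_identity, 100)
  expect_false(grepl("-", p$aligned_a))

  p2 <- global_align("MKLV", "MKIV")
  expect_equal(p2$percent_identity, 75)
  expect_equal(p2$aligned_a, "MKLV")
  expect_equal(p2$aligned_b, "MKIV")
})

test_that("dynamic-programming scores equal exhaustive enumeration", {
  pm <- alignment_params()
  alphabet <- rownames(pm$sub)
  set.seed(31)
  for (i in 1:60) {
    a <- random_protein(sample(2:8, 1))
    b <- random_protein(sample(2:8, 1))
    dp <- global_align(a, b, pm)$score
    bf <- baitminer:::nw_score_bruteforce_cpp(
      baitminer:::.aa_codes(a, alphabet), baitminer:::.aa_codes(b, alphabet),
      pm$sub, pm$gap_open, pm$gap_extend)
    expect_equal(dp, bf)
  }
})

test_that("scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(17)
  for (i in 1:8) {
    a <- random_protein(50)
    b <- random_protein(45)
    ours <- global_align(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("alignment score is symmetric", {
  set.seed(19)
  for (i in 1:10) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("moderately diverged equal-length pairs align without gaps", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_protein(80)
    b <- mutate_orthologue(a, 0.78, seed = i)   # 22 % substitutions
    p <- global_align(a, b)
    expect_false(grepl("-", p$aligned_a))
    expect_false(grepl("-", p$aligned_b))
    expect_equal(p$percent_identity, 78, tolerance = 1 / 80 * 100 / 78)
  }
})

test_that("percent identity respects the configured denominator", {
  # terminal overhang: b lacks the leading M
  p <- global_align("MKLVPQ", "KLVPQ")
  expect_equal(percent_identity(p, alignment_params()), 100)
  expect_equal(
    percent_identity(p, alignment_params(identity_denominator = "shorter_sequence")),
    100)
  expect_equal(
    percent_identity(p, alignment_params(identity_denominator = "longer_sequence")),
    100 * 5 / 6)

  # disjoint alphabets: no identical column at all
  expect_equal(global_align("AAAA", "GGGG")$percent_identity, 0)
})

test_that("ambiguity codes score zero and illegal residues are reported", {
  p <- global_align("MKXV", "MKXV")
  expect_equal(p$score,
               global_align("MKV", "MKV")$score)  # X-X contributes 0
  expect_equal(p$percent_identity, 100)
  expect_error(global_align("MK1V", "MKLV"), "1")
  expect_error(global_align("", "MKLV"), "non-empty")
})

test_that("reciprocal best hits recover a mutated proteome's identity map", {
  pr <- simulate_proteome(12, 200, target_identity = 0.9, seed = 41)
  pairs <- reciprocal_best_hits(pr$parent_sequences, pr$child_sequences)
  tab <- rbh_table(pairs)
  expect_equal(nrow(tab), 12L)
  expect_equal(sub("P", "", tab$id_a), sub("C", "", tab$id_b))
  expect_true(all(tab$rbh))
  expect_true(all(abs(tab$percent_identity - 90) <= 100 / 200))
})

test_that("an exact copy proteome gives a complete RBH map", {
  pr <- simulate_proteome(6, 120, target_identity = 1, seed = 8)
  pairs <- reciprocal_best_hits(pr$parent_sequences, pr$child_sequences)
  tab <- rbh_table(pairs)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$percent_identity == 100))
})

test_that("deleted partners and tied scores yield no RBH call", {
  pr <- simulate_proteome(6, 150, target_identity = 0.9, seed = 12)
  a <- pr$parent_sequences
  b <- pr$child_sequences[-2]
  tab <- rbh_table(reciprocal_best_hits(a, b))
  expect_false("P002" %in% tab$id_a)

  # duplicate one partner: its parent's top score is tied, so no call
  b_dup <- c(pr$child_sequences, DUP = unname(pr$child_sequences[1]))
  expect_message(tab2 <- rbh_table(reciprocal_best_hits(a, b_dup)), "tied")
  expect_false("P001" %in% tab2$id_a)
})
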