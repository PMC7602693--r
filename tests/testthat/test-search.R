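test_that("exhaustive search finds the concordant quartet and ties on constant data", {
  m <- morph_matrix(c("A", "B", "C", "D"),
                    list("0", "0", "1", "1"))
  ex <- exhaustive_search(m)
  expect_equal(ex$best_length, 1L)
  expect_equal(ex$n_trees, 1L)
  expect_equal(rf_distance(ex$trees[[1]], parse_newick("((A,B),(C,D));")), 0L)

  const <- morph_matrix(paste0("t", 1:5), rep(list(rep("0", 3)), 5))
  exc <- exhaustive_search(const)
  expect_equal(exc$best_length, 0L)
  expect_equal(exc$n_trees, 15L)
  expect_error(exhaustive_search(random_test_matrix(10, 3, 1)), "cap")
})

test_that("branch-and-bound equals plain enumeration", {
  for (case in 1:30) {
    n <- if (case <= 20) 6 else 7
    m <- random_test_matrix(n, 8, seed = 1200 + case, states = 2,
                            p_missing = 0.1)
    bb <- exhaustive_search(m, prune = TRUE)
    pl <- exhaustive_search(m, prune = FALSE)
    expect_equal(bb$best_length, pl$best_length, info = paste("case", case))
    expect_setequal(vapply(bb$trees, oracle_tree_key, ""),
                    vapply(pl$trees, oracle_tree_key, ""))
  }
})

test_that("heuristic search is reproducible and matches the exact optimum", {
  for (case in 1:10) {
    m <- random_test_matrix(7, 10, seed = 1500 + case, states = 2,
                            p_missing = 0.05)
    hs <- heuristic_search(m, search_config(replicates = 5, seed = case))
    ex <- exhaustive_search(m)
    expect_equal(hs$best_length, ex$best_length, info = paste("case", case))
    hs2 <- heuristic_search(m, search_config(replicates = 5, seed = case))
    expect_equal(vapply(hs$trees, write_newick, ""),
                 vapply(hs2$trees, write_newick, ""))
    expect_equal(hs$replicate_log, hs2$replicate_log)
  }
})

test_that("retained optimal trees are TBR-local optima", {
  m <- random_test_matrix(8, 12, seed = 77, states = 2)
  hs <- heuristic_search(m, search_config(replicates = 4, seed = 8,
                                          collapse_rule = "none"))
  for (tr in hs$trees[seq_len(min(5, length(hs$trees)))]) {
    lens <- vapply(tbr_neighbors(tr), tree_length, 1L, matrix = m)
    expect_gte(min(lens), hs$best_length)
  }
})

test_that("suboptimal retention is monotone in the bound and equals optima at 0", {
  m <- random_test_matrix(6, 10, seed = 31, states = 2)
  cfg <- search_config(replicates = 4, seed = 5, collapse_rule = "none")
  s0 <- search_suboptimal(m, 0, cfg)
  hs <- heuristic_search(m, cfg)
  expect_equal(s0$best_length, hs$best_length)
  expect_setequal(vapply(s0$archive, oracle_tree_key, ""),
                  vapply(hs$trees, oracle_tree_key, ""))
  k1 <- vapply(search_suboptimal(m, 1, cfg)$archive, oracle_tree_key, "")
  k2 <- vapply(search_suboptimal(m, 2, cfg)$archive, oracle_tree_key, "")
  expect_true(all(vapply(s0$archive, oracle_tree_key, "") %in% k1))
  expect_true(all(k1 %in% k2))
  expect_true(all(s0$archive_lengths <= s0$best_length))
})

test_that("zero-length branch collapsing follows its rule and never lengthens the tree", {
  # all-constant matrix: every internal branch can be zero -> star
  const <- morph_matrix(paste0("t", 1:6), rep(list(rep("0", 4)), 6))
  tr <- simulate_tree(6, seed = 3)
  star <- collapse_zero_branches(tr, const, "min_zero")
  expect_equal(length(mpclad:::utree_splits(mpclad:::utree_from_phylo(star))), 0L)
  # a branch carrying an unambiguous change (A+B+C, two clean characters)
  # survives both rules; the unsupported A+B branch collapses under min_zero
  m <- builtin_fixture("toy6")
  t6 <- parse_newick("(((A,B),C),(D,E),F);")
  for (rule in c("min_zero", "max_zero")) {
    kept <- collapse_zero_branches(t6, m, rule)
    expect_true("A+B+C" %in% tree_splits(kept))
  }
  expect_false("A+B" %in%
    tree_splits(collapse_zero_branches(t6, m, "min_zero")))
  # collapsing never increases length
  for (case in 1:20) {
    mm <- random_test_matrix(7, 6, seed = 2100 + case, states = 2,
                             p_missing = 0.2)
    tt <- simulate_tree(7, seed = 2200 + case, taxa = mm$taxa)
    for (rule in c("min_zero", "max_zero")) {
      cc <- collapse_zero_branches(tt, mm, rule)
      expect_lte(tree_length(cc, mm), tree_length(tt, mm))
      expect_equal(tree_length(cc, mm), tree_length(tt, mm))
    }
  }
})
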