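test_that("strict consensus keeps exactly the shared splits", {
  t1 <- parse_newick("(((A,B),C),(D,E),F);")
  expect_equal(rf_distance(strict_consensus(list(t1, t1)), t1), 0L)
  # maximally conflicting quartets -> star
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  star <- strict_consensus(list(q1, q2))
  expect_length(tree_splits(star), 0L)
  # order invariance and idempotence
  t2 <- parse_newick("(((A,C),B),(D,E),F);")
  c12 <- strict_consensus(list(t1, t2))
  c21 <- strict_consensus(list(t2, t1))
  expect_equal(rf_distance(c12, c21), 0L)
  expect_equal(rf_distance(strict_consensus(list(c12)), c12), 0L)
  expect_setequal(tree_splits(c12),
                  intersect(tree_splits(t1), tree_splits(t2)))
  expect_error(strict_consensus(list()), "empty")
  # agreement with ape::consensus on random tree sets
  for (case in 1:5) {
    trees <- lapply(1:3, function(i) simulate_tree(8, seed = 3000 + 10 * case + i))
    mine <- strict_consensus(trees)
    apec <- ape::consensus(trees)
    expect_setequal(tree_splits(mine), tree_splits(apec))
  }
})

test_that("consensus diagnostics use the polytomy-aware length", {
  m <- random_test_matrix(7, 12, seed = 55, states = 2)
  hs <- heuristic_search(m, search_config(replicates = 4, seed = 2))
  cons <- strict_consensus(hs$trees)
  cd <- consensus_diagnostics(cons, m)
  expect_gte(cd$L, hs$best_length)
  single <- consensus_diagnostics(strict_consensus(hs$trees[1]), m)
  expect_equal(single$L, tree_length(hs$trees[[1]], m))
})

test_that("Bremer decay equals the exhaustive-enumeration oracle", {
  # clade {A,B} backed by exactly three conflict-free characters
  taxa <- c("A", "B", "C", "D", "E", "F")
  ab <- c("1", "1", "0", "0", "0", "0")
  abc <- c("1", "1", "1", "0", "0", "0")
  de <- c("0", "0", "0", "1", "1", "0")
  cells <- lapply(seq_along(taxa), function(i)
    c(ab[i], ab[i], ab[i], abc[i], abc[i], de[i], de[i]))
  m <- morph_matrix(taxa, cells)
  # oracle: scan every 6-taxon topology
  all_trees <- enumerate_unrooted_trees(taxa)
  lens <- vapply(all_trees, tree_length, 1L, matrix = m)
  best <- min(lens)
  has_ab <- vapply(all_trees, function(t) "A+B" %in% tree_splits(t), TRUE)
  oracle_bremer <- min(lens[!has_ab]) - best
  expect_equal(oracle_bremer, 3L)
  mpts <- heuristic_search(m, search_config(replicates = 4, seed = 9))$trees
  br <- bremer_supports(m, mpts, max_bound = 6,
                        config = search_config(replicates = 4, seed = 9,
                                               hold = 50,
                                               global_buffer = 5000))
  expect_equal(br$bremer[br$split == "A+B"], 3)
  # every strict-consensus node has decay >= 1, monotone under deeper bounds
  expect_true(all(br$bremer >= 1))
  br2 <- bremer_supports(m, mpts, max_bound = 4,
                         config = search_config(replicates = 4, seed = 9,
                                                hold = 50,
                                                global_buffer = 5000))
  expect_true(all(pmin(br$bremer, 4) == br2$bremer[match(br$split, br2$split)]))
})

test_that("jackknife at p_delete = 0 recovers every consensus node always", {
  m <- builtin_fixture("toy6")
  jk <- jackknife_supports(m, reps = 20, p_delete = 0, seed = 4,
                           config = search_config(replicates = 2, hold = 20))
  expect_true(all(jk$pct == 100))
  expect_true(all(!jk$below_cutoff))
})

test_that("jackknife frequencies are seed-reproducible", {
  m <- builtin_fixture("toy6")
  j1 <- jackknife_supports(m, reps = 30, p_delete = 0.36, seed = 11,
                           config = search_config(replicates = 2, hold = 20))
  j2 <- jackknife_supports(m, reps = 30, p_delete = 0.36, seed = 11,
                           config = search_config(replicates = 2, hold = 20))
  expect_equal(j1, j2)
})
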