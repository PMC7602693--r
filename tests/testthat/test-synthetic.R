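test_that("simulated topologies are reproducible, well-formed and uniform", {
  a <- simulate_tree(5, seed = 6)
  b <- simulate_tree(5, seed = 6)
  expect_equal(write_newick(a), write_newick(b))
  big <- simulate_tree(43, seed = 1)
  expect_length(big$tip.label, 43L)
  # unrooted binary: n-3 internal (non-trivial) splits
  expect_length(tree_splits(big), 40L)
  # uniformity over the 3 quartet topologies
  keys <- vapply(1:3000, function(s) oracle_tree_key(simulate_tree(4, seed = s)), "")
  tab <- table(keys)
  expect_length(tab, 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("matrix simulation honours its contracts", {
  tr <- simulate_tree(8, seed = 12)
  # zero change rate: all characters constant, length 0 on any tree
  m0 <- simulate_matrix(tr, 20, sim_model(change_rate = 0, missing_rate = 0,
                                          polymorphism_rate = 0, seed = 2))
  expect_equal(tree_length(tr, m0), 0L)
  expect_equal(tree_length(simulate_tree(8, seed = 99), m0), 0L)
  # requested dimensions and multistate composition
  ns <- c(rep(2L, 53), rep(3L, 14), rep(5L, 5))
  tr43 <- simulate_tree(43, seed = 4)
  m43 <- simulate_matrix(tr43, 72, sim_model(n_states = ns, seed = 4))
  expect_equal(dim(m43), c(43L, 72L))
  clean <- attr(m43, "clean")
  nst <- vapply(seq_len(72), function(j)
    length(unique(unlist(lapply(matrix_column(clean, j), `[[`, "states")))), 1L)
  expect_true(all(nst <= ns))
  expect_equal(sum(ns > 2), 19L)
})

test_that("degradation injects exactly what it claims and nothing else", {
  tr <- simulate_tree(7, seed = 21)
  base <- simulate_matrix(tr, 12, sim_model(change_rate = 0.15,
                                            missing_rate = 0,
                                            polymorphism_rate = 0, seed = 3))
  # missing_rate = 1: every cell missing
  all_missing <- degrade(base, sim_model(missing_rate = 1,
                                         polymorphism_rate = 0, seed = 3))
  expect_true(all(all_missing$kind == "missing"))
  # controller rule mirrors reductive coding
  rule <- list(controller = 1, state = 0, dependents = c(2, 3))
  dg <- degrade(base, sim_model(missing_rate = 0, polymorphism_rate = 0,
                                inapplicable_rule = rule, seed = 3))
  hit <- vapply(matrix_column(base, 1), function(c0)
    c0$kind == "det" && identical(c0$states, 0L), TRUE)
  for (j in 2:3)
    expect_equal(dg$kind[, j] == "inapp", hit, ignore_attr = TRUE)
  # untouched determinate cells are identical
  expect_equal(dg$states[, 4:12], base$states[, 4:12], ignore_attr = TRUE)
  expect_error(degrade(base, sim_model(inapplicable_rule =
    list(controller = 99, state = 0, dependents = 2))), "out of range")
})

test_that("homoplasy-free regimes score ci = ri = 1 on the generating tree", {
  # very low change rate conditional on at least one change
  tr <- simulate_tree(10, seed = 30)
  m <- simulate_matrix(tr, 60, sim_model(change_rate = 0.005,
                                         missing_rate = 0,
                                         polymorphism_rate = 0, seed = 30))
  d <- diagnostics(tr, m)$per_character
  varied <- d$s > 0
  expect_true(any(varied))
  expect_true(all(d$ci[varied] == 1))
  expect_true(all(d$ri[varied & d$g > d$m] == 1))
})

test_that("expected steps grow with the change rate", {
  rates <- c(0.02, 0.08, 0.2)
  mean_steps <- vapply(rates, function(r) {
    mean(vapply(1:15, function(s) {
      tr <- simulate_tree(8, seed = 4000 + s)
      m <- simulate_matrix(tr, 15, sim_model(change_rate = r, seed = 5000 + s,
                                             missing_rate = 0,
                                             polymorphism_rate = 0))
      tree_length(tr, m) / 15
    }, 0))
  }, 0)
  expect_true(all(diff(mean_steps) > 0))
})

test_that("the generating tree attains the optimum whenever it is homoplasy-free (exhaustive check at n=7)", {
  # sum(m) is a tree-independent lower bound on length; a matrix whose every
  # character fits the generating tree perfectly (s == m) therefore makes
  # that tree globally optimal. With homoplasy the generating tree can be
  # (and occasionally is) beaten — only the bounds hold then.
  seen_clean <- FALSE; seen_homoplastic <- FALSE
  for (s in 1:8) {
    tr <- simulate_tree(7, seed = 6000 + s)
    m <- simulate_matrix(tr, 40, sim_model(change_rate = 0.03,
                                           missing_rate = 0,
                                           polymorphism_rate = 0,
                                           seed = 7000 + s))
    d <- diagnostics(tr, m)$per_character
    gen_len <- sum(d$s)
    ex <- exhaustive_search(m)
    expect_gte(ex$best_length, sum(d$m))
    expect_lte(ex$best_length, gen_len)
    if (all(d$s == d$m)) {
      seen_clean <- TRUE
      expect_equal(ex$best_length, gen_len, info = paste("seed", s))
      expect_equal(min(vapply(ex$trees, rf_distance, 1L, t2 = tr)), 0L)
    } else seen_homoplastic <- TRUE
  }
  expect_true(seen_clean)         # both regimes actually exercised
  expect_true(seen_homoplastic)
})
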