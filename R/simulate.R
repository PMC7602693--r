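# Synthetic morphological matrices: characters evolved on a known tree by a
# branch-level Bernoulli change process, with controllable homoplasy and
# injected missing / inapplicable / polymorphic cells. All randomness flows
# from one seed through a deterministic splitting scheme.

#' Simulation model
#'
#' Defaults emulate the shape of a 43-taxon, 72-character weevil matrix:
#' mostly binary characters with a multistate minority (some of them
#' additive), sparse missing data, a single-digit number of polymorphic
#' cells, and reductive (controller-dependent) inapplicable coding.
#'
#' @param n_states Integer vector of per-character state counts (2-5),
#'   recycled to the character count; or NULL to draw counts with
#'   probabilities `c(0.74, 0.15, 0.07, 0.04)` for 2-5 states (roughly the
#'   53:19 binary:multistate ratio of the motivating matrix).
#' @param change_rate Per-branch probability of a state transition
#'   (default 0.05: appreciable but not saturating homoplasy on mid-sized
#'   trees).
#' @param ordered_fraction Fraction of multistate characters made additive
#'   (default 0.26, i.e. about 5 of 19).
#' @param missing_rate Per-cell missing probability (default 0.01).
#' @param polymorphism_rate Per-cell probability of adding an adjacent
#'   observed state (default 0.0013, about one cell per 774).
#' @param inapplicable_rule NULL, or
#'   `list(controller=, state=, dependents=)`: taxa whose determinate
#'   controller cell equals `state` get `"-"` in every dependent character.
#' @param seed Integer seed.
#' @return List of class `"sim_model"`.
#' @export
sim_model <- function(n_states = NULL, change_rate = 0.05,
                      ordered_fraction = 0.26, missing_rate = 0.01,
                      polymorphism_rate = 0.0013, inapplicable_rule = NULL,
                      seed = 1L) {
  stopifnot(change_rate >= 0, change_rate <= 1, missing_rate >= 0,
            missing_rate <= 1, polymorphism_rate >= 0, polymorphism_rate <= 1,
            ordered_fraction >= 0, ordered_fraction <= 1)
  if (!is.null(inapplicable_rule))
    stopifnot(is.list(inapplicable_rule),
              all(c("controller", "state", "dependents") %in%
                    names(inapplicable_rule)))
  structure(list(n_states = n_states, change_rate = change_rate,
                 ordered_fraction = ordered_fraction,
                 missing_rate = missing_rate,
                 polymorphism_rate = polymorphism_rate,
                 inapplicable_rule = inapplicable_rule,
                 seed = as.integer(seed)),
            class = "sim_model")
}

#' Simulate a uniform random unrooted binary tree
#'
#' Sequential addition to a uniformly chosen edge, which yields the uniform
#' distribution over the (2n-5)!! labelled topologies. Deterministic given
#' the seed.
#'
#' @param n_taxa Number of taxa (>= 4); taxa are named `t1..tn`.
#' @param seed Integer seed.
#' @param taxa Optional explicit taxon names.
#' @return A `"phylo"`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, taxa = NULL) {
  stopifnot(n_taxa >= 4L)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa)
  phylo_from_utree(random_utree(taxa, seed = seed))
}

#' Evolve a character matrix on a tree
#'
#' Each character evolves root to tip: the root state is drawn uniformly;
#' on each branch a transition happens with probability `change_rate`, to a
#' uniformly chosen different state (ordered characters move one step up or
#' down, reflecting at the ends of the state line). Degradation (missing /
#' inapplicable / polymorphic cells) is then applied by [degrade()].
#'
#' @param tree A `"phylo"` with at least 4 tips.
#' @param n_chars Number of characters.
#' @param model A [sim_model()].
#' @return A [morph_matrix]; the pre-degradation determinate matrix is kept
#'   in attribute `"clean"`.
#' @export
simulate_matrix <- function(tree, n_chars, model = sim_model()) {
  ut <- as_ut(tree)
  n <- ut$n
  tr <- utree_traversal(ut)
  set.seed(split_seed(model$seed, 1L))
  k <- n_chars
  ns <- if (is.null(model$n_states))
    sample(2:5, k, replace = TRUE, prob = c(0.74, 0.15, 0.07, 0.04))
  else rep_len(as.integer(model$n_states), k)
  ordered <- rep(FALSE, k)
  multi <- which(ns > 2L)
  if (length(multi))
    ordered[multi] <- stats::runif(length(multi)) < model$ordered_fraction
  # preorder over nodes: virtual root edge joins root tip and top
  pre <- rev(tr$post)
  m <- length(ut$adj)
  states <- matrix(0L, m, k)
  for (j in seq_len(k)) {
    S <- ns[j]
    root_state <- sample.int(S, 1L) - 1L
    states[tr$parent[tr$top], j] <- root_state  # the rooting tip
    walk <- function(v, st) {
      if (stats::runif(1) < model$change_rate) {
        st <- if (ordered[j]) {
          if (st == 0L) 1L
          else if (st == S - 1L) S - 2L
          else st + sample(c(-1L, 1L), 1L)
        } else sample(setdiff(0:(S - 1L), st), 1L)
      }
      states[v, j] <<- st
      if (v > n) for (c in tr$children[[v]]) walk(c, st)
      invisible()
    }
    walk(tr$top, root_state)
  }
  tips <- states[seq_len(n), , drop = FALSE]
  cells <- lapply(seq_len(n), function(i) as.character(tips[i, ]))
  clean <- morph_matrix(ut$labels, cells, ordered = ordered)
  out <- degrade(clean, model)
  attr(out, "clean") <- clean
  attr(out, "generating_tree") <- phylo_from_utree(ut)
  out
}

#' Inject missing, inapplicable and polymorphic cells
#'
#' Applies only degradation, never re-evolution: determinate cells are
#' turned missing with probability `missing_rate`, dependent characters are
#' set inapplicable wherever the controller character is determinate and
#' equal to the rule state, and with probability `polymorphism_rate` a cell
#' gains an adjacent observed state (mimicking `[01]`-style terminal
#' polymorphism). Untouched cells are bit-identical to the input.
#'
#' @param matrix A [morph_matrix].
#' @param model A [sim_model()].
#' @return A [morph_matrix].
#' @export
degrade <- function(matrix, model = sim_model()) {
  set.seed(split_seed(model$seed, 2L))
  n <- length(matrix$taxa); k <- matrix$nchar
  states <- matrix$states; kind <- matrix$kind
  rule <- model$inapplicable_rule
  if (!is.null(rule)) {
    if (rule$controller < 1L || rule$controller > k ||
        any(rule$dependents < 1L) || any(rule$dependents > k))
      stop("inapplicable_rule character index out of range")
    ctrl <- rule$controller
    hit <- kind[, ctrl] == "det" &
      states[, ctrl] == mask_of(rule$state)
    for (j in rule$dependents) {
      states[hit, j] <- 0L
      kind[hit, j] <- "inapp"
    }
  }
  if (model$polymorphism_rate > 0) for (j in seq_len(k)) {
    obs <- sort(unique(unlist(lapply(which(kind[, j] == "det"), function(i)
      states_of(states[i, j])))))
    if (length(obs) < 2L) next
    for (i in which(kind[, j] == "det")) {
      if (stats::runif(1) < model$polymorphism_rate) {
        st <- states_of(states[i, j])
        nb <- obs[which.min(abs(obs - st) + (obs == st) * 99)]
        states[i, j] <- mask_of(c(st, nb))
        kind[i, j] <- "poly"
      }
    }
  }
  if (model$missing_rate > 0) {
    miss <- matrix(stats::runif(n * k) < model$missing_rate, n, k) &
      kind == "det"
    states[miss] <- 0L
    kind[miss] <- "missing"
  }
  out <- matrix
  out$states <- states
  out$kind <- kind
  out
}
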