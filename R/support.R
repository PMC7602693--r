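# Consensus and branch support.

#' Non-trivial splits of a tree
#'
#' Each bipartition is labelled by its smaller side (ties broken
#' lexicographically) as a `name1+name2+...` string.
#'
#' @param tree A `"phylo"`.
#' @return Character vector of split labels.
#' @export
tree_splits <- function(tree) {
  ut <- as_ut(tree)
  ut <- remap_tips(ut, sort(ut$labels))
  vapply(utree_splits(ut), split_label, "", labels = sort(tree$tip.label),
         USE.NAMES = FALSE)
}

splits_of_ut_canon <- function(ut) {
  utree_splits(remap_tips(ut, sort(ut$labels)))
}

#' Strict consensus of a set of trees
#'
#' The tree whose splits are exactly those present in every member.
#'
#' @param trees Non-empty list of `"phylo"` trees on one leaf set.
#' @return A `"phylo"`, generally polytomous.
#' @export
strict_consensus <- function(trees) {
  if (!length(trees)) stop("empty tree set")
  labs <- sort(trees[[1L]]$tip.label)
  common <- NULL
  for (t in trees) {
    if (!setequal(t$tip.label, labs)) stop("trees have different leaf sets")
    s <- splits_of_ut_canon(as_ut(t))
    common <- if (is.null(common)) s else intersect(common, s)
  }
  build_tree_from_splits(labs, common)
}

# Build an (unrooted, phylo-encoded) tree containing exactly the given
# pairwise-compatible splits. Splits are "i.j.k" strings over indices into
# `labs`, never containing index 1.
build_tree_from_splits <- function(labs, splits) {
  n <- length(labs)
  sets <- lapply(splits, function(s) as.integer(strsplit(s, ".", fixed = TRUE)[[1L]]))
  ord <- order(vapply(sets, length, 1L))          # small clusters first
  sets <- sets[ord]
  # nest clusters: each node = cluster; newick built recursively from the
  # root cluster {2..n} with tip 1 attached at the top
  newick_of <- function(members, remaining) {
    inside <- remaining[vapply(remaining, function(x) all(x %in% members), TRUE)]
    parts <- character(0)
    used <- integer(0)
    # maximal clusters strictly inside
    ok <- rep(TRUE, length(inside))
    for (a in seq_along(inside)) {
      for (b in seq_along(inside)) {
        if (a != b && ok[a] && length(inside[[a]]) <= length(inside[[b]]) &&
            all(inside[[a]] %in% inside[[b]]) &&
            !identical(inside[[a]], inside[[b]])) ok[a] <- FALSE
      }
    }
    tops <- inside[ok]
    # drop the cluster equal to `members` itself (if handed down)
    tops <- Filter(function(x) !identical(sort(x), sort(members)), tops)
    rest <- setdiff(inside, tops)
    for (cl in tops) {
      sub <- Filter(function(x) all(x %in% cl) && !identical(sort(x), sort(cl)),
                    inside)
      parts <- c(parts, newick_of(cl, sub))
      used <- c(used, cl)
    }
    free <- setdiff(members, used)
    parts <- c(parts, quoteq(labs[free]))
    if (length(parts) == 1L) parts[[1L]]
    else paste0("(", paste(parts, collapse = ","), ")")
  }
  core <- newick_of(2:n, sets)
  txt <- paste0("(", quoteq(labs[1L]), ",", core, ");")
  parse_newick(txt)
}

quoteq <- function(x) {
  ifelse(grepl("[ ,():;]", x), paste0("'", x, "'"), x)
}

#' Ensemble diagnostics of a consensus tree
#'
#' Length and ensemble indices of a (possibly polytomous) consensus,
#' computed with the same generalized dynamic program used for binary
#' trees. A consensus is never shorter than the trees it summarizes.
#'
#' @inheritParams char_length
#' @return The `ensemble` element of [diagnostics()].
#' @export
consensus_diagnostics <- function(tree, matrix) {
  diagnostics(tree, matrix)$ensemble
}

#' Bremer decay values from retained suboptimal trees
#'
#' One suboptimal-retaining search is run with `bound = max_bound` and the
#' archive is filtered by length: the Bremer support of a consensus node is
#' the smallest number of extra steps at which some retained tree lacks the
#' node, i.e. the decay level at which the node disappears from the strict
#' consensus of near-optimal trees. Nodes still present at `max_bound` are
#' reported as `>= max_bound`.
#'
#' @param matrix A [morph_matrix].
#' @param mpts List of optimal `"phylo"` trees for the matrix.
#' @param max_bound Largest decay examined (the published protocol used 15,
#'   retaining up to 10,000 trees).
#' @param config A [search_config()] for the suboptimal search.
#' @return Data frame: `split` (taxon-name label), `bremer` (integer),
#'   `at_bound` (logical: value is a `>=` floor).
#' @export
bremer_supports <- function(matrix, mpts, max_bound = 15L,
                            config = search_config()) {
  cons <- strict_consensus(mpts)
  labs <- sort(cons$tip.label)
  target <- splits_of_ut_canon(as_ut(cons))
  sub <- search_suboptimal(matrix, bound = max_bound, config = config)
  best <- sub$best_length
  arch <- sub$archive
  arch_len <- sub$archive_lengths
  bremer <- rep(NA_integer_, length(target))
  for (i in seq_along(arch)) {
    s <- splits_of_ut_canon(as_ut(arch[[i]]))
    excess <- arch_len[i] - best
    miss <- !(target %in% s)
    upd <- miss & (is.na(bremer) | bremer > excess)
    bremer[upd] <- excess
  }
  data.frame(split = vapply(target, split_label, "", labels = labs,
                            USE.NAMES = FALSE),
             bremer = ifelse(is.na(bremer), max_bound, bremer),
             at_bound = is.na(bremer),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parsimony jackknife support
#'
#' Each replicate deactivates every character independently with
#' probability `p_delete` (0.36, close to e^-1, by convention), reruns a
#' reduced heuristic search on the jackknifed matrix and records the splits
#' of the replicate's strict consensus. Reported values are the percentage
#' of replicates recovering each reference split; splits under the cutoff
#' are flagged.
#'
#' @param matrix A [morph_matrix].
#' @param reps Number of jackknife replicates (the published protocol used
#'   1,000).
#' @param p_delete Independent character deletion probability.
#' @param cutoff_pct Display cutoff percentage (e.g. 63).
#' @param seed Integer seed.
#' @param config A [search_config()] for the *reduced* searches inside
#'   replicates (default 5 addition sequences, hold 20: a deliberate
#'   fidelity/runtime trade-off).
#' @param mpts Optional list of optimal trees defining the reference
#'   splits; computed by [heuristic_search()] when omitted.
#' @param method `"heuristic"` reruns the reduced search per replicate;
#'   `"exact"` enumerates every topology once, precomputes the
#'   topology-by-character length matrix (character lengths do not depend
#'   on which characters a replicate resamples) and reads each replicate's
#'   full optimal set off it — feasible up to 8 taxa and free of search
#'   noise. `"auto"` (default) picks `"exact"` when the matrix has at most
#'   8 taxa.
#' @return Data frame: `split`, `pct`, `below_cutoff`.
#' @export
jackknife_supports <- function(matrix, reps = 1000L, p_delete = 0.36,
                               cutoff_pct = 63, seed = 1L,
                               config = search_config(replicates = 5L,
                                                      hold = 20L),
                               mpts = NULL,
                               method = c("auto", "heuristic", "exact")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (length(matrix$taxa) <= 8L) "exact" else "heuristic"
  stopifnot(reps >= 1L, p_delete >= 0, p_delete < 1)
  if (is.null(mpts))
    mpts <- heuristic_search(matrix, search_config(replicates = 10L,
                                                   seed = seed))$trees
  cons <- strict_consensus(mpts)
  labs <- sort(cons$tip.label)
  target <- splits_of_ut_canon(as_ut(cons))
  hits <- integer(length(target))
  if (method == "exact") {
    prep <- prep_matrix(matrix)
    uts <- enumerate_uts(matrix$taxa, cap = 8L)
    Lmat <- t(vapply(uts, char_lengths_ut, integer(matrix$nchar),
                     prep = prep))
    # incidence of each target split in each topology, in the fast numeric
    # key encoding over the matrix's own taxon order
    ck <- utree_key(remap_tips(as_ut(cons), matrix$taxa))
    tkeys <- if (nzchar(ck)) strsplit(ck, ",")[[1L]] else character(0)
    # align tkeys with `target` labels: both derive from cons' splits, but
    # in different encodings; recompute target labels from tkeys directly
    target_lab <- vapply(tkeys, function(k)
      num_key_label(as.numeric(k), matrix$taxa), "")
    P <- matrix(FALSE, length(uts), length(tkeys))
    for (i in seq_along(uts)) {
      ks <- strsplit(utree_key(uts[[i]]), ",")[[1L]]
      P[i, ] <- tkeys %in% ks
    }
    hits <- integer(length(tkeys))
    for (r in seq_len(reps)) {
      set.seed(split_seed(seed, r))
      keep <- stats::runif(matrix$nchar) >= p_delete
      act <- which(matrix$active & keep)
      if (!length(act)) next
      tot <- if (length(act) == 1L) Lmat[, act] else rowSums(Lmat[, act,
                                                                  drop = FALSE])
      opt <- tot == min(tot)
      hits <- hits + (colSums(P[opt, , drop = FALSE]) == sum(opt))
    }
    pct <- 100 * hits / reps
    return(data.frame(split = target_lab, pct = pct,
                      below_cutoff = pct < cutoff_pct,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  for (r in seq_len(reps)) {
    set.seed(split_seed(seed, r))
    keep <- stats::runif(matrix$nchar) >= p_delete
    sub <- matrix
    sub$active <- matrix$active & keep
    cfg <- config
    cfg$seed <- split_seed(seed, r + reps)
    if (!any(sub$active)) next       # all characters deleted: star consensus
    sr <- heuristic_search(sub, cfg)
    scon <- strict_consensus(sr$trees)
    s <- splits_of_ut_canon(as_ut(scon))
    hits <- hits + (target %in% s)
  }
  pct <- 100 * hits / reps
  data.frame(split = vapply(target, split_label, "", labels = labs),
             pct = pct, below_cutoff = pct < cutoff_pct,
             stringsAsFactors = FALSE)
}

# Decode a numeric tip-set key (sum of 2^(i-1)) into a canonical label.
num_key_label <- function(key, taxa) {
  idx <- integer(0)
  for (i in seq_along(taxa)) {
    if (key %% 2 == 1) idx <- c(idx, i)
    key <- key %/% 2
  }
  canon_split_label(idx, taxa)
}

#' Annotate a consensus tree with support values
#'
#' Writes `bremer/jackknife` strings into the node labels of the consensus
#' so the tree can be exported as annotated Newick.
#'
#' @param tree Consensus `"phylo"`.
#' @param bremer Data frame from [bremer_supports()] (optional).
#' @param jackknife Data frame from [jackknife_supports()] (optional).
#' @return The tree with `node.label` filled.
#' @export
annotate_supports <- function(tree, bremer = NULL, jackknife = NULL) {
  n <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    node <- n + nd
    tips <- tips_below(tree, node)
    if (length(tips) %in% c(1L, n)) next
    key <- canon_split_label(match(tips, tree$tip.label), tree$tip.label)
    b <- if (!is.null(bremer)) bremer$bremer[match(key, bremer$split)] else NA
    j <- if (!is.null(jackknife)) jackknife$pct[match(key, jackknife$split)] else NA
    lab <- c(if (!is.na(b)) paste0("b", b),
             if (length(j) && !is.na(j)) paste0("jk", round(j)))
    labs[nd] <- paste(lab, collapse = "/")
  }
  tree$node.label <- labs
  tree
}

tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) tips_below(tree, k)))
}
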