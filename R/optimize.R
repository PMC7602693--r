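# Parsimony length and character-state optimization.
#
# Two evaluation routes share one traversal:
#  * a vectorized Fitch pass (bitmask set operations across all unordered
#    characters at once) on binary trees;
#  * a generalized Sankoff dynamic program (cost 1 for any change, unordered;
#    cost |i-j|, ordered/additive) that natively handles polytomies and
#    set-valued terminals, used for ordered characters and polytomous trees.
# Missing and inapplicable cells are expanded to the column's observed state
# set; polymorphic cells score as uncertainty (min over member states).

BIGC <- 1e7

# Per-matrix scoring cache: expanded terminal bitmasks, state counts,
# per-character Sankoff terminal cost matrices.
prep_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "morph_matrix"))
  n <- length(matrix$taxa); k <- matrix$nchar
  emat <- matrix$states
  nstates <- integer(k)
  tipcost <- vector("list", k)
  for (j in seq_len(k)) {
    obs <- Reduce(bitwOr, matrix$states[, j], 0L)
    if (obs == 0L) obs <- 1L          # wholly missing column: one dummy state
    maxs <- max(states_of(obs))
    nstates[j] <- maxs + 1L
    full <- mask_of(states_of(obs))
    blank <- emat[, j] == 0L
    emat[blank, j] <- full
    tc <- matrix(BIGC, nstates[j], n)
    for (i in seq_len(n)) tc[states_of(emat[i, j]) + 1L, i] <- 0
    tipcost[[j]] <- tc
  }
  list(n = n, k = k, emat = emat, nstates = nstates,
       ordered = matrix$ordered, active = matrix$active, tipcost = tipcost,
       taxa = matrix$taxa)
}

# min_t cost(s,t) + C(t) for the two cost regimes.
dtransform <- function(C, ordered) {
  if (!ordered) return(pmin(C, min(C) + 1))
  S <- length(C)
  D <- C
  if (S > 1L) {
    for (s in 2:S) D[s] <- min(D[s], D[s - 1L] + 1)
    for (s in (S - 1L):1L) D[s] <- min(D[s], D[s + 1L] + 1)
  }
  D
}

cost_pair <- function(a, b, ordered) if (ordered) abs(a - b) else as.numeric(a != b)

# Sankoff down-pass for one character on a traversal rooted on tip 1's
# pendant edge. Returns total steps and the node cost matrices.
sankoff_char <- function(tr, prep, j, keep = FALSE) {
  tc <- prep$tipcost[[j]]
  S <- prep$nstates[j]
  ordered <- prep$ordered[j]
  m <- length(tr$children)
  C <- matrix(0, S, m)
  C[, seq_len(prep$n)] <- tc
  for (v in tr$post) {
    acc <- numeric(S)
    for (c in tr$children[[v]]) acc <- acc + dtransform(C[, c], ordered)
    C[, v] <- acc
  }
  root_tip <- tr$parent[tr$top]
  tot <- dtransform(C[, root_tip], ordered) + dtransform(C[, tr$top], ordered)
  steps <- min(tot)
  if (!keep) return(list(steps = steps))
  list(steps = steps, C = C, root_tot = tot)
}

# Fast vectorized Fitch over the unordered characters of a *binary* tree.
# Exact for set-valued terminals under cost 1. Returns per-character steps.
fitch_lengths <- function(tr, prep, cols) {
  if (!length(cols)) return(integer(0))
  n <- prep$n
  m <- length(tr$children)
  M <- matrix(0L, m, length(cols))
  M[seq_len(n), ] <- prep$emat[, cols, drop = FALSE]
  steps <- integer(length(cols))
  for (v in tr$post) {
    kids <- tr$children[[v]]
    a <- M[kids[1L], ]; b <- M[kids[2L], ]
    z <- bitwAnd(a, b)
    un <- z == 0L
    steps <- steps + un
    z[un] <- bitwOr(a, b)[un]
    M[v, ] <- z
  }
  rt <- tr$parent[tr$top]
  a <- M[rt, ]; b <- M[tr$top, ]
  steps + (bitwAnd(a, b) == 0L)
}

binary_traversal_ok <- function(tr, n) {
  all(lengths(tr$children[tr$post]) == 2L)
}

char_lengths_ut <- function(ut, prep) {
  tr <- utree_traversal(ut)
  k <- prep$k
  out <- integer(k)
  binary <- binary_traversal_ok(tr, prep$n)
  fit_cols <- if (binary) which(!prep$ordered) else integer(0)
  if (length(fit_cols)) out[fit_cols] <- fitch_lengths(tr, prep, fit_cols)
  rest <- setdiff(seq_len(k), fit_cols)
  for (j in rest) out[j] <- as.integer(sankoff_char(tr, prep, j)$steps)
  out
}

tree_len_ut <- function(ut, prep) {
  # works on partial trees during stepwise addition: traverse from any
  # attached tip
  root_tip <- which(lengths(ut$adj[seq_len(ut$n)]) > 0L)[1L]
  tr <- utree_traversal(ut, root_tip)
  binary <- binary_traversal_ok(tr, prep$n)
  act <- which(prep$active)
  fit_cols <- if (binary) act[!prep$ordered[act]] else integer(0)
  tot <- if (length(fit_cols)) sum(fitch_lengths(tr, prep, fit_cols)) else 0L
  for (j in setdiff(act, fit_cols)) tot <- tot + sankoff_char(tr, prep, j)$steps
  as.integer(tot)
}

as_ut <- function(tree) if (inherits(tree, "utree")) tree else utree_from_phylo(tree)

match_matrix_tree <- function(matrix, ut) {
  if (!setequal(matrix$taxa, ut$labels))
    stop("tree leaves and matrix taxa differ")
  remap_tips(ut, matrix$taxa)
}

#' Parsimony length of one character on a tree
#'
#' Minimum number of state changes implied by the tree, with cost 1 for any
#' change (non-additive) or `|i-j|` (additive). Polytomies are scored
#' natively by the dynamic program.
#'
#' @param tree A `"phylo"` (binary or polytomous; rooting irrelevant).
#' @param matrix A [morph_matrix] whose taxa match the tree's leaves.
#' @param char 1-based character index.
#' @return Non-negative integer step count.
#' @export
char_length <- function(tree, matrix, char) {
  ut <- match_matrix_tree(matrix, as_ut(tree))
  prep <- prep_matrix(matrix)
  tr <- utree_traversal(ut)
  as.integer(sankoff_char(tr, prep, char)$steps)
}

#' Parsimony length of a tree
#'
#' Sum of [char_length()] over the active characters; invariant under
#' rerooting.
#'
#' @inheritParams char_length
#' @return Non-negative integer.
#' @export
tree_length <- function(tree, matrix) {
  ut <- match_matrix_tree(matrix, as_ut(tree))
  tree_len_ut(ut, prep_matrix(matrix))
}

#' Minimum conceivable steps of a character over all trees
#'
#' Unordered: one fewer than the number of states forced by at least one
#' determinate cell (floored at 0). Ordered: the range spanned by the forced
#' states. Polymorphic, missing and inapplicable cells force nothing.
#'
#' @inheritParams char_length
#' @return Integer `m`.
#' @export
min_steps <- function(matrix, char) {
  det <- matrix$kind[, char] == "det"
  st <- unique(unlist(lapply(which(det), function(i)
    states_of(matrix$states[i, char]))))
  if (length(st) < 2L) return(0L)
  if (matrix$ordered[char]) as.integer(max(st) - min(st))
  else length(st) - 1L
}

#' Maximum steps of a character: its star-tree (bush) length
#'
#' Length of the character on the completely unresolved tree: the minimum
#' over ancestral states `a` of the summed cheapest cost from each cell's
#' state set to `a`.
#'
#' @inheritParams char_length
#' @return Integer `g`.
#' @export
max_steps <- function(matrix, char) {
  prep <- prep_matrix(matrix)
  S <- prep$nstates[char]
  ordered <- matrix$ordered[char]
  best <- Inf
  for (a in 0:(S - 1L)) {
    tot <- 0
    for (i in seq_len(prep$n)) {
      st <- states_of(prep$emat[i, char])
      tot <- tot + min(cost_pair(st, a, ordered))
    }
    best <- min(best, tot)
  }
  as.integer(best)
}

# Two-decimal truncation toward zero, from an exact integer fraction.
# Matches how consistency/retention indices are conventionally printed
# (2/7 -> "0.28", 12/17 -> "0.70").
trunc2_str <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) return(NA_character_)
  if (num == den) return("1")
  if (num == 0) return("0")
  v <- (100L * as.integer(num)) %/% as.integer(den)
  sprintf("0.%02d", v)
}

#' Per-character and ensemble homoplasy diagnostics
#'
#' For each active character on the given tree: observed steps `s`, minimum
#' steps `m`, star-tree steps `g`, consistency index `ci = m/s`, retention
#' index `ri = (g-s)/(g-m)` and rescaled consistency `rc = ci*ri`, plus the
#' conventional two-decimal truncated renderings. The ensemble indices are
#' `L = sum(s)`, `CI = sum(m)/sum(s)` and `RI = (sum(g)-sum(s))/(sum(g)-sum(m))`
#' over all active characters, including parsimony-uninformative ones.
#'
#' @inheritParams char_length
#' @return List with elements `per_character` (data frame) and `ensemble`.
#' @export
diagnostics <- function(tree, matrix) {
  ut <- match_matrix_tree(matrix, as_ut(tree))
  prep <- prep_matrix(matrix)
  s <- char_lengths_ut(ut, prep)
  k <- matrix$nchar
  m <- vapply(seq_len(k), function(j) min_steps(matrix, j), 1L)
  g <- vapply(seq_len(k), function(j) max_steps(matrix, j), 1L)
  ci <- ifelse(s > 0, m / s, NA_real_)
  ri <- ifelse(g > m, (g - s) / (g - m), NA_real_)
  per <- data.frame(
    char = seq_len(k), label = matrix$labels, ordered = matrix$ordered,
    active = matrix$active, s = s, m = m, g = g, ci = ci, ri = ri,
    rc = ci * ri,
    ci_str = vapply(seq_len(k), function(j)
      if (s[j] > 0) trunc2_str(m[j], s[j]) else NA_character_, ""),
    ri_str = vapply(seq_len(k), function(j)
      if (g[j] > m[j]) trunc2_str(g[j] - s[j], g[j] - m[j]) else NA_character_, ""),
    stringsAsFactors = FALSE)
  act <- matrix$active
  L <- sum(s[act]); SM <- sum(m[act]); SG <- sum(g[act])
  ens <- list(L = as.integer(L), sum_m = as.integer(SM), sum_g = as.integer(SG),
              CI = SM / L, RI = (SG - L) / (SG - SM),
              CI_str = trunc2_str(SM, L),
              RI_str = trunc2_str(SG - L, SG - SM))
  list(per_character = per, ensemble = ens)
}

# ---- MPR machinery -------------------------------------------------------
# Down-pass cost matrices C, child contributions D, and up-pass context U
# for one character on a rooted traversal. U_v(s): cheapest cost of the rest
# of the tree when v is fixed to s.
mpr_machinery <- function(tr, prep, j) {
  sk <- sankoff_char(tr, prep, j, keep = TRUE)
  S <- prep$nstates[j]
  ordered <- prep$ordered[j]
  C <- sk$C
  m <- ncol(C)
  D <- matrix(0, S, m)           # D[, c] = dtransform(C[, c])
  for (c in seq_len(m)) D[, c] <- dtransform(C[, c], ordered)
  U <- matrix(0, S, m)
  root_tip <- tr$parent[tr$top]
  # virtual root joins root_tip and top
  U[, tr$top] <- cheapest_to(D[, root_tip], ordered)
  U[, root_tip] <- cheapest_to(D[, tr$top], ordered)
  for (v in rev(tr$post)) {
    base <- U[, v] + C[, v]
    for (c in tr$children[[v]]) {
      U[, c] <- cheapest_to(base - D[, c], ordered)
    }
  }
  list(C = C, D = D, U = U, steps = sk$steps, S = S, ordered = ordered,
       root_tip = root_tip)
}

# min over s of X(s) + cost(s, t), as a function of t — same structure as
# dtransform but applied to arbitrary vectors.
cheapest_to <- function(X, ordered) dtransform(X, ordered)

rooted_traversal_for <- function(tree, matrix) {
  ut <- match_matrix_tree(matrix, as_ut(tree))
  list(ut = ut, tr = utree_traversal(ut))
}

#' Most-parsimonious-reconstruction state sets
#'
#' For every internal node the set of states it can take in at least one
#' reconstruction of minimum length, computed from the Sankoff down-pass and
#' an up-pass over the cost vectors.
#'
#' @inheritParams char_length
#' @return Named list: for each internal node id (as labelled by
#'   [tree_splits()] side sets), an integer vector of states; attribute
#'   `"steps"` carries the character length.
#' @export
mpr_sets <- function(tree, matrix, char) {
  rt <- rooted_traversal_for(tree, matrix)
  prep <- prep_matrix(matrix)
  mk <- mpr_machinery(rt$tr, prep, char)
  res <- list()
  eps <- 1e-9
  for (v in rt$tr$post) {
    tot <- mk$C[, v] + mk$U[, v]
    res[[as.character(v)]] <- which(tot <= min(tot) + eps) - 1L
  }
  # label by clade tip sets for stability
  below <- clade_sets(rt$ut, rt$tr)
  names(res) <- vapply(rt$tr$post, function(v)
    paste(sort(rt$ut$labels[below[[v]]]), collapse = "+"), "")
  attr(res, "steps") <- as.integer(mk$steps)
  attr(res, "node_ids") <- rt$tr$post
  res
}

clade_sets <- function(ut, tr) {
  below <- vector("list", length(ut$adj))
  for (i in seq_len(ut$n)) below[[i]] <- i
  for (v in tr$post) below[[v]] <- sort(unlist(below[tr$children[[v]]]))
  below
}

# Resolve one character to a single state per node. ACCTRAN prefers, among
# cost-optimal child states, the one farthest from the parent state (changes
# are pulled rootward and reversed later); DELTRAN prefers the nearest
# (changes are pushed tipward as parallelisms). Ties break to the lowest
# state code. The root state is the lowest member of the root MPR set.
resolve_char <- function(tr, prep, j, mode) {
  mk <- mpr_machinery(tr, prep, j)
  S <- mk$S; ordered <- mk$ordered
  m <- length(tr$children)
  state <- integer(m)
  eps <- 1e-9
  # virtual-root: choose the state optimal for the full tree on the edge
  rt_tot <- dtransform(mk$C[, mk$root_tip], ordered) +
    dtransform(mk$C[, tr$top], ordered)
  root_state <- which(rt_tot <= min(rt_tot) + eps)[1L] - 1L
  assign_down <- function(v, p_state) {
    vals <- cost_pair(0:(S - 1L), p_state, ordered) + mk$C[, v]
    opt <- which(vals <= min(vals) + eps) - 1L
    st <- if (mode == "acctran") {
      d <- cost_pair(opt, p_state, ordered)
      opt[order(-d, opt)][1L]
    } else {
      d <- cost_pair(opt, p_state, ordered)
      opt[order(d, opt)][1L]
    }
    state[v + 0L] <<- st
    if (v > prep$n)
      for (c in tr$children[[v]]) assign_down(c, st)
    invisible()
  }
  assign_down(tr$top, root_state)
  assign_down(mk$root_tip, root_state)
  # terminals: fix to their observed state nearest the assignment when
  # ambiguous (missing cells inherit the ancestral assignment when allowed)
  list(state = state, steps = mk$steps, root_state = root_state)
}

#' Resolve ancestral states under ACCTRAN or DELTRAN
#'
#' Produces one state per node per character. Under either mode the implied
#' number of changes of each character equals its length `s`; the modes
#' differ only in how optimization ambiguity is resolved (ACCTRAN
#' accelerates transformations toward the root, favouring reversals;
#' DELTRAN delays them toward the tips, favouring parallelisms).
#'
#' @inheritParams char_length
#' @param mode `"acctran"` or `"deltran"`.
#' @param root_taxon Taxon whose pendant edge roots the presentation
#'   (default: first taxon of the matrix).
#' @return Object of class `"mpclad_reconstruction"`: list with `mode`,
#'   `node_states` (internal nodes x characters), `tip_states`, `steps`
#'   (per-character lengths), `clades` (tip-name sets labelling internal
#'   nodes) and `changes` (see [list_changes()]).
#' @export
reconstruct <- function(tree, matrix, mode = c("acctran", "deltran"),
                        root_taxon = NULL) {
  mode <- match.arg(mode)
  ut <- match_matrix_tree(matrix, as_ut(tree))
  root_tip <- if (is.null(root_taxon)) 1L else match(root_taxon, ut$labels)
  if (is.na(root_tip)) stop("unknown root taxon")
  tr <- utree_traversal(ut, root_tip)
  prep <- prep_matrix(matrix)
  k <- matrix$nchar
  m <- length(tr$children)
  states <- matrix(NA_integer_, m, k)
  steps <- integer(k)
  for (j in seq_len(k)) {
    r <- resolve_char(tr, prep, j, mode)
    states[, j] <- r$state
    steps[j] <- r$steps
  }
  below <- clade_sets(ut, tr)
  clades <- vapply(seq_len(m), function(v)
    paste(sort(ut$labels[below[[v]]]), collapse = "+"), "")
  res <- list(mode = mode, ut = ut, tr = tr,
              node_states = states[tr$post, , drop = FALSE],
              all_states = states,
              tip_states = states[seq_len(ut$n), , drop = FALSE],
              steps = steps, clades = clades, taxa = ut$labels)
  class(res) <- "mpclad_reconstruction"
  res
}

#' @export
print.mpclad_reconstruction <- function(x, ...) {
  cat("mpclad_reconstruction (", x$mode, "): ", length(x$steps),
      " characters, total steps ", sum(x$steps), "\n", sep = "")
  invisible(x)
}

changes_from_states <- function(rec, matrix) {
  tr <- rec$tr; ut <- rec$ut
  k <- ncol(rec$all_states)
  ord <- matrix$ordered
  rows <- list()
  edges <- list()
  # every node except the rooting tip hangs below one branch; the branch
  # above tr$top is the rooting edge itself
  for (v in c(rev(tr$post), seq_len(ut$n))) {
    p <- tr$parent[v]
    if (p == 0L) next
    edges[[length(edges) + 1L]] <- c(p, v)
  }
  for (e in edges) {
    a <- rec$all_states[e[1L], ]; b <- rec$all_states[e[2L], ]
    for (j in which(a != b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        node = e[2L], clade = rec$clades[e[2L]], char = j,
        from = a[j], to = b[j],
        steps = as.integer(cost_pair(a[j], b[j], ord[j])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(node = integer(0), clade = character(0),
                      char = integer(0), from = integer(0), to = integer(0),
                      steps = integer(0)))
  do.call(rbind, rows)
}

#' List character-state transformations on each branch
#'
#' Walks a resolved reconstruction and reports one record per branch per
#' changing character, with the transformation (`from`, `to`), a
#' `homoplastic` flag (a transformation is non-homoplastic iff its derived
#' state arises exactly once on the tree and never reverses) and an
#' `ambiguity` class: `"unambiguous"` when the identical record occurs under
#' both ACCTRAN and DELTRAN, otherwise `"acctran-only"`/`"deltran-only"`.
#'
#' @inheritParams reconstruct
#' @return Data frame of transformation records.
#' @export
list_changes <- function(tree, matrix, mode = c("acctran", "deltran"),
                         root_taxon = NULL) {
  mode <- match.arg(mode)
  rec_a <- reconstruct(tree, matrix, "acctran", root_taxon)
  rec_d <- reconstruct(tree, matrix, "deltran", root_taxon)
  ch_a <- changes_from_states(rec_a, matrix)
  ch_d <- changes_from_states(rec_d, matrix)
  keyify <- function(df) paste(df$node, df$char, df$from, df$to)
  ka <- keyify(ch_a); kd <- keyify(ch_d)
  main <- if (mode == "acctran") ch_a else ch_d
  kmain <- if (mode == "acctran") ka else kd
  kother <- if (mode == "acctran") kd else ka
  main$ambiguity <- ifelse(kmain %in% kother, "unambiguous",
                           paste0(mode, "-only"))
  # homoplasy flag per record, within this mode's reconstruction
  main$homoplastic <- vapply(seq_len(nrow(main)), function(i) {
    ch <- main[main$char == main$char[i], , drop = FALSE]
    arises <- sum(ch$to == main$to[i])
    reverses <- any(ch$from == main$to[i])
    !(arises == 1L && !reverses)
  }, TRUE)
  main[order(main$char, main$clade), ]
}

#' Count characters by optimization-ambiguity class on a tree
#'
#' A character is unambiguous when its ACCTRAN and DELTRAN resolutions
#' coincide on every node; otherwise it is ambiguous and the two modes
#' differ.
#'
#' @inheritParams char_length
#' @param root_taxon Outgroup used to root the optimization.
#' @return List with `unambiguous` / `ambiguous` character index vectors.
#' @export
ambiguity_summary <- function(tree, matrix, root_taxon = NULL) {
  rec_a <- reconstruct(tree, matrix, "acctran", root_taxon)
  rec_d <- reconstruct(tree, matrix, "deltran", root_taxon)
  same <- vapply(seq_len(ncol(rec_a$node_states)), function(j)
    all(rec_a$node_states[, j] == rec_d$node_states[, j]), TRUE)
  list(unambiguous = which(same), ambiguous = which(!same))
}
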