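# Heuristic and exact equal-weights parsimony tree search.

#' Search configuration
#'
#' @param replicates Number of random addition sequences (default 50; raise
#'   toward several hundred for difficult matrices).
#' @param hold Maximum trees retained per replicate.
#' @param seed Master seed; per-replicate seeds are derived from it
#'   deterministically, so runs are reproducible bit for bit.
#' @param collapse_rule Zero-length branch collapsing applied to the pooled
#'   optimal trees: `"min_zero"` (collapse branches whose minimum length
#'   over all most-parsimonious reconstructions is zero, the TNT-style
#'   default), `"max_zero"` (only branches that cannot have positive
#'   length), or `"none"`.
#' @param suboptimal_bound Extra steps allowed when buffering trees
#'   (0 = optimal only).
#' @param global_buffer Cap on the total number of retained trees.
#' @return A list of class `"search_config"`.
#' @export
search_config <- function(replicates = 50L, hold = 200L, seed = 1L,
                          collapse_rule = c("min_zero", "max_zero", "none"),
                          suboptimal_bound = 0L, global_buffer = 10000L) {
  collapse_rule <- match.arg(collapse_rule)
  stopifnot(replicates >= 1L, hold >= 1L, suboptimal_bound >= 0L)
  structure(list(replicates = as.integer(replicates), hold = as.integer(hold),
                 seed = as.integer(seed), collapse_rule = collapse_rule,
                 suboptimal_bound = as.integer(suboptimal_bound),
                 global_buffer = as.integer(global_buffer)),
            class = "search_config")
}

split_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i * 2654435) %% 2147483647)
}

# TBR swap from a starting tree. Buffers up to `hold` trees within
# `bound` steps of the running best; strictly better trees restart
# swapping from scratch. Returns list(best, trees, archive) where archive
# holds all distinct trees within bound encountered (for Bremer).
tbr_swap <- function(ut0, prep, hold, bound = 0L, keep_archive = FALSE,
                     archive_cap = 10000L) {
  best <- tree_len_ut(ut0, prep)
  buffer <- list(ut0)
  keys <- utree_key(ut0)
  lens <- best
  archive <- list(); arch_lens <- integer(0)
  arch_seen <- new.env(parent = emptyenv())
  if (keep_archive) {
    archive <- list(ut0); arch_lens <- best
    assign(keys, TRUE, envir = arch_seen)
  }
  i <- 1L
  while (i <= length(buffer)) {
    improved <- FALSE
    for (nb in tbr_neighbors_ut(buffer[[i]])) {
      len <- tree_len_ut(nb, prep)
      key <- NULL
      if (keep_archive && len <= best + bound &&
          length(archive) < archive_cap) {
        key <- utree_key(nb)
        if (!exists(key, envir = arch_seen, inherits = FALSE)) {
          assign(key, TRUE, envir = arch_seen)
          archive[[length(archive) + 1L]] <- nb
          arch_lens <- c(arch_lens, len)
        }
      }
      if (len < best) {
        best <- len
        buffer <- list(nb)
        keys <- if (is.null(key)) utree_key(nb) else key
        lens <- len
        improved <- TRUE
        break
      } else if (len == best && length(buffer) < hold) {
        if (is.null(key)) key <- utree_key(nb)
        if (!key %in% keys) {
          buffer[[length(buffer) + 1L]] <- nb
          keys <- c(keys, key)
          lens <- c(lens, len)
        }
      }
    }
    i <- if (improved) 1L else i + 1L
  }
  if (keep_archive) {
    sel <- arch_lens <= best + bound
    archive <- archive[sel]; arch_lens <- arch_lens[sel]
  }
  list(best = best, trees = buffer, archive = archive, archive_lens = arch_lens)
}

#' Heuristic parsimony search (random addition sequences + TBR)
#'
#' For each replicate a Wagner starting tree is built from a random taxon
#' addition sequence and refined by tree bisection and reconnection
#' swapping, holding up to `hold` equally parsimonious trees. The pooled
#' optimal trees are collapsed according to `collapse_rule` and
#' deduplicated by unrooted topology.
#'
#' @param matrix A [morph_matrix] with at least 4 taxa.
#' @param config A [search_config()].
#' @return List of class `"search_result"`: `best_length`, `trees` (list of
#'   `"phylo"`), `replicate_log` (data frame), `config`.
#' @export
heuristic_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "morph_matrix"), length(matrix$taxa) >= 4L)
  prep <- prep_matrix(matrix)
  best <- Inf
  pool <- list(); pool_lens <- integer(0)
  log <- data.frame(replicate = integer(0), seed = integer(0),
                    start_length = integer(0), best_length = integer(0),
                    trees_held = integer(0))
  for (r in seq_len(config$replicates)) {
    s <- split_seed(config$seed, r)
    ut <- random_addition_ut(matrix, s)
    start_len <- tree_len_ut(ut, prep)
    sw <- tbr_swap(ut, prep, config$hold)
    log <- rbind(log, data.frame(replicate = r, seed = s,
                                 start_length = start_len,
                                 best_length = sw$best,
                                 trees_held = length(sw$trees)))
    if (sw$best < best) { best <- sw$best; pool <- list() }
    if (sw$best == best) pool <- c(pool, sw$trees)
  }
  finalize_search(matrix, prep, pool, best, config)
}

finalize_search <- function(matrix, prep, pool, best, config,
                            log = NULL, archive = NULL, archive_lens = NULL) {
  rule <- config$collapse_rule
  if (rule != "none")
    pool <- lapply(pool, function(ut) collapse_zero_ut(ut, prep, rule))
  keys <- vapply(pool, utree_key, "")
  pool <- pool[!duplicated(keys)]
  if (length(pool) > config$global_buffer)
    pool <- pool[seq_len(config$global_buffer)]
  res <- list(best_length = as.integer(best),
              trees = lapply(pool, phylo_from_utree),
              n_trees = length(pool),
              replicate_log = log, config = config)
  if (!is.null(archive)) {
    res$archive <- lapply(archive, phylo_from_utree)
    res$archive_lengths = as.integer(archive_lens)
  }
  class(res) <- "search_result"
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: best length ", x$best_length, ", ", x$n_trees,
      " tree(s)\n", sep = "")
  invisible(x)
}

#' Exhaustive (or branch-and-bound) parsimony search
#'
#' Evaluates every unrooted binary topology by recursive taxon addition.
#' With `prune = TRUE` partial trees longer than the current best (plus
#' `bound`) are abandoned; because adding taxa can never decrease parsimony
#' length this never changes the result. Refuses more than `cap` taxa.
#'
#' @param matrix A [morph_matrix].
#' @param cap Largest taxon count accepted (default 9).
#' @param bound Retain all trees within `bound` steps of the optimum.
#' @param prune Use branch-and-bound pruning (default TRUE).
#' @return A `"search_result"` (collapse rule `"none"`; every optimal
#'   binary topology is returned).
#' @export
exhaustive_search <- function(matrix, cap = 9L, bound = 0L, prune = TRUE) {
  n <- length(matrix$taxa)
  if (n > cap) stop("refusing exhaustive search on ", n, " taxa (cap = ",
                    cap, ")")
  stopifnot(n >= 4L)
  prep <- prep_matrix(matrix)
  best <- Inf
  found <- list(); found_lens <- integer(0)
  adj <- vector("list", 2L * n - 2L)
  v0 <- n + 1L
  adj[[v0]] <- c(1L, 2L, 3L); adj[[1L]] <- v0; adj[[2L]] <- v0; adj[[3L]] <- v0
  ut0 <- utree(n, adj, matrix$taxa)
  recurse <- function(ut, next_tip) {
    len <- tree_len_ut(ut, prep)
    if (prune && len > best + bound) return(invisible())
    if (next_tip > n) {
      if (len < best) {
        best <<- len
        keep <- found_lens <= best + bound
        found <<- found[keep]; found_lens <<- found_lens[keep]
      }
      if (len <= best + bound) {
        found[[length(found) + 1L]] <<- ut
        found_lens <<- c(found_lens, len)
      }
      return(invisible())
    }
    ed <- utree_edges(ut)
    for (i in seq_len(nrow(ed)))
      recurse(attach_tip(ut, next_tip, ed[i, ], n), next_tip + 1L)
    invisible()
  }
  recurse(ut0, 4L)
  keep <- found_lens <= best + bound
  cfg <- search_config(collapse_rule = "none", suboptimal_bound = bound)
  res <- finalize_search(matrix, prep, found[keep], best, cfg)
  res$tree_lengths <- found_lens[keep]
  res
}

#' Heuristic search retaining suboptimal trees
#'
#' As [heuristic_search()], but every distinct topology encountered during
#' swapping whose length is within `bound` steps of the best is retained
#' (up to `config$global_buffer`), which is the raw material for Bremer
#' support.
#'
#' @param matrix A [morph_matrix].
#' @param bound Steps above the optimum to retain.
#' @param config A [search_config()].
#' @return A `"search_result"` with `archive` / `archive_lengths` fields.
#' @export
search_suboptimal <- function(matrix, bound, config = search_config()) {
  stopifnot(bound >= 0L)
  prep <- prep_matrix(matrix)
  best <- Inf
  pool <- list()
  archive <- list(); arch_lens <- integer(0)
  arch_seen <- new.env(parent = emptyenv())
  for (r in seq_len(config$replicates)) {
    s <- split_seed(config$seed, r)
    ut <- random_addition_ut(matrix, s)
    sw <- tbr_swap(ut, prep, config$hold, bound = bound, keep_archive = TRUE,
                   archive_cap = config$global_buffer)
    if (sw$best < best) best <- sw$best
    if (sw$best == best) pool <- c(pool, sw$trees)
    for (idx in seq_along(sw$archive)) {
      if (sw$archive_lens[idx] > best + bound) next
      key <- utree_key(sw$archive[[idx]])
      if (!exists(key, envir = arch_seen, inherits = FALSE) &&
          length(archive) < config$global_buffer) {
        assign(key, TRUE, envir = arch_seen)
        archive[[length(archive) + 1L]] <- sw$archive[[idx]]
        arch_lens <- c(arch_lens, sw$archive_lens[idx])
      }
    }
  }
  sel <- arch_lens <= best + bound
  finalize_search(matrix, prep, pool, best, config,
                  archive = archive[sel], archive_lens = arch_lens[sel])
}

# Per-edge length range over all most-parsimonious reconstructions, summed
# over active characters. Returns a matrix: rows = internal edges
# (child-node keyed), cols = min / max.
branch_length_ranges <- function(ut, prep) {
  tr <- utree_traversal(ut)
  act <- which(prep$active)
  # internal edges: parent(v) -> v where both are internal
  eds <- Filter(function(v) tr$parent[v] > prep$n, tr$post)
  mins <- setNames(numeric(length(eds)), as.character(eds))
  maxs <- setNames(numeric(length(eds)), as.character(eds))
  eps <- 1e-9
  for (j in act) {
    mk <- mpr_machinery(tr, prep, j)
    S <- mk$S
    sv <- 0:(S - 1L)
    for (z in seq_along(eds)) {
      v <- eds[[z]]; p <- tr$parent[v]
      base <- mk$U[, p] + mk$C[, p] - mk$D[, v]   # context at parent, child
                                                  # contribution removed
      lo <- Inf; hi <- -Inf
      for (sp in sv) {
        tot_t <- base[sp + 1L] + cost_pair(sv, sp, mk$ordered) + mk$C[, v]
        opt <- which(tot_t <= mk$steps + eps)
        if (length(opt)) {
          d <- cost_pair(opt - 1L, sp, mk$ordered)
          lo <- min(lo, min(d)); hi <- max(hi, max(d))
        }
      }
      mins[z] <- mins[z] + lo
      maxs[z] <- maxs[z] + hi
    }
  }
  list(edges = eds, min = mins, max = maxs, tr = tr)
}

# Collapse one branch at a time, recomputing ranges after each contraction:
# contracting a single branch whose per-character minimum length is zero
# preserves every character's length, whereas contracting several such
# branches at once can lengthen the tree (different characters may need
# different reconstructions).
collapse_zero_ut <- function(ut, prep, rule = c("min_zero", "max_zero", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(ut)
  repeat {
    if (ut$n < 4L) return(ut)
    br <- branch_length_ranges(ut, prep)
    drop <- if (rule == "min_zero") br$edges[br$min <= 0]
            else br$edges[br$max <= 0]
    if (!length(drop)) return(ut)
    v <- drop[[1L]]
    p <- br$tr$parent[v]
    adj <- ut$adj
    adj[[p]] <- c(setdiff(adj[[p]], v), setdiff(adj[[v]], p))
    for (w in setdiff(adj[[v]], p))
      adj[[w]] <- replace(adj[[w]], adj[[w]] == v, p)
    adj[[v]] <- integer(0)
    ut <- compact_utree(utree(ut$n, adj, ut$labels))
  }
}

#' Collapse zero-length branches of a tree
#'
#' Under `"min_zero"` every internal branch whose minimum length over all
#' most-parsimonious reconstructions is zero is collapsed into a polytomy
#' (TNT-style default); `"max_zero"` collapses only branches that cannot
#' carry any change; `"none"` returns the tree unchanged. Collapsing never
#' increases tree length.
#'
#' @inheritParams char_length
#' @param rule Collapsing rule.
#' @return A `"phylo"`, possibly polytomous.
#' @export
collapse_zero_branches <- function(tree, matrix,
                                   rule = c("min_zero", "max_zero", "none")) {
  rule <- match.arg(rule)
  ut <- match_matrix_tree(matrix, as_ut(tree))
  phylo_from_utree(collapse_zero_ut(ut, prep_matrix(matrix), rule))
}
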