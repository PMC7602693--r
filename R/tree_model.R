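#' Parse a Newick string into a phylogenetic tree
#'
#' Topology-only Newick reader. Branch lengths, if present, are discarded:
#' the package works with cladograms. A light syntax pre-check reports the
#' character position of unbalanced parentheses before handing the text to
#' [ape::read.tree()].
#'
#' @param text A single Newick string (terminating `;` optional).
#' @return An object of class `"phylo"`.
#' @export
#' @examples
#' tr <- parse_newick("(A,(B,C));")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") depth <- depth + 1L
    if (chars[[i]] == ")") depth <- depth - 1L
    if (depth < 0L) stop("newick syntax error: unmatched ')' at position ", i)
  }
  if (depth > 0L)
    stop("newick syntax error: ", depth, " unclosed '(' at end of input (position ",
         length(chars), ")")
  if (!grepl(";", text, fixed = TRUE)) text <- paste0(text, ";")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("newick syntax error: ape could not parse the string")
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

#' Serialize a tree as a Newick string
#'
#' @param tree A `"phylo"` object.
#' @return A Newick string (with trailing `;`), topology only.
#' @export
write_newick <- function(tree) {
  tree$edge.length <- NULL
  ape::write.tree(tree)
}

#' Root a tree on the pendant edge of a taxon
#'
#' Returns the same unrooted topology presented with `taxon` as the
#' outgroup, i.e. sister to all remaining taxa. The unrooted split set is
#' unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param taxon Name of the outgroup taxon.
#' @return A `"phylo"` object rooted on the pendant edge of `taxon`.
#' @export
root_at <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label)
    stop("unknown taxon: ", taxon)
  ut <- utree_from_phylo(tree)
  if (ut$n <= 2L) return(tree)
  phylo_from_utree(ut, root_tip = match(taxon, ut$labels))
}

#' Enumerate all unrooted binary topologies on a taxon set
#'
#' Produces each of the (2n-5)!! unrooted binary topologies exactly once by
#' recursive taxon addition. Intended as a small-n oracle for the heuristic
#' search; refuses taxon sets above `cap`.
#'
#' @param taxa Character vector of taxon names (3 <= n <= cap).
#' @param cap Largest taxon count accepted (default 9).
#' @return A list of `"phylo"` trees.
#' @export
enumerate_unrooted_trees <- function(taxa, cap = 9L) {
  lapply(enumerate_uts(taxa, cap), phylo_from_utree)
}

enumerate_uts <- function(taxa, cap = 9L) {
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > cap) stop("refusing to enumerate ", n, " taxa (cap = ", cap, ")")
  res <- list()
  recurse <- function(ut, next_tip) {
    if (next_tip > n) {
      res[[length(res) + 1L]] <<- ut
      return(invisible())
    }
    ed <- utree_edges(ut)
    for (i in seq_len(nrow(ed)))
      recurse(attach_tip(ut, next_tip, ed[i, ], n), next_tip + 1L)
  }
  # base 3-taxon star on the full label set so tip ids are stable
  adj <- vector("list", 2L * n - 2L)
  v0 <- n + 1L
  adj[[v0]] <- c(1L, 2L, 3L); adj[[1L]] <- v0; adj[[2L]] <- v0; adj[[3L]] <- v0
  ut0 <- utree(n, adj, taxa)
  recurse(ut0, 4L)
  res
}

# Attach tip `tip` into edge e of ut (labels already sized for n taxa).
attach_tip <- function(ut, tip, e, n_total) {
  adj <- ut$adj
  x <- length(adj) + 1L
  used <- which(vapply(adj, length, 1L) > 0L)
  x <- max(used, n_total) + 1L
  if (x > length(adj)) adj[[x]] <- integer(0)
  adj[[e[1L]]] <- replace(adj[[e[1L]]], adj[[e[1L]]] == e[2L], x)
  adj[[e[2L]]] <- replace(adj[[e[2L]]], adj[[e[2L]]] == e[1L], x)
  adj[[x]] <- c(e[1L], e[2L], tip)
  adj[[tip]] <- x
  utree(ut$n, adj, ut$labels)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the non-trivial splits of the two unrooted
#' topologies.
#'
#' @param t1,t2 `"phylo"` objects on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ")
  u1 <- utree_from_phylo(t1)
  u2 <- utree_from_phylo(t2)
  # align tip indexing of t2 to t1's label order
  u2 <- remap_tips(u2, u1$labels)
  s1 <- utree_splits(u1)
  s2 <- utree_splits(u2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

remap_tips <- function(ut, ref_labels) {
  perm <- match(ut$labels, ref_labels)      # old tip id -> new tip id
  m <- length(ut$adj)
  map <- seq_len(m)
  map[seq_len(ut$n)] <- perm
  adj <- vector("list", m)
  for (v in seq_len(m)) adj[[map[v]]] <- map[ut$adj[[v]]]
  utree(ut$n, adj, ref_labels)
}

#' All tree bisection and reconnection (TBR) neighbours of a binary tree
#'
#' Every edge of the tree is bisected in turn; the two fragments are
#' reconnected across every pair of their edges. Leaf and cherry fragments
#' degenerate to SPR moves, so the TBR neighbourhood contains the full SPR
#' neighbourhood. Duplicate topologies (and the input tree itself) are
#' removed.
#'
#' @param tree A binary `"phylo"` with at least 4 tips.
#' @return List of `"phylo"` trees.
#' @export
tbr_neighbors <- function(tree) {
  ut <- utree_from_phylo(tree)
  res <- tbr_neighbors_ut(ut)
  lapply(res, phylo_from_utree)
}

tbr_neighbors_ut <- function(ut) {
  stopifnot(is_binary_utree(ut), ut$n >= 4L)
  self_key <- utree_key(ut)
  seen <- new.env(parent = emptyenv())
  assign(self_key, TRUE, envir = seen)
  out <- list()
  ed <- utree_edges(ut)
  for (i in seq_len(nrow(ed))) {
    frags <- bisect_edge(ut, ed[i, ])
    if (is.null(frags)) next
    for (ea in seq_len(nrow(frags$edges_a))) {
      for (eb in seq_len(nrow(frags$edges_b))) {
        nt <- reconnect(frags, frags$edges_a[ea, ], frags$edges_b[eb, ])
        key <- utree_key(nt)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- nt
        }
      }
    }
  }
  out
}

# Bisect edge (u,v): label every node with its fragment; suppress the two
# cut endpoints (each becomes degree 2 inside its fragment, or is a tip).
# Returns the fragment membership plus candidate reattachment edges. Edges
# are encoded on the *original* node ids after endpoint suppression.
bisect_edge <- function(ut, e) {
  n <- ut$n
  adj <- ut$adj
  u <- e[1L]; v <- e[2L]
  adj[[u]] <- setdiff(adj[[u]], v)
  adj[[v]] <- setdiff(adj[[v]], u)
  memb <- integer(length(adj))
  for (start in c(u, v)) {
    lab <- if (start == u) 1L else 2L
    stack <- start
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (memb[x]) next
      memb[x] <- lab
      stack <- c(stack, adj[[x]][memb[adj[[x]]] == 0L])
    }
  }
  # splice out degree-2 cut endpoints (internal ones)
  spliced <- list()
  for (x in c(u, v)) {
    if (x > n && length(adj[[x]]) == 2L) {
      nb <- adj[[x]]
      adj[[nb[1L]]] <- replace(adj[[nb[1L]]], adj[[nb[1L]]] == x, nb[2L])
      adj[[nb[2L]]] <- replace(adj[[nb[2L]]], adj[[nb[2L]]] == x, nb[1L])
      adj[[x]] <- integer(0)
      spliced[[length(spliced) + 1L]] <- x
    }
  }
  edge_of <- function(lab, anchor) {
    ids <- which(memb == lab & (vapply(adj, length, 1L) > 0L | seq_along(adj) <= n))
    ids <- ids[vapply(adj[ids], length, 1L) > 0L | ids <= n]
    res <- list()
    for (a in ids) for (b in adj[[a]]) if (a < b) res[[length(res) + 1L]] <- c(a, b)
    if (!length(res)) {
      # single-node fragment (a leaf, or a leaf pair): reattachment point is
      # the node itself, encoded as (x, 0)
      root <- if (anchor > n && !length(adj[[anchor]])) {
        cand <- which(memb == lab & seq_along(adj) <= n)
        cand[1L]
      } else anchor
      return(matrix(c(root, 0L), 1L, 2L))
    }
    do.call(rbind, res)
  }
  list(adj = adj, n = n, labels = ut$labels,
       edges_a = edge_of(1L, u), edges_b = edge_of(2L, v),
       memb = memb)
}

# Reconnect the two fragments across edge ea (fragment A) and eb (fragment
# B). An edge encoded (x, 0) means "attach directly to node x".
reconnect <- function(frags, ea, eb) {
  adj <- frags$adj
  n <- frags$n
  free <- which(vapply(adj, length, 1L) == 0L & seq_along(adj) > n)
  need <- (ea[2L] != 0L) + (eb[2L] != 0L)
  while (length(free) < max(need, 0L) + 0L) { adj[[length(adj) + 1L]] <- integer(0); free <- c(free, length(adj)) }
  pts <- integer(2)
  ends <- list(ea, eb)
  newmid <- integer(0)
  for (k in 1:2) {
    e <- ends[[k]]
    if (e[2L] == 0L) {
      pts[k] <- e[1L]
    } else {
      x <- free[[1L]]; free <- free[-1L]
      adj[[e[1L]]] <- replace(adj[[e[1L]]], adj[[e[1L]]] == e[2L], x)
      adj[[e[2L]]] <- replace(adj[[e[2L]]], adj[[e[2L]]] == e[1L], x)
      adj[[x]] <- c(e[1L], e[2L])
      pts[k] <- x
    }
  }
  adj[[pts[1L]]] <- c(adj[[pts[1L]]], pts[2L])
  adj[[pts[2L]]] <- c(adj[[pts[2L]]], pts[1L])
  suppress_degree2(utree(n, adj, frags$labels))
}

#' Wagner (random addition sequence) starting tree
#'
#' Builds a greedy stepwise-addition tree: taxa are added in a
#' seed-determined random order, each at the insertion point that minimizes
#' total parsimony length; ties are broken by lowest edge index in a fixed
#' enumeration order, so the result is fully deterministic given the seed.
#'
#' @param matrix A [morph_matrix] object.
#' @param seed Integer seed controlling the addition order.
#' @return A `"phylo"` tree on all taxa of the matrix.
#' @export
random_addition_tree <- function(matrix, seed = 1L) {
  ut <- random_addition_ut(matrix, seed)
  phylo_from_utree(ut)
}

random_addition_ut <- function(matrix, seed = 1L) {
  stopifnot(inherits(matrix, "morph_matrix"))
  n <- length(matrix$taxa)
  stopifnot(n >= 3L)
  set.seed(seed)
  ord <- sample.int(n)
  prep <- prep_matrix(matrix)
  adj <- vector("list", 2L * n - 2L)
  v0 <- n + 1L
  adj[[v0]] <- ord[1:3]
  for (t in ord[1:3]) adj[[t]] <- v0
  ut <- utree(n, adj, matrix$taxa)
  for (tip in ord[-(1:3)]) {
    ed <- utree_edges(ut)
    best <- NULL; best_len <- Inf
    for (i in seq_len(nrow(ed))) {
      cand <- attach_tip(ut, tip, ed[i, ], n)
      len <- tree_len_ut(cand, prep)
      if (len < best_len) { best_len <- len; best <- cand }
    }
    ut <- best
  }
  ut
}
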