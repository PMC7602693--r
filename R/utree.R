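# Internal unrooted-tree representation used by the search and optimization
# engines. Tips are nodes 1..n (in the order of `labels`); internal nodes are
# n+1 .. length(adj). `adj` is an adjacency list of integer vectors. Public
# functions accept and return ape "phylo" objects; these helpers convert.

utree <- function(n, adj, labels) {
  structure(list(n = as.integer(n), adj = adj, labels = labels),
            class = "utree")
}

utree_from_phylo <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  m <- max(phy$edge)
  adj <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ut <- utree(n, adj, phy$tip.label)
  suppress_degree2(ut)
}

# Remove degree-2 nodes (e.g. a rooted phylo's root) by splicing their two
# neighbours together; then compact node ids so internal ids are contiguous.
suppress_degree2 <- function(ut) {
  n <- ut$n
  adj <- ut$adj
  repeat {
    deg2 <- which(vapply(adj, length, 1L) == 2L)
    deg2 <- deg2[deg2 > n]
    if (!length(deg2)) break
    v <- deg2[[1L]]
    nb <- adj[[v]]
    adj[[nb[1L]]] <- replace(adj[[nb[1L]]], adj[[nb[1L]]] == v, nb[2L])
    adj[[nb[2L]]] <- replace(adj[[nb[2L]]], adj[[nb[2L]]] == v, nb[1L])
    adj[[v]] <- integer(0)
  }
  compact_utree(utree(n, adj, ut$labels))
}

compact_utree <- function(ut) {
  keep <- which(vapply(ut$adj, length, 1L) > 0L | seq_along(ut$adj) <= ut$n)
  if (length(keep) == length(ut$adj)) return(ut)
  map <- integer(length(ut$adj))
  map[keep] <- seq_along(keep)
  adj <- lapply(ut$adj[keep], function(v) map[v])
  utree(ut$n, adj, ut$labels)
}

# Rooted traversal over the pendant edge of tip `root_tip`: a virtual root
# joins `root_tip` and its neighbour, so every internal node has >= 2
# children. Returns postorder of internal nodes, children lists and parents.
utree_traversal <- function(ut, root_tip = 1L) {
  n <- ut$n
  m <- length(ut$adj)
  if (n == 1L) return(list(post = integer(0), children = vector("list", m),
                           parent = integer(m), top = root_tip))
  top <- ut$adj[[root_tip]][1L]
  parent <- integer(m)
  parent[top] <- root_tip
  children <- vector("list", m)
  stack <- top
  order_v <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    kids <- setdiff(ut$adj[[v]], parent[v])
    children[[v]] <- kids
    parent[kids] <- v
    kids <- kids[kids > n]
    if (length(kids)) stack <- c(stack, kids)
  }
  post <- rev(order_v[order_v > n])
  list(post = post, children = children, parent = parent, top = top)
}

utree_edges <- function(ut) {
  res <- list()
  for (v in seq_along(ut$adj)) {
    for (w in ut$adj[[v]]) if (v < w) res[[length(res) + 1L]] <- c(v, w)
  }
  do.call(rbind, res)
}

is_binary_utree <- function(ut) {
  deg <- vapply(ut$adj, length, 1L)
  all(deg[seq_len(ut$n)] == 1L) && all(deg[-seq_len(ut$n)] %in% c(0L, 3L))
}

# Canonical split signature: for every internal edge, the set of tip indices
# on the side not containing tip 1, rendered "a.b.c" and sorted. Used for
# consensus construction and RF distance.
utree_splits <- function(ut) {
  n <- ut$n
  if (n < 4L) return(character(0))
  tr <- utree_traversal(ut)
  below <- vector("list", length(ut$adj))
  for (i in seq_len(n)) below[[i]] <- i
  for (v in tr$post) below[[v]] <- sort(unlist(below[tr$children[[v]]]))
  keys <- character(0)
  for (v in tr$post) {
    # edge above v; nontrivial iff both sides have >= 2 tips
    side <- below[[v]]
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(side, collapse = "."))
  }
  sort(keys)
}

# Fast topology identity key: tip-set bitmasks accumulated as exact sums of
# powers of two (doubles are exact below 2^53; tip counts here are far
# smaller). Same canonicalisation as utree_splits (side without tip 1).
utree_key <- function(ut) {
  n <- ut$n
  if (n > 52L) return(paste(utree_splits(ut), collapse = ";"))
  if (n < 4L) return("")
  tr <- utree_traversal(ut)
  m <- length(ut$adj)
  below <- numeric(m)
  cnt <- integer(m)
  below[seq_len(n)] <- 2^(seq_len(n) - 1L)
  cnt[seq_len(n)] <- 1L
  keys <- numeric(0)
  total <- 2^n - 1
  for (v in tr$post) {
    kids <- tr$children[[v]]
    below[v] <- sum(below[kids])
    cnt[v] <- sum(cnt[kids])
    if (cnt[v] >= 2L && cnt[v] <= n - 2L) {
      side <- below[v]
      if (side %% 2 == 1) side <- total - side   # canonical: exclude tip 1
      keys <- c(keys, side)
    }
  }
  paste(sprintf("%.0f", sort(keys)), collapse = ",")
}

# Human-facing split label: the smaller side of the bipartition (ties broken
# lexicographically), "+"-joined.
canon_split_label <- function(idx, labels) {
  other <- setdiff(seq_along(labels), idx)
  a <- paste(sort(labels[idx]), collapse = "+")
  b <- paste(sort(labels[other]), collapse = "+")
  if (length(idx) < length(other)) a
  else if (length(other) < length(idx)) b
  else min(a, b)
}

# Map split signatures (tip-index based) to taxon-name based labels.
split_label <- function(key, labels) {
  idx <- as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])
  canon_split_label(idx, labels)
}

phylo_from_utree <- function(ut, root_tip = NULL) {
  n <- ut$n
  if (n == 1L)
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = ut$labels,
                          Nnode = 1L), class = "phylo"))
  if (n == 2L) {
    phy <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                          tip.label = ut$labels, Nnode = 1L), class = "phylo")
    return(phy)
  }
  tr <- utree_traversal(ut, if (is.null(root_tip)) 1L else root_tip)
  m <- length(ut$adj)
  # ape numbering: tips 1..n, internals n+1.. ; root gets n+1
  nint <- length(tr$post) + 1L            # +1 for the virtual root
  map <- integer(m + 1L)
  newid <- n + 1L                         # virtual root id
  edges <- matrix(0L, 0L, 2L)
  rt <- if (is.null(root_tip)) 1L else root_tip
  # assign ids in preorder
  pre <- rev(tr$post)
  ids <- integer(m)
  nxt <- n + 2L
  for (v in pre) { ids[v] <- nxt; nxt <- nxt + 1L }
  edge_list <- list()
  edge_list[[1L]] <- c(n + 1L, rt)
  edge_list[[2L]] <- c(n + 1L, if (tr$top <= n) tr$top else ids[tr$top])
  for (v in pre) {
    for (k in tr$children[[v]])
      edge_list[[length(edge_list) + 1L]] <- c(ids[v], if (k <= n) k else ids[k])
  }
  edge <- do.call(rbind, edge_list)
  structure(list(edge = edge, tip.label = ut$labels, Nnode = nint),
            class = "phylo")
}

# Uniform-random unrooted binary topology by sequential addition to a
# uniformly chosen edge (gives the uniform distribution on labelled
# topologies).
random_utree <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  stopifnot(n >= 3L)
  adj <- vector("list", 2L * n - 2L)
  v0 <- n + 1L
  adj[[v0]] <- c(1L, 2L, 3L)
  adj[[1L]] <- v0; adj[[2L]] <- v0; adj[[3L]] <- v0
  nxt <- n + 2L
  for (tip in seq_len(n)[-(1:3)]) {
    ed <- list()
    for (v in seq_len(nxt - 1L)) {
      for (w in adj[[v]]) if (v < w) ed[[length(ed) + 1L]] <- c(v, w)
    }
    e <- ed[[sample.int(length(ed), 1L)]]
    x <- nxt; nxt <- nxt + 1L
    adj[[e[1L]]] <- replace(adj[[e[1L]]], adj[[e[1L]]] == e[2L], x)
    adj[[e[2L]]] <- replace(adj[[e[2L]]], adj[[e[2L]]] == e[1L], x)
    adj[[x]] <- c(e[1L], e[2L], tip)
    adj[[tip]] <- x
  }
  utree(n, adj[seq_len(nxt - 1L)], labels)
}
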