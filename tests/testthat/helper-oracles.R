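# Independent oracles and fixture builders. These deliberately avoid the
# package's DP/traversal internals: parsimony length is computed by explicit
# enumeration of ancestral-state assignments over the phylo edge matrix.

# Minimum parsimony length of one character by brute force.
# col_sets: list (per tip, in tip.label order) of allowed integer states.
# ordered: additive (cost |i-j|) vs unordered (cost 0/1).
oracle_char_length <- function(phy, col_sets, ordered = FALSE) {
  n <- length(phy$tip.label)
  nodes <- sort(unique(phy$edge[phy$edge > n]))
  S <- sort(unique(unlist(col_sets)))
  cost <- function(a, b) if (ordered) abs(a - b) else as.numeric(a != b)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(S), length(nodes)))
  for (r in seq_len(nrow(grid))) {
    asn <- stats::setNames(as.integer(grid[r, ]), nodes)
    tot <- 0
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
      av <- asn[[as.character(a)]]
      if (b <= n) tot <- tot + min(vapply(col_sets[[b]], cost, 0, b = av))
      else tot <- tot + cost(av, asn[[as.character(b)]])
    }
    best <- min(best, tot)
  }
  as.integer(best)
}

# States each internal node can take in some minimum-length assignment.
oracle_mpr_sets <- function(phy, col_sets, ordered = FALSE) {
  n <- length(phy$tip.label)
  nodes <- sort(unique(phy$edge[phy$edge > n]))
  S <- sort(unique(unlist(col_sets)))
  cost <- function(a, b) if (ordered) abs(a - b) else as.numeric(a != b)
  grid <- do.call(expand.grid, rep(list(S), length(nodes)))
  tots <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    asn <- stats::setNames(as.integer(grid[r, ]), nodes)
    tot <- 0
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
      av <- asn[[as.character(a)]]
      if (b <= n) tot <- tot + min(vapply(col_sets[[b]], cost, 0, b = av))
      else tot <- tot + cost(av, asn[[as.character(b)]])
    }
    tots[r] <- tot
  }
  keep <- which(tots == min(tots))
  out <- lapply(seq_along(nodes), function(j) sort(unique(as.integer(grid[keep, j]))))
  names(out) <- nodes
  attr(out, "steps") <- as.integer(min(tots))
  out
}

# Column state-sets of a morph_matrix character, expanded the way scoring
# expands them (missing/inapplicable -> observed set).
expanded_column <- function(m, j) {
  col <- matrix_column(m, j)
  obs <- sort(unique(unlist(lapply(col, `[[`, "states"))))
  lapply(col, function(cell)
    if (cell$kind %in% c("missing", "inapp")) obs else cell$states)
}

# phangorn cross-check: parsimony length with an explicit cost matrix.
phangorn_char_length <- function(phy, col_sets, ordered = FALSE) {
  S <- sort(unique(unlist(col_sets)))
  ns <- length(S)
  tokens <- vapply(col_sets, function(s) paste(s, collapse = ""), "")
  contrast <- matrix(0, length(unique(tokens)), ns,
                     dimnames = list(unique(tokens), as.character(S)))
  for (tk in rownames(contrast))
    contrast[tk, as.character(as.integer(strsplit(tk, "")[[1L]]))] <- 1
  dat <- phangorn::phyDat(matrix(tokens, ncol = 1,
                                 dimnames = list(phy$tip.label, NULL)),
                          type = "USER", contrast = contrast)
  cost <- outer(S, S, function(a, b) if (ordered) abs(a - b) else (a != b) * 1)
  dimnames(cost) <- list(as.character(S), as.character(S))
  as.integer(phangorn::parsimony(phy, dat, method = "sankoff", cost = cost))
}

# Independent SPR neighbourhood on a binary unrooted phylo, written directly
# over newick strings: prune every tip / tip subset forming a clade is hard,
# so do it structurally: cut each edge, keep the fragment's own attachment
# point fixed, reattach the pruned part to every edge of the rest.
oracle_spr_neighbors <- function(phy) {
  edges_of <- function(adj, n) {
    res <- list()
    for (v in seq_along(adj)) for (w in adj[[v]]) if (v < w)
      res[[length(res) + 1L]] <- c(v, w)
    res
  }
  n <- length(phy$tip.label)
  # adjacency from edge matrix, root (degree-2) spliced
  m <- max(phy$edge)
  adj <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (v in seq_len(m)) if (v > n && length(adj[[v]]) == 2L) {
    nb <- adj[[v]]
    adj[[nb[1]]] <- replace(adj[[nb[1]]], adj[[nb[1]]] == v, nb[2])
    adj[[nb[2]]] <- replace(adj[[nb[2]]], adj[[nb[2]]] == v, nb[1])
    adj[[v]] <- integer(0)
  }
  key_of <- function(adj) {
    # canonical split key via recursive tip collection
    below <- function(v, p) {
      if (v <= n) return(v)
      sort(unlist(lapply(setdiff(adj2[[v]], p), below, p = v)))
    }
    adj2 <- adj
    keys <- character(0)
    for (v in seq_along(adj2)) for (w in adj2[[v]]) if (v < w && v > n && w > n) {
      s <- below(w, v)
      if (1 %in% s) s <- setdiff(seq_len(n), s)
      keys <- c(keys, paste(sort(s), collapse = "."))
    }
    paste(sort(keys), collapse = ";")
  }
  res <- list(); seen <- key_of(adj)
  for (e in edges_of(adj, n)) {
    for (dir in 1:2) {
      # prune the fragment hanging at `b` away from `a`
      a <- e[dir]; b <- e[3 - dir]
      adj1 <- adj
      adj1[[a]] <- setdiff(adj1[[a]], b)
      adj1[[b]] <- setdiff(adj1[[b]], a)
      # splice a if it became degree 2
      if (a > n && length(adj1[[a]]) == 2L) {
        nb <- adj1[[a]]
        adj1[[nb[1]]] <- replace(adj1[[nb[1]]], adj1[[nb[1]]] == a, nb[2])
        adj1[[nb[2]]] <- replace(adj1[[nb[2]]], adj1[[nb[2]]] == a, nb[1])
        adj1[[a]] <- integer(0)
      } else if (a <= n) next  # pruning all-but-one-leaf: skip, mirrored case
      # which nodes are in the pruned fragment?
      frag <- integer(0); stack <- b
      while (length(stack)) {
        x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        frag <- c(frag, x)
        stack <- c(stack, setdiff(adj1[[x]], frag))
      }
      # regraft b onto every edge of the remaining tree
      for (e2 in edges_of(adj1, n)) {
        if (e2[1] %in% frag || e2[2] %in% frag) next
        adj3 <- adj1
        x <- which(lengths(adj3) == 0L & seq_along(adj3) > n)[1]
        if (is.na(x)) { adj3[[length(adj3) + 1L]] <- integer(0); x <- length(adj3) }
        adj3[[e2[1]]] <- replace(adj3[[e2[1]]], adj3[[e2[1]]] == e2[2], x)
        adj3[[e2[2]]] <- replace(adj3[[e2[2]]], adj3[[e2[2]]] == e2[1], x)
        adj3[[x]] <- c(e2[1], e2[2], b)
        adj3[[b]] <- c(adj3[[b]], x)
        k <- key_of(adj3)
        if (k != seen && !k %in% names(res)) res[[k]] <- TRUE
      }
    }
  }
  names(res)
}

# Split-key set of a phylo, canonicalised the same way as
# oracle_spr_neighbors' key_of (tip indices in tip.label order).
oracle_tree_key <- function(phy) {
  n <- length(phy$tip.label)
  m <- max(phy$edge)
  adj <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (v in seq_len(m)) if (v > n && length(adj[[v]]) == 2L) {
    nb <- adj[[v]]
    adj[[nb[1]]] <- replace(adj[[nb[1]]], adj[[nb[1]]] == v, nb[2])
    adj[[nb[2]]] <- replace(adj[[nb[2]]], adj[[nb[2]]] == v, nb[1])
    adj[[v]] <- integer(0)
  }
  below <- function(v, p) {
    if (v <= n) return(v)
    sort(unlist(lapply(setdiff(adj[[v]], p), below, p = v)))
  }
  keys <- character(0)
  for (v in seq_along(adj)) for (w in adj[[v]]) if (v < w && v > n && w > n) {
    s <- below(w, v)
    if (1 %in% s) s <- setdiff(seq_len(n), s)
    keys <- c(keys, paste(sort(s), collapse = "."))
  }
  paste(sort(keys), collapse = ";")
}

# Random test matrix: n taxa, k characters, a few states, some missing /
# polymorphic cells. Deterministic given seed.
random_test_matrix <- function(n, k, seed, states = 2L, p_missing = 0.05,
                               p_poly = 0.03, p_ordered = 0) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n))
  cells <- lapply(seq_len(n), function(i)
    vapply(seq_len(k), function(j) {
      u <- runif(1)
      if (u < p_missing) "?"
      else if (u < p_missing + p_poly && states >= 2) {
        st <- sort(sample(0:(states - 1L), 2L))
        paste0("[", paste(st, collapse = ""), "]")
      } else as.character(sample(0:(states - 1L), 1L))
    }, ""))
  morph_matrix(taxa, cells, ordered = runif(k) < p_ordered)
}
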