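# Low-level tree operations on an adjacency-list representation: conversion
# to/from ape "phylo", NNI neighborhoods, topology enumeration for small n,
# and canonical Newick strings used for deterministic tie-breaking.

gkey <- function(u, v) paste0(pmin(u, v), ":", pmax(u, v))

graph_from_phylo <- function(tr) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  nbr <- vector("list", nn)
  len <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    nbr[[u]] <- c(nbr[[u]], v)
    nbr[[v]] <- c(nbr[[v]], u)
    len[gkey(u, v)] <- if (is.null(tr$edge.length)) NA_real_ else tr$edge.length[e]
  }
  list(nbr = nbr, len = len, ntip = ntip, labels = tr$tip.label)
}

# Build a phylo from the graph, rooted at an internal node (default: the
# internal node adjacent to tip 1). Tip ids 1..ntip are preserved, so
# tip.label order always matches g$labels.
graph_to_phylo <- function(g, root = NULL) {
  ntip <- g$ntip
  if (is.null(root)) root <- g$nbr[[1L]][1L]
  stopifnot(root > ntip)
  n_int <- sum(!vapply(g$nbr, is.null, logical(1L))) - ntip
  newid <- integer(length(g$nbr))
  newid[root] <- ntip + 1L
  next_int <- ntip + 2L
  stack <- list(c(root, 0L))
  # preorder DFS; assign new internal ids on first visit
  edges_p <- integer(2L * length(g$nbr)); edges_c <- integer(2L * length(g$nbr))
  edges_l <- numeric(2L * length(g$nbr)); ne <- 0L
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1L]; from <- top[2L]
    for (nb in g$nbr[[node]]) {
      if (nb == from) next
      if (nb > ntip && newid[nb] == 0L) { newid[nb] <- next_int; next_int <- next_int + 1L }
      ne <- ne + 1L
      edges_p[ne] <- newid[node]
      edges_c[ne] <- if (nb > ntip) newid[nb] else nb
      edges_l[ne] <- g$len[gkey(node, nb)]
      if (nb > ntip) stack[[length(stack) + 1L]] <- c(nb, node)
    }
  }
  tr <- list(edge = cbind(edges_p[seq_len(ne)], edges_c[seq_len(ne)]),
             tip.label = g$labels, Nnode = n_int)
  if (!all(is.na(edges_l[seq_len(ne)]))) tr$edge.length <- edges_l[seq_len(ne)]
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

graph_copy <- function(g) g  # lists copy on modify; explicit for clarity

# Remove edge (u,v) and its length
graph_drop_edge <- function(g, u, v) {
  g$nbr[[u]] <- g$nbr[[u]][g$nbr[[u]] != v]
  g$nbr[[v]] <- g$nbr[[v]][g$nbr[[v]] != u]
  g$len <- g$len[names(g$len) != gkey(u, v)]
  g
}

graph_add_edge <- function(g, u, v, len = NA_real_) {
  g$nbr[[u]] <- c(g$nbr[[u]], v)
  g$nbr[[v]] <- c(g$nbr[[v]], u)
  g$len[gkey(u, v)] <- len
  g
}

# Attach tip `tip` onto edge (u,v) through a fresh internal node `w`.
graph_insert_tip <- function(g, tip, u, v, w, tip_len = NA_real_) {
  old <- g$len[gkey(u, v)]
  g <- graph_drop_edge(g, u, v)
  g <- graph_add_edge(g, u, w, old / 2)
  g <- graph_add_edge(g, w, v, old / 2)
  graph_add_edge(g, w, tip, tip_len)
}

graph_edges <- function(g) {
  ek <- names(g$len)
  do.call(rbind, lapply(strsplit(ek, ":", fixed = TRUE), as.integer))
}

# All NNI neighbors of an unrooted binary tree. For each internal edge (u,v)
# with u-side subtrees {a,b} and v-side subtrees {c,d}, the two rearrangements
# swap b with c and b with d. Subtrees keep their stem lengths.
nni_neighbors <- function(tr) {
  g <- graph_from_phylo(tr)
  ntip <- g$ntip
  em <- graph_edges(g)
  internal <- em[em[, 1L] > ntip & em[, 2L] > ntip, , drop = FALSE]
  if (!nrow(internal)) return(list())
  internal <- internal[order(internal[, 1L], internal[, 2L]), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(internal))) {
    u <- internal[r, 1L]; v <- internal[r, 2L]
    ab <- sort(g$nbr[[u]][g$nbr[[u]] != v])
    cd <- sort(g$nbr[[v]][g$nbr[[v]] != u])
    if (length(ab) != 2L || length(cd) != 2L) next  # non-binary vertex
    b <- ab[2L]
    for (x in cd) {
      g2 <- g
      lb <- g2$len[gkey(u, b)]; lx <- g2$len[gkey(v, x)]
      g2 <- graph_drop_edge(g2, u, b)
      g2 <- graph_drop_edge(g2, v, x)
      g2 <- graph_add_edge(g2, u, x, lx)
      g2 <- graph_add_edge(g2, v, b, lb)
      out[[length(out) + 1L]] <- graph_to_phylo(g2)
    }
  }
  out
}

# Enumerate all unrooted binary topologies on the given labels (1x3x5x...
# trees; intended for <= 8 taxa). Returns phylo objects without branch
# lengths.
enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  if (n > 9L) stop("refusing to enumerate topologies for > 9 taxa")
  base <- list(nbr = c(lapply(1:3, function(i) n + 1L),
                       vector("list", 2L * n)),
               len = setNames(rep(NA_real_, 3), gkey(1:3, n + 1L)),
               ntip = n, labels = labels)
  base$nbr[[n + 1L]] <- 1:3
  trees <- list(base)
  if (n > 3L) {
    for (k in 4:n) {
      w <- n + (k - 2L)  # fresh internal id for this round
      nxt <- list()
      for (g in trees) {
        em <- graph_edges(g)
        for (r in seq_len(nrow(em))) {
          nxt[[length(nxt) + 1L]] <-
            graph_insert_tip(g, k, em[r, 1L], em[r, 2L], w)
        }
      }
      trees <- nxt
    }
  }
  lapply(trees, graph_to_phylo)
}

# Random unrooted binary topology by random stepwise addition (uses the
# current RNG stream).
random_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  ord <- sample.int(n)
  g <- list(nbr = vector("list", 2L * n), len = numeric(0), ntip = n,
            labels = labels)
  g$nbr[[ord[1L]]] <- n + 1L; g$nbr[[ord[2L]]] <- n + 1L; g$nbr[[ord[3L]]] <- n + 1L
  g$nbr[[n + 1L]] <- ord[1:3]
  g$len <- setNames(rep(NA_real_, 3), gkey(ord[1:3], n + 1L))
  if (n > 3L) {
    for (k in 4:n) {
      em <- graph_edges(g)
      r <- sample.int(nrow(em), 1L)
      g <- graph_insert_tip(g, ord[k], em[r, 1L], em[r, 2L], n + (k - 2L))
    }
  }
  graph_to_phylo(g)
}

# Canonical Newick string of an unrooted topology (no branch lengths):
# rooted at the lexicographically smallest label, subtrees sorted by their
# canonical strings. Equal strings <=> equal unrooted topologies.
canonical_newick <- function(tr) {
  g <- graph_from_phylo(tr)
  t0 <- order(g$labels)[1L]
  sub <- function(node, from) {
    if (node <= g$ntip) return(g$labels[node])
    kids <- sort(vapply(g$nbr[[node]][g$nbr[[node]] != from], sub,
                        character(1L), from = node))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0("(", g$labels[t0], ",", sub(g$nbr[[t0]][1L], t0), ");")
}

#' Test two trees for identical unrooted topology
#'
#' @param t1,t2 [ape::phylo] trees on the same label set.
#' @return Logical: do the trees induce the same bipartition set?
#' @export
topo_equal <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  setequal(names(tree_splits(t1)), names(tree_splits(t2)))
}
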