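# Neighbor joining (Saitou & Nei agglomeration) with the negative-branch
# convention: a negative pendant estimate is clamped to zero and its deficit
# moved to the sibling edge.

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a symmetric distance matrix. Exact on
#' additive distances (recovers the generating topology and branch lengths).
#' Negative branch-length estimates are clamped to 0 with the deficit shifted
#' to the sibling edge, preserving the pair's summed length.
#'
#' @param distance_matrix Symmetric numeric matrix with zero diagonal and
#'   row/column names; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  ntip <- n
  # graph built bottom-up; active nodes carry graph ids
  g <- list(nbr = vector("list", 2L * n), len = numeric(0), ntip = ntip,
            labels = labels)
  active_ids <- seq_len(n)
  next_internal <- ntip + 1L
  while (length(active_ids) > 3L) {
    m <- length(active_ids)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- ij[1L]; j <- ij[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    u <- next_internal; next_internal <- next_internal + 1L
    g <- graph_add_edge(g, u, active_ids[i], li)
    g <- graph_add_edge(g, u, active_ids[j], lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    active_ids <- c(active_ids[keep], u)
    rownames(d) <- colnames(d) <- as.character(active_ids)
  }
  # final 3-point formulas
  a <- d[1, 2]; b <- d[1, 3]; cc <- d[2, 3]
  l1 <- (a + b - cc) / 2; l2 <- (a + cc - b) / 2; l3 <- (b + cc - a) / 2
  u <- next_internal
  lens <- pmax(c(l1, l2, l3), 0)
  for (k in 1:3) g <- graph_add_edge(g, u, active_ids[k], lens[k])
  graph_to_phylo(g, root = u)
}
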