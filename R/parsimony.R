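# Fitch parsimony: bit-coded state sets, graph-level scoring, stepwise
# addition and NNI branch swapping, exhaustive search for small taxon sets.

# Bit codes: A=1, C=2, G=4, T=8; ambiguity codes are unions; gaps and '?'
# carry the full state set (missing data never adds changes).
.fitch_codes <- function() {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(ALN_ALPHABET, function(ch) sum(bits[IUPAC_MAP[[ch]]]), integer(1L))
}
FITCH_CODES <- .fitch_codes()

# Pattern-compressed integer codes for an alignment: list(codes = ntaxa x
# npat integer matrix ordered like the alignment rows, weights).
fitch_patterns <- function(alignment) {
  m <- unclass(alignment)
  keys <- do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  first <- !duplicated(keys)
  weights <- tabulate(match(keys, keys[first]), nbins = sum(first))
  codes <- matrix(FITCH_CODES[match(m[, first, drop = FALSE], ALN_ALPHABET)],
                  nrow = nrow(m))
  rownames(codes) <- rownames(m)
  list(codes = codes, weights = weights)
}

# Postorder directed edges of a graph, rooted at `root` (an internal node).
graph_postorder <- function(g, root) {
  stack <- list(c(root, 0L))
  out <- matrix(0L, 0L, 2L)
  ord <- integer(0); par <- integer(0)
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1L]; from <- top[2L]
    ord <- c(ord, node); par <- c(par, from)
    for (nb in g$nbr[[node]]) {
      if (nb != from) stack[[length(stack) + 1L]] <- c(nb, node)
    }
  }
  # reverse preorder = postorder
  cbind(parent = rev(par), child = rev(ord))[rev(par) != 0L, , drop = FALSE]
}

# Fitch score on a graph whose placed tips index rows of `codes` by tip id.
# Sequential set-intersection folding at each internal vertex; exact on
# binary trees (a trifurcating root is equivalent to rooting on its third
# edge).
fitch_graph <- function(g, codes, weights) {
  root <- NULL
  for (i in seq_len(g$ntip)) {
    if (!is.null(g$nbr[[i]])) { root <- g$nbr[[i]][1L]; break }
  }
  po <- graph_postorder(g, root)
  state <- vector("list", length(g$nbr))
  changes <- 0
  for (r in seq_len(nrow(po))) {
    pa <- po[r, 1L]; ch <- po[r, 2L]
    s_ch <- if (ch <= g$ntip) codes[ch, ] else state[[ch]]
    if (is.null(state[[pa]])) {
      state[[pa]] <- s_ch
    } else {
      inter <- bitwAnd(state[[pa]], s_ch)
      z <- inter == 0L
      if (any(z)) {
        changes <- changes + sum(weights[z])
        inter[z] <- bitwOr(state[[pa]][z], s_ch[z])
      }
      state[[pa]] <- inter
    }
  }
  changes
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over all sites under unit-cost (Fitch)
#' parsimony. Missing characters (`-`, `?`) and ambiguity codes contribute
#' their full compatible state set and thus never force a change on their own.
#'
#' @param tree A binary [ape::phylo] tree (rooted or unrooted) whose leaves
#'   match the alignment labels.
#' @param alignment An [aln()] object.
#' @return Integer parsimony length.
#' @export
fitch_score <- function(tree, alignment) {
  check_tree_aln(tree, alignment)
  fp <- fitch_patterns(alignment)
  g <- graph_from_phylo(tree)
  codes <- fp$codes[match(g$labels, rownames(fp$codes)), , drop = FALSE]
  fitch_graph(g, codes, fp$weights)
}

# Greedy random stepwise addition on pattern codes; returns a graph.
stepwise_addition <- function(labels, codes, weights, ord) {
  n <- length(labels)
  g <- list(nbr = vector("list", 2L * n), len = numeric(0), ntip = n,
            labels = labels)
  g$nbr[[ord[1L]]] <- n + 1L; g$nbr[[ord[2L]]] <- n + 1L; g$nbr[[ord[3L]]] <- n + 1L
  g$nbr[[n + 1L]] <- ord[1:3]
  g$len <- setNames(rep(NA_real_, 3L), gkey(ord[1:3], n + 1L))
  if (n >= 4L) {
    for (k in 4:n) {
      em <- graph_edges(g)
      scores <- vapply(seq_len(nrow(em)), function(r) {
        g2 <- graph_insert_tip(g, ord[k], em[r, 1L], em[r, 2L], n + (k - 2L))
        fitch_graph(g2, codes, weights)
      }, numeric(1L))
      r <- which.min(scores)  # first minimum: deterministic given the order
      g <- graph_insert_tip(g, ord[k], em[r, 1L], em[r, 2L], n + (k - 2L))
    }
  }
  g
}

#' Heuristic maximum-parsimony tree search
#'
#' For seven or fewer taxa the search is exhaustive over all unrooted binary
#' topologies. Otherwise, each replicate builds a tree by random-order greedy
#' stepwise addition and improves it by NNI branch swapping until no
#' rearrangement shortens the tree. Ties are broken by the lexicographically
#' smallest canonical Newick, so results are reproducible given the seed.
#'
#' @param alignment An [aln()] object with at least 4 taxa.
#' @param n_random_starts Number of random-addition replicates (default 10).
#' @param seed Integer seed controlling the random addition orders.
#' @return The best tree found (unrooted, no branch lengths) with attribute
#'   `"score"` (its parsimony length).
#' @export
parsimony_search <- function(alignment, n_random_starts = 10L, seed = 1L) {
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  labels <- rownames(alignment)
  n <- length(labels)
  if (n < 4L) stop("parsimony search needs at least 4 taxa")
  fp <- fitch_patterns(alignment)
  codes <- fp$codes; weights <- fp$weights
  if (n <= 7L) {
    trees <- enumerate_topologies(labels)
    scores <- vapply(trees, function(tr) {
      fitch_graph(graph_from_phylo(tr), codes, weights)
    }, numeric(1L))
    best <- which(scores == min(scores))
    keys <- vapply(trees[best], canonical_newick, character(1L))
    tr <- trees[[best[order(keys)[1L]]]]
    tr$edge.length <- NULL
    attr(tr, "score") <- min(scores)
    return(tr)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  best_tr <- NULL; best_score <- Inf; best_key <- NULL
  for (rep in seq_len(n_random_starts)) {
    ord <- sample.int(n)
    g <- stepwise_addition(labels, codes, weights, ord)
    tr <- graph_to_phylo(g)
    score <- fitch_graph(g, codes, weights)
    # NNI hill climbing: accept the best strict improvement each round
    repeat {
      cands <- nni_neighbors(tr)
      sc <- vapply(cands, function(ct) {
        fitch_graph(graph_from_phylo(ct), codes, weights)
      }, numeric(1L))
      if (!length(sc) || min(sc) >= score) break
      hits <- which(sc == min(sc))
      keys <- vapply(cands[hits], canonical_newick, character(1L))
      tr <- cands[[hits[order(keys)[1L]]]]
      score <- min(sc)
    }
    key <- canonical_newick(tr)
    if (score < best_score ||
        (score == best_score && key < best_key)) {
      best_tr <- tr; best_score <- score; best_key <- key
    }
  }
  best_tr$edge.length <- NULL
  attr(best_tr, "score") <- best_score
  best_tr
}
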