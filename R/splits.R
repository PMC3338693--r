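# Bipartition (split) utilities: canonical split sets with supports,
# majority-rule consensus built from compatible splits, and nonparametric
# bootstrap supports.

# Canonical key of a split side: the side NOT containing the reference taxon
# (the lexicographically smallest label of the universe), sorted and joined.
split_key <- function(side, universe) {
  ref <- sort(universe)[1L]
  if (ref %in% side) side <- setdiff(universe, side)
  paste(sort(side), collapse = "|")
}

#' Internal bipartitions of a tree
#'
#' Returns every non-trivial split (both sides with >= 2 taxa) of the tree in
#' canonical form, with the edge support where the tree carries numeric
#' `node.label` supports.
#'
#' @param tree An [ape::phylo].
#' @return A named list of splits; each element is a character vector (the
#'   canonical side), names are canonical keys, and the `"support"` attribute
#'   per element holds the edge support (`NA` when absent). Splits of a rooted
#'   binary tree's two root edges collapse to a single entry.
#' @export
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  labels <- tree$tip.label
  po <- stats::reorder(tree, "postorder")
  sup <- if (!is.null(tree$node.label)) suppressWarnings(as.numeric(tree$node.label)) else
    rep(NA_real_, tree$Nnode)
  # accumulate descendant tip sets bottom-up
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- labels[i]
  for (r in seq_len(nrow(po$edge))) {
    pa <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    tips_below[[pa]] <- c(tips_below[[pa]], tips_below[[ch]])
  }
  out <- list()
  for (r in seq_len(nrow(po$edge))) {
    ch <- po$edge[r, 2L]
    if (ch <= ntip) next
    side <- tips_below[[ch]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    key <- split_key(side, labels)
    s <- sup[ch - ntip]
    if (!is.null(out[[key]])) {
      old <- attr(out[[key]], "support")
      s <- if (is.na(old)) s else if (is.na(s)) old else max(old, s)
    }
    el <- sort(if (sort(labels)[1L] %in% side) setdiff(labels, side) else side)
    attr(el, "support") <- s
    out[[key]] <- el
  }
  out
}

#' Majority-rule consensus tree
#'
#' Retains every bipartition occurring in more than `cutoff` of the input
#' trees (strictly greater), annotating it with its observed frequency. The
#' retained splits are mutually compatible by construction for any
#' `cutoff >= 0.5`, and the consensus is assembled directly from them.
#'
#' @param trees A list of [ape::phylo] trees on an identical label set.
#' @param cutoff Retention threshold on the split frequency (default 0.5).
#' @return An unrooted consensus tree; numeric `node.label` holds the split
#'   frequencies (root label `NA`).
#' @export
majority_rule_consensus <- function(trees, cutoff = 0.5) {
  stopifnot(length(trees) >= 1L)
  labels <- trees[[1L]]$tip.label
  for (tr in trees) {
    if (!setequal(tr$tip.label, labels)) {
      stop("trees are not on the same label set")
    }
  }
  if (cutoff < 0.5) stop("cutoff below 0.5 can retain incompatible splits")
  tally <- split_frequencies(trees)
  keep <- tally$freq > cutoff
  build_tree_from_splits(labels, tally$side[keep], tally$freq[keep])
}

# Tally split frequencies over a tree list. Returns list(key, side, freq).
split_frequencies <- function(trees) {
  counts <- new.env(parent = emptyenv())
  sides <- new.env(parent = emptyenv())
  for (tr in trees) {
    sp <- tree_splits(tr)
    for (key in names(sp)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
      if (is.null(sides[[key]])) sides[[key]] <- as.character(sp[[key]])
    }
  }
  keys <- ls(counts)
  list(key = keys,
       side = lapply(keys, function(k) sides[[k]]),
       freq = vapply(keys, function(k) counts[[k]], numeric(1L)) / length(trees))
}

# Assemble an unrooted tree from mutually compatible splits. Sides are
# oriented away from the reference taxon, giving a nested clade family in the
# tree rooted at that taxon; the Newick is built recursively from maximal
# clades.
build_tree_from_splits <- function(labels, sides, freqs) {
  ref <- sort(labels)[1L]
  clades <- lapply(sides, function(s) if (ref %in% s) setdiff(labels, s) else s)
  freq_label <- function(i) formatC(freqs[i], format = "g", digits = 12)
  expand <- function(tipset, avail) {
    inside <- avail[vapply(avail, function(i) {
      length(clades[[i]]) < length(tipset) && all(clades[[i]] %in% tipset)
    }, logical(1L))]
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j) {
        j != i && length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]])
      }, logical(1L)))
    }, logical(1L))]
    parts <- vapply(maximal, function(i) {
      paste0("(", paste(expand(clades[[i]], setdiff(inside, i)), collapse = ","),
             ")", freq_label(i))
    }, character(1L))
    c(parts, setdiff(tipset, unlist(clades[maximal])))
  }
  txt <- paste0("(", ref, ",",
                paste(expand(setdiff(labels, ref), seq_along(clades)),
                      collapse = ","), ");")
  read_tree(txt)
}

#' Bootstrap support for a point-estimate tree
#'
#' Columns are resampled with replacement; a tree is inferred per replicate
#' by the requested method; the support of each internal edge of the
#' point-estimate tree is the fraction of replicate trees containing its
#' bipartition. Replicate seeds derive deterministically from the master
#' seed.
#'
#' @param alignment An [aln()] object.
#' @param method `"nj"` (neighbor joining on K2P distances), `"mp"`
#'   (parsimony search), or `"ml"` (NNI likelihood search from an NJ start).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Master integer seed.
#' @param model A [substitution_model()] (required for `method = "ml"`).
#' @param point_tree Optional point-estimate tree to annotate; default infers
#'   one from the full alignment with the same method.
#' @param keep_trees Return the replicate trees in attribute `"replicates"`?
#' @return The point-estimate tree with numeric `node.label` supports in
#'   `[0, 1]`.
#' @export
bootstrap_support <- function(alignment, method = c("nj", "mp", "ml"),
                              replicates = 100L, seed = 1L, model = NULL,
                              point_tree = NULL, keep_trees = FALSE) {
  method <- match.arg(method)
  stopifnot(replicates >= 1L)
  infer <- make_inferrer(method, model)
  if (is.null(point_tree)) point_tree <- infer(alignment, derive_seed(seed, 0L))
  m <- unclass(alignment)
  reps <- lapply(seq_len(replicates), function(b) {
    rep_seed <- derive_seed(seed, b)
    cols <- with_seed(rep_seed, sample.int(ncol(m), ncol(m), replace = TRUE))
    infer(aln(m[, cols, drop = FALSE]), rep_seed)
  })
  annotated <- annotate_supports(point_tree, reps)
  if (keep_trees) attr(annotated, "replicates") <- reps
  annotated
}

make_inferrer <- function(method, model = NULL) {
  switch(method,
    nj = function(a, seed) {
      d <- tryCatch(pairwise_distance_matrix(a, "k2p"),
                    error = function(e) pairwise_distance_matrix(a, "p_distance"))
      nj_tree(d)
    },
    mp = function(a, seed) parsimony_search(a, n_random_starts = 2L, seed = seed),
    ml = {
      if (is.null(model)) stop("method 'ml' requires a model")
      function(a, seed) {
        d <- tryCatch(pairwise_distance_matrix(a, "k2p"),
                      error = function(e) pairwise_distance_matrix(a, "p_distance"))
        start <- nj_tree(d)
        start$edge.length <- pmax(start$edge.length, 1e-6)
        nni_search(start, a, model)
      }
    }
  )
}

# Attach split frequencies from `trees` onto the internal nodes of `tree`.
annotate_supports <- function(tree, trees) {
  tally <- split_frequencies(trees)
  freq <- setNames(tally$freq, tally$key)
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  sup <- rep(NA_real_, tree$Nnode)
  for (r in seq_len(nrow(po$edge))) {
    pa <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    tips_below[[pa]] <- c(tips_below[[pa]], tips_below[[ch]])
    if (ch > ntip) {
      side <- tips_below[[ch]]
      if (length(side) >= 2L && length(side) <= ntip - 2L) {
        key <- split_key(side, tree$tip.label)
        f <- freq[key]
        sup[ch - ntip] <- if (is.na(f)) 0 else f
      }
    }
  }
  tree$node.label <- sup
  tree
}
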