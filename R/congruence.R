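# Gene-performance assessment: congruent-node scoring of per-gene trees
# against a reference (combined-data) tree, stratified by edge support, plus
# ranking and good/medium/poor classification.

#' Reference node set of a combined-data tree
#'
#' Enumerates the reference tree's internal bipartitions whose
#' outgroup-free side contains at least two ingroup taxa (and only ingroup
#' taxa), numbered in preorder. These are the "nodes" against which each
#' gene tree is scored. A user-supplied subset (e.g., a published numbered
#' node list) overrides the default.
#'
#' @param reference_tree An [ape::phylo] on the full taxon set.
#' @param outgroup Character vector of outgroup taxa (must be tips of the
#'   tree).
#' @param node_subset Optional list of character vectors, each an
#'   ingroup-taxon side defining one reference bipartition; must all exist in
#'   the tree. Given in scoring order.
#' @return An object of class `"ref_nodes"`: list with `reference_tree`,
#'   `outgroup`, `ingroup`, and `nodes` (named list `node_id -> ingroup
#'   side`).
#' @export
reference_nodes <- function(reference_tree, outgroup, node_subset = NULL) {
  labels <- reference_tree$tip.label
  miss <- setdiff(outgroup, labels)
  if (length(miss)) stop("outgroup taxa not in tree: ", paste(miss, collapse = ", "))
  ingroup <- setdiff(labels, outgroup)
  ntip <- length(labels)
  po <- stats::reorder(reference_tree, "postorder")
  tips_below <- vector("list", ntip + reference_tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- labels[i]
  for (r in seq_len(nrow(po$edge))) {
    tips_below[[po$edge[r, 1L]]] <- c(tips_below[[po$edge[r, 1L]]],
                                      tips_below[[po$edge[r, 2L]]])
  }
  # walk edges in preorder; keep non-trivial splits whose outgroup-free side
  # is >= 2 ingroup taxa
  pre <- stats::reorder(reference_tree, "cladewise")
  ingroup_sides <- list()
  seen <- character(0)
  for (r in seq_len(nrow(pre$edge))) {
    ch <- pre$edge[r, 2L]
    if (ch <= ntip) next
    below <- tips_below[[ch]]
    if (length(below) < 2L || length(below) > ntip - 2L) next
    side <- if (!any(below %in% outgroup)) below else {
      other <- setdiff(labels, below)
      if (!any(other %in% outgroup)) other else NULL
    }
    if (is.null(side) || length(side) < 2L) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    ingroup_sides[[length(ingroup_sides) + 1L]] <- side
  }
  if (!is.null(node_subset)) {
    have <- vapply(ingroup_sides, function(s) paste(sort(s), collapse = "|"),
                   character(1L))
    nodes <- lapply(node_subset, function(s) sort(as.character(s)))
    bad <- which(!vapply(nodes, function(s) paste(s, collapse = "|") %in% have,
                         logical(1L)))
    if (length(bad)) {
      stop("node_subset entry ", bad[1L], " is not a bipartition of the reference tree")
    }
  } else {
    nodes <- lapply(ingroup_sides, sort)
  }
  names(nodes) <- as.character(seq_along(nodes))
  structure(list(reference_tree = reference_tree, outgroup = outgroup,
                 ingroup = ingroup, nodes = nodes),
            class = "ref_nodes")
}

#' @export
print.ref_nodes <- function(x, ...) {
  cat(sprintf("Reference node set: %d nodes, %d ingroup / %d outgroup taxa\n",
              length(x$nodes), length(x$ingroup), length(x$outgroup)))
  for (id in names(x$nodes)) {
    cat(sprintf("  node %s: {%s}\n", id, paste(x$nodes[[id]], collapse = ", ")))
  }
  invisible(x)
}

#' Score one gene tree against the reference nodes
#'
#' A reference node is congruent when its bipartition, restricted to the taxa
#' shared between the gene tree and the reference, occurs among the gene
#' tree's bipartitions. Congruent nodes are stratified by the gene tree's own
#' support on the matching edge: strong (support >= `threshold`) versus weak
#' (below, or no support recorded).
#'
#' @param gene_tree An [ape::phylo], optionally with numeric `node.label`
#'   supports in `[0, 1]`. Must contain every ingroup taxon.
#' @param refs A [reference_nodes()] object.
#' @param threshold Support threshold for the strong stratum (default 0.95).
#' @param locus_name Name recorded in the result.
#' @return A one-row data.frame of class `"gene_performance"`: `locus`,
#'   `n_congruent_strong`, `n_congruent_weak`, `n_total`, and `recovered_ids`
#'   (comma-joined node ids).
#' @export
score_gene <- function(gene_tree, refs, threshold = 0.95, locus_name = "gene") {
  stopifnot(inherits(refs, "ref_nodes"))
  shared <- intersect(gene_tree$tip.label, refs$reference_tree$tip.label)
  missing_in <- setdiff(refs$ingroup, gene_tree$tip.label)
  if (length(missing_in)) {
    stop("gene tree is missing ingroup taxa: ", paste(missing_in, collapse = ", "))
  }
  gs <- tree_splits(gene_tree)
  # restrict gene splits to shared taxa
  restricted <- new.env(parent = emptyenv())
  for (s in gs) {
    side <- intersect(as.character(s), shared)
    if (length(side) < 2L || length(side) > length(shared) - 2L) next
    key <- split_key(side, shared)
    sup <- attr(s, "support")
    old <- restricted[[key]]
    restricted[[key]] <- if (is.null(old)) sup else {
      if (is.na(old)) sup else if (is.na(sup)) old else max(old, sup)
    }
  }
  strong <- 0L; weak <- 0L; recovered <- character(0)
  for (id in names(refs$nodes)) {
    side <- intersect(refs$nodes[[id]], shared)
    other <- setdiff(shared, side)
    if (length(side) < 2L || length(other) < 2L) next
    key <- split_key(side, shared)
    sup <- restricted[[key]]
    if (is.null(sup)) next
    recovered <- c(recovered, id)
    if (!is.na(sup) && sup >= threshold) strong <- strong + 1L else weak <- weak + 1L
  }
  out <- data.frame(locus = locus_name, n_congruent_strong = strong,
                    n_congruent_weak = weak, n_total = strong + weak,
                    recovered_ids = paste(recovered, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_performance", class(out))
  out
}

#' Rank genes by congruent-node counts
#'
#' Sorts loci by total congruent nodes (descending), then strong count
#' (descending), then locus name, and assigns good/medium/poor classes by
#' tertiles of the total, with ties sharing the better class.
#'
#' @param performances A list of [score_gene()] rows, or a data.frame binding
#'   them.
#' @param class_rule Classification rule; only `"tertile"` is implemented.
#' @return A data.frame sorted by rank with added columns `rank` and `class`.
#' @export
rank_genes <- function(performances, class_rule = c("tertile")) {
  class_rule <- match.arg(class_rule)
  tab <- if (is.data.frame(performances)) performances else
    do.call(rbind, performances)
  stopifnot(nrow(tab) >= 1L)
  ord <- order(-tab$n_total, -tab$n_congruent_strong, tab$locus)
  tab <- tab[ord, , drop = FALSE]
  n <- nrow(tab)
  third <- ceiling(n / 3)
  base <- rep(c("good", "medium", "poor"),
              c(third, min(third, n - third), max(n - 2L * third, 0L)))[seq_len(n)]
  # ties on the total share the better (earlier) class
  cls <- base
  for (i in seq_len(n)[-1L]) {
    if (tab$n_total[i] == tab$n_total[i - 1L] && cls[i] != cls[i - 1L]) {
      cls[i] <- cls[i - 1L]
    }
  }
  tab$rank <- seq_len(n)
  tab$class <- cls
  rownames(tab) <- NULL
  tab
}
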