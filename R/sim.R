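# Synthetic study generator: a species tree in coalescent units, gene trees
# sampled under the multispecies coalescent (with an optional introgression
# pulse), and sequence alignments evolved along them. Emulates a marker panel
# of many slow nuclear non-coding loci plus one fast, non-recombining
# mitochondrial partition across a rapid radiation.

#' Specify a species tree for simulation
#'
#' Branch lengths are in coalescent units (2N generations); the tree must be
#' rooted, binary and ultrametric (all tips contemporaneous). Per-branch rate
#' scalers multiply the substitution rate on that branch, letting lineages
#' evolve at unequal rates.
#'
#' @param topology A Newick string or [ape::phylo] with branch lengths in
#'   coalescent units.
#' @param rate_scalers Optional numeric vector of per-edge multipliers (> 0)
#'   in the tree's edge order; default all 1.
#' @return An object of class `"species_tree_spec"`.
#' @export
species_tree_spec <- function(topology, rate_scalers = NULL) {
  tr <- if (inherits(topology, "phylo")) topology else read_tree(topology)
  if (is.null(rate_scalers)) rate_scalers <- rep(1, nrow(tr$edge))
  structure(list(tree = tr, rate_scalers = rate_scalers),
            class = "species_tree_spec")
}

#' Validate and build the species tree
#'
#' @param spec A [species_tree_spec()].
#' @return The validated [ape::phylo] tree with attribute `"rate_scalers"`
#'   and all supports set to 1 (it is the true tree).
#' @export
build_species_tree <- function(spec) {
  stopifnot(inherits(spec, "species_tree_spec"))
  tr <- spec$tree
  if (anyDuplicated(tr$tip.label)) {
    stop(sprintf("duplicate taxon label: '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  }
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    stop("species tree must be rooted and binary")
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop("all internode lengths must be finite and >= 0")
  }
  if (length(spec$rate_scalers) != nrow(tr$edge) || any(spec$rate_scalers <= 0)) {
    stop("rate_scalers must be positive, one per edge")
  }
  node_times(tr)  # errors if not ultrametric
  tr$node.label <- rep(1, tr$Nnode)
  attr(tr, "rate_scalers") <- spec$rate_scalers
  tr
}

# Time (coalescent units before present) of every node; tips at 0. Errors if
# the tree is not ultrametric.
node_times <- function(tr) {
  ntip <- length(tr$tip.label)
  po <- stats::reorder(tr, "postorder")
  tt <- rep(NA_real_, ntip + tr$Nnode)
  tt[seq_len(ntip)] <- 0
  for (r in seq_len(nrow(po$edge))) {
    pa <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    t_pa <- tt[ch] + po$edge.length[r]
    if (!is.na(tt[pa]) && abs(tt[pa] - t_pa) > 1e-6) {
      stop("species tree must be ultrametric in coalescent units")
    }
    tt[pa] <- t_pa
  }
  tt
}

#' Specify an introgression pulse
#'
#' A single one-time gene-flow event: at `time` (coalescent units before the
#' present), each gene lineage then in the recipient branch is rerouted into
#' the donor branch with probability `proportion` (looking backwards in
#' time). Branches are identified by the tip set of the clade they subtend.
#'
#' @param donor,recipient Character vectors of tip labels; the branch is the
#'   edge above the MRCA of those tips.
#' @param time Event time in coalescent units before present.
#' @param proportion Fraction of lineages rerouted, in `[0, 1]`.
#' @return An object of class `"introgression_event"`.
#' @export
introgression_event <- function(donor, recipient, time, proportion) {
  if (proportion < 0 || proportion > 1) stop("proportion must be in [0, 1]")
  stopifnot(time >= 0)
  structure(list(donor = donor, recipient = recipient, time = time,
                 proportion = proportion), class = "introgression_event")
}

# Edge above the MRCA of `tips`; returns list(child, parent, t0, t1) with the
# time span the branch covers (t1 = Inf for the root stem).
edge_above_clade <- function(tr, tips, times) {
  miss <- setdiff(tips, tr$tip.label)
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  node <- if (length(tips) == 1L) match(tips, tr$tip.label) else
    ape::getMRCA(tr, tips)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  if (node == root) return(list(child = root, parent = 0L,
                                t0 = times[root], t1 = Inf))
  r <- which(tr$edge[, 2L] == node)
  list(child = node, parent = tr$edge[r, 1L], t0 = times[node],
       t1 = times[tr$edge[r, 1L]])
}

#' Sample a gene tree under the multispecies coalescent
#'
#' One haploid lineage is sampled per species. Within each species-tree
#' branch, the j extant lineages coalesce at exponential rate j(j-1)/2 per
#' coalescent time unit; surviving lineages move into the parent branch at
#' speciation times and everything coalesces above the root. With an
#' introgression event, lineages in the recipient branch at the event time
#' jump into the donor branch with the stated probability.
#'
#' @param species_tree A tree from [build_species_tree()] (coalescent units;
#'   optional `"rate_scalers"` attribute).
#' @param event Optional [introgression_event()].
#' @param seed Integer seed; the same seed reproduces the gene tree exactly.
#' @return An [ape::phylo] gene tree on the species labels with `edge.length`
#'   in coalescent units and component `subst.length`: the rate-scaler
#'   weighted lengths (coalescent units x per-branch scaler, to be multiplied
#'   by a per-locus rate to give substitutions/site).
#' @export
sample_gene_tree <- function(species_tree, event = NULL, seed = 1L) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  if (ntip == 1L) {
    out <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = tr$tip.label,
                Nnode = 1L, edge.length = 0, subst.length = 0)
    class(out) <- "phylo"
    return(out)
  }
  times <- node_times(tr)
  clade_sizes <- integer(ntip + tr$Nnode)
  clade_sizes[seq_len(ntip)] <- 1L
  po_edges <- stats::reorder(tr, "postorder")$edge
  for (r in seq_len(nrow(po_edges))) {
    clade_sizes[po_edges[r, 1L]] <- clade_sizes[po_edges[r, 1L]] +
      clade_sizes[po_edges[r, 2L]]
  }
  scalers <- attr(tr, "rate_scalers")
  if (is.null(scalers)) scalers <- rep(1, nrow(tr$edge))
  # population id = child node of the species edge; root population = 0
  pop_scaler <- c(setNames(scalers, tr$edge[, 2L]))
  root <- ntip + 1L
  ev <- NULL
  if (!is.null(event)) {
    stopifnot(inherits(event, "introgression_event"))
    don <- edge_above_clade(tr, event$donor, times)
    rec <- edge_above_clade(tr, event$recipient, times)
    if (event$time < don$t0 - 1e-9 || event$time >= don$t1 + 1e-9) {
      stop("donor branch does not exist at the event time")
    }
    if (event$time < rec$t0 - 1e-9 || event$time >= rec$t1 + 1e-9) {
      stop("recipient branch does not exist at the event time")
    }
    ev <- list(donor = don$child, recipient = rec$child, time = event$time,
               proportion = event$proportion)
  }

  with_seed(seed, {
    # lineage bookkeeping
    node_time <- c(rep(0, ntip), rep(NA_real_, ntip))  # grown as nodes appear
    acc <- numeric(2L * ntip)     # accrued scaler-weighted length per lineage
    kids <- list(); klen <- list(); kslen <- list()
    next_node <- ntip + 1L
    pops <- new.env(parent = emptyenv())
    for (i in seq_len(ntip)) {
      key <- as.character(i)
      pops[[key]] <- c(if (is.null(pops[[key]])) integer(0), i)
    }
    pop_key <- function(node) if (node == root) "0" else as.character(node)
    # reassign tips to their edges: population of tip i is edge with child i
    # (unless the species tree is a single tip)
    boundaries <- sort(unique(c(times[(ntip + 1L):(ntip + tr$Nnode)],
                                if (!is.null(ev)) ev$time)))
    coalesce_in <- function(key, t0, t1) {
      lin <- pops[[key]]
      if (is.null(lin) || length(lin) == 0L) return(invisible(NULL))
      sc <- if (key == "0") 1 else pop_scaler[[key]]
      last_t <- t0
      while (length(lin) >= 2L) {
        j <- length(lin)
        tcur <- last_t + rexp(1L, j * (j - 1) / 2)
        if (tcur > t1) break
        pick <- sample.int(j, 2L)
        a <- lin[pick[1L]]; b <- lin[pick[2L]]
        acc[lin] <<- acc[lin] + (tcur - last_t) * sc
        newid <- next_node
        next_node <<- next_node + 1L
        if (newid > length(node_time)) {
          node_time <<- c(node_time, rep(NA_real_, ntip))
          acc <<- c(acc, numeric(ntip))
        }
        node_time[newid] <<- tcur
        kids[[newid]] <<- c(a, b)
        klen[[newid]] <<- tcur - node_time[c(a, b)]
        kslen[[newid]] <<- acc[c(a, b)]
        acc[newid] <<- 0
        lin <- c(lin[-pick], newid)
        last_t <- tcur
      }
      acc[lin] <<- acc[lin] + (t1 - last_t) * sc
      pops[[key]] <- lin
      invisible(NULL)
    }

    t_prev <- 0
    for (tb in boundaries) {
      for (key in ls(pops)) coalesce_in(key, t_prev, tb)
      if (!is.null(ev) && abs(tb - ev$time) < 1e-12) {
        rk <- pop_key(ev$recipient); dk <- pop_key(ev$donor)
        lin <- pops[[rk]]
        if (!is.null(lin) && length(lin)) {
          move <- runif(length(lin)) < ev$proportion
          if (any(move)) {
            pops[[dk]] <- c(if (is.null(pops[[dk]])) integer(0) else pops[[dk]],
                            lin[move])
            pops[[rk]] <- lin[!move]
          }
        }
      }
      # merge populations whose parent node time is tb; with tied node times
      # (zero-length internodes) descendants must merge first
      tied <- (ntip + 1L):(ntip + tr$Nnode)
      tied <- tied[abs(times[tied] - tb) < 1e-12]
      tied <- tied[order(clade_sizes[tied])]
      for (nd in tied) {
        if (TRUE) {
          ch <- tr$edge[tr$edge[, 1L] == nd, 2L]
          merged <- integer(0)
          for (c1 in ch) {
            k <- as.character(c1)
            if (!is.null(pops[[k]])) { merged <- c(merged, pops[[k]]); rm(list = k, envir = pops) }
          }
          key <- pop_key(nd)
          pops[[key]] <- c(if (is.null(pops[[key]])) integer(0) else pops[[key]],
                           merged)
        }
      }
      t_prev <- tb
    }
    # above the root: coalesce to a single lineage
    key <- "0"
    lin <- pops[[key]]
    if (is.null(lin)) {  # single-population tree collapses here
      allk <- ls(pops)
      stopifnot(length(allk) == 1L)
      key <- allk; lin <- pops[[key]]
    }
    last_t <- t_prev
    while (length(lin) >= 2L) {
      j <- length(lin)
      tcur <- last_t + rexp(1L, j * (j - 1) / 2)
      pick <- sample.int(j, 2L)
      a <- lin[pick[1L]]; b <- lin[pick[2L]]
      acc[lin] <- acc[lin] + (tcur - last_t)
      newid <- next_node; next_node <- next_node + 1L
      if (newid > length(node_time)) {
        node_time <- c(node_time, rep(NA_real_, ntip))
        acc <- c(acc, numeric(ntip))
      }
      node_time[newid] <- tcur
      kids[[newid]] <- c(a, b)
      klen[[newid]] <- tcur - node_time[c(a, b)]
      kslen[[newid]] <- acc[c(a, b)]
      acc[newid] <- 0
      lin <- c(lin[-pick], newid)
      last_t <- tcur
    }
    build_gene_phylo(tr$tip.label, kids, klen, kslen, lin)
  })
}

# Assemble an ape phylo from the recorded coalescent nodes.
build_gene_phylo <- function(labels, kids, klen, kslen, root_id) {
  ntip <- length(labels)
  if (ntip == 1L) {
    stop("gene tree on a single taxon is a bare leaf; nothing to build")
  }
  n_int <- ntip - 1L
  newid <- integer(length(kids))
  # preorder DFS from root
  stack <- root_id
  order_int <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    order_int <- c(order_int, nd)
    for (k in kids[[nd]]) if (k > ntip) stack <- c(stack, k)
  }
  newid[order_int] <- ntip + seq_along(order_int)
  edges <- matrix(0L, 0L, 2L); el <- numeric(0); sl <- numeric(0)
  for (nd in order_int) {
    for (i in 1:2) {
      k <- kids[[nd]][i]
      edges <- rbind(edges, c(newid[nd], if (k > ntip) newid[k] else k))
      el <- c(el, klen[[nd]][i])
      sl <- c(sl, kslen[[nd]][i])
    }
  }
  tr <- list(edge = edges, tip.label = labels, Nnode = n_int,
             edge.length = el, subst.length = sl)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Simulate an alignment along a gene tree
#'
#' Root states are drawn from the model's base frequencies; each site evolves
#' independently down the tree with transition probabilities `P(t r)`, where
#' `t` is the branch length (expected substitutions/site) and `r` the site's
#' rate class (invariant class rate 0, or one of the discrete gamma rates).
#' Alignments are gap-free.
#'
#' @param gene_tree An [ape::phylo] with `edge.length` in expected
#'   substitutions per site.
#' @param model A [substitution_model()].
#' @param length Number of sites (> 0).
#' @param seed Integer seed.
#' @return An [aln()] of the tip sequences.
#' @export
simulate_alignment <- function(gene_tree, model, length, seed = 1L) {
  if (length <= 0) stop("alignment length must be positive")
  stopifnot(inherits(model, "submodel"))
  tr <- stats::reorder(gene_tree, "cladewise")  # parents before children
  ntip <- base::length(tr$tip.label)
  eig <- model_eigen(model)
  cls <- model_rate_classes(model)
  with_seed(seed, {
    site_class <- sample.int(base::length(cls$rates), length, replace = TRUE,
                             prob = cls$weights)
    states <- matrix(0L, ntip + tr$Nnode, length)
    root <- ntip + 1L
    states[root, ] <- sample.int(4L, length, replace = TRUE,
                                 prob = model$base_freqs)
    for (r in seq_len(nrow(tr$edge))) {
      pa <- tr$edge[r, 1L]; ch <- tr$edge[r, 2L]
      for (ci in seq_along(cls$rates)) {
        idx <- which(site_class == ci)
        if (!base::length(idx)) next
        t_eff <- tr$edge.length[r] * cls$rates[ci]
        if (t_eff == 0) { states[ch, idx] <- states[pa, idx]; next }
        P <- prob_matrix(eig, t_eff)
        for (s in 1:4) {
          sel <- idx[states[pa, idx] == s]
          if (base::length(sel)) {
            states[ch, sel] <- sample.int(4L, base::length(sel), replace = TRUE,
                                          prob = P[s, ])
          }
        }
      }
    }
    m <- matrix(ALN_STATES[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
    rownames(m) <- tr$tip.label
    aln(m)
  })
}
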