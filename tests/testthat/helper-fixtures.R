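# Shared fixtures and independent oracles used across the suite.

# Random gap-free alignment (uniform iid characters; optionally with missing
# data) -- used for property-style checks, not for realism.
rand_aln <- function(ntaxa, len, seed, p_missing = 0) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), ntaxa * len, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(ntaxa * len) < p_missing
      chars[miss] <- sample(c("-", "?", "N"), sum(miss), replace = TRUE)
    }
    m <- matrix(chars, nrow = ntaxa)
    rownames(m) <- paste0("t", seq_len(ntaxa))
    aln(m)
  })
}

# Random unrooted binary topology on n taxa with exponential branch lengths.
rand_tree <- function(ntaxa, seed, mean_bl = 0.1) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntaxa, rooted = FALSE, tip.label = paste0("t", seq_len(ntaxa)))
    tr$edge.length <- rexp(nrow(tr$edge), 1 / mean_bl)
    tr
  })
}

# Unit-cost Sankoff dynamic programming parsimony score: an independent
# oracle for the Fitch implementation. Missing/ambiguous characters allow
# every compatible state at cost 0.
sankoff_score <- function(tree, alignment) {
  m <- unclass(alignment)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  m <- m[tr$tip.label, , drop = FALSE]
  states <- c("A", "C", "G", "T")
  compat <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = states, "-" = states, "?" = states)
  total <- 0
  for (site in seq_len(ncol(m))) {
    cost <- matrix(Inf, ntip + tr$Nnode, 4L)
    for (i in seq_len(ntip)) cost[i, match(compat[[m[i, site]]], states)] <- 0
    done <- rep(FALSE, ntip + tr$Nnode)
    for (r in seq_len(nrow(tr$edge))) {
      pa <- tr$edge[r, 1L]; ch <- tr$edge[r, 2L]
      child_min <- vapply(1:4, function(s) {
        min(cost[ch, ] + (seq_len(4) != s))
      }, numeric(1L))
      if (!done[pa]) { cost[pa, ] <- child_min; done[pa] <- TRUE }
      else cost[pa, ] <- cost[pa, ] + child_min
    }
    total <- total + min(cost[ntip + 1L, ])
  }
  total
}

# Exhaustive likelihood by summing over all internal-state assignments:
# an enumeration oracle for the pruning algorithm (<= 5 taxa). Handles one
# rate class at a time and mixes classes with their weights.
enum_log_likelihood <- function(tree, alignment, model) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  m <- unclass(alignment)[tr$tip.label, , drop = FALSE]
  eig <- radsplit:::model_eigen(model)
  cls <- radsplit:::model_rate_classes(model)
  states <- c("A", "C", "G", "T")
  compat <- lapply(radsplit:::IUPAC_MAP, function(s) match(s, states))
  nint <- tr$Nnode
  grids <- as.matrix(expand.grid(rep(list(1:4), nint)))
  total <- 0
  site_lik <- matrix(0, ncol(m), length(cls$rates))
  for (ci in seq_along(cls$rates)) {
    P <- lapply(seq_len(nrow(tr$edge)), function(e) {
      radsplit:::prob_matrix(eig, tr$edge.length[e] * cls$rates[ci])
    })
    for (site in seq_len(ncol(m))) {
      tipsets <- lapply(seq_len(ntip), function(i) compat[[m[i, site]]])
      lik <- 0
      for (g in seq_len(nrow(grids))) {
        assign_state <- function(node) {
          if (node <= ntip) tipsets[[node]] else grids[g, node - ntip]
        }
        pr_root <- model$base_freqs[grids[g, 1L]]
        pr <- pr_root
        for (r in seq_len(nrow(tr$edge))) {
          pa <- assign_state(tr$edge[r, 1L])
          chs <- assign_state(tr$edge[r, 2L])
          pr <- pr * sum(P[[r]][pa, chs])
        }
        lik <- lik + pr
      }
      site_lik[site, ci] <- lik
    }
  }
  sum(log(site_lik %*% cls$weights))
}

# Brute-force bipartition frequency tally over a tree list, keyed the same
# way as the package's canonical split keys.
brute_split_freqs <- function(trees) {
  all_keys <- character(0)
  per_tree <- lapply(trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(idx) {
      side <- labs[idx]
      radsplit:::split_key(side, labs)
    }, character(1L))
    ntip <- length(labs)
    sizes <- lengths(pp)
    unique(keys[sizes >= 2L & sizes <= ntip - 2L])
  })
  tab <- table(unlist(per_tree))
  setNames(as.numeric(tab) / length(trees), names(tab))
}

# The default study's donor/recipient clades for introgression scenarios.
SEMNO <- c("Semnopithecus_entellus", "Semnopithecus_johnii",
           "Semnopithecus_vetulus")
TRACHY <- c("Trachypithecus_hatinhensis", "Trachypithecus_germaini",
            "Trachypithecus_shortridgei")
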