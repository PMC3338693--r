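# Maximum-likelihood machinery: Felsenstein pruning over site patterns (C++
# kernel), branch-length optimization, NNI hill-climbing, and AIC model
# selection over the JC69/K80/HKY85/GTR x {none, +I, +G} ladder.

# 0/1 compatibility masks for every alignment character (columns) over the
# four states (rows).
.aln_masks <- function() {
  M <- matrix(0, 4L, length(ALN_ALPHABET),
              dimnames = list(ALN_STATES, ALN_ALPHABET))
  for (ch in ALN_ALPHABET) M[IUPAC_MAP[[ch]], ch] <- 1
  M
}
ALN_MASKS <- .aln_masks()

# Pattern-compress an alignment in a fixed tip order. Returns tip partials
# (4 x npat x ntip), pattern weights, and the site -> pattern index map.
lik_patterns <- function(alignment, tip_order) {
  m <- unclass(alignment)[tip_order, , drop = FALSE]
  keys <- do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  weights <- tabulate(idx, nbins = sum(first))
  pm <- m[, first, drop = FALSE]
  npat <- ncol(pm)
  ntip <- nrow(pm)
  tp <- array(0, dim = c(4L, npat, ntip))
  for (i in seq_len(ntip)) tp[, , i] <- ALN_MASKS[, match(pm[i, ], ALN_ALPHABET)]
  list(tip_partials = tp, weights = weights, site_index = idx,
       npat = npat, ntip = ntip)
}

# Per-pattern likelihoods for a model on a postorder edge set.
pattern_lik <- function(pat, model, edge, lengths, nnode, root,
                        eig = model_eigen(model),
                        cls = model_rate_classes(model)) {
  L <- mix_lik_cpp(edge, pat$ntip, nnode, pat$tip_partials, eig$right,
                   eig$left, eig$vals, lengths, cls$rates, cls$weights,
                   model$base_freqs, root)
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("non-finite site likelihood encountered (underflow or invalid input)")
  }
  L
}

check_tree_aln <- function(tree, alignment) {
  if (!setequal(tree$tip.label, rownames(alignment))) {
    stop("tree leaves and alignment labels differ: ",
         paste(symdiff <- union(setdiff(tree$tip.label, rownames(alignment)),
                                setdiff(rownames(alignment), tree$tip.label)),
               collapse = ", "))
  }
  invisible(TRUE)
}

postorder_parts <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  if (is.null(po$edge.length) || anyNA(po$edge.length)) {
    stop("tree branch lengths must be known for likelihood computation")
  }
  if (any(po$edge.length < 0)) stop("negative branch length")
  list(edge = po$edge, lengths = po$edge.length,
       root = length(tree$tip.label) + 1L, nnode = tree$Nnode)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over compressed site patterns. Invariant sites enter as
#' a zero-rate class of weight `p_inv`; gamma rate variation as `n_categories`
#' equal-weight classes (rates rescaled so the overall mean rate is 1). Gaps,
#' `?`, and IUPAC ambiguity codes contribute a partial likelihood of 1 over
#' their compatible states.
#'
#' @param tree An [ape::phylo] with branch lengths in expected substitutions
#'   per site; leaf set must equal the alignment's labels. Rooted or unrooted.
#' @param alignment An [aln()] object.
#' @param model A [substitution_model()].
#' @return The total log-likelihood (finite scalar).
#' @export
log_likelihood <- function(tree, alignment, model) {
  check_tree_aln(tree, alignment)
  pp <- postorder_parts(tree)
  pat <- lik_patterns(alignment, tree$tip.label)
  L <- pattern_lik(pat, model, pp$edge, pp$lengths, pp$nnode, pp$root)
  sum(pat$weights * log(L))
}

#' Site-wise log-likelihoods
#'
#' Per-site log-likelihood vector; sums to [log_likelihood()] of the same
#' inputs. Used as the input of the RELL topology tests.
#'
#' @inheritParams log_likelihood
#' @return Numeric vector, one value per aligned column.
#' @export
sitewise_lnL <- function(tree, alignment, model) {
  check_tree_aln(tree, alignment)
  pp <- postorder_parts(tree)
  pat <- lik_patterns(alignment, tree$tip.label)
  L <- pattern_lik(pat, model, pp$edge, pp$lengths, pp$nnode, pp$root)
  log(L)[pat$site_index]
}

# Internal: lnL as a function of postorder branch lengths, with patterns
# computed once.
make_lnL_fun <- function(tree, alignment, model) {
  check_tree_aln(tree, alignment)
  po <- stats::reorder(tree, "postorder")
  pat <- lik_patterns(alignment, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  nnode <- tree$Nnode
  eig <- model_eigen(model)
  cls <- model_rate_classes(model)
  list(po = po,
       fn = function(lengths) {
         L <- pattern_lik(pat, model, po$edge, lengths, nnode, root,
                          eig = eig, cls = cls)
         sum(pat$weights * log(L))
       })
}

#' Optimize branch lengths by coordinate-wise search
#'
#' Each branch in turn is optimized by scalar (Brent) search on `[0, 10]`
#' substitutions/site, sweeping over all branches until the log-likelihood
#' improves by less than `tol`. The log-likelihood never decreases across
#' sweeps.
#'
#' @inheritParams log_likelihood
#' @param tol Stop when a full sweep improves lnL by less than this
#'   (default 1e-6).
#' @param max_sweeps Hard cap on sweeps.
#' @param init Starting value for branches with unknown (`NA`) length.
#' @param xtol Brent tolerance on each branch length (coarser is faster).
#' @return The tree with optimized `edge.length` and attribute `"lnL"`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, tol = 1e-6,
                                    max_sweeps = 20L, init = 0.1,
                                    xtol = 1e-6) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(init, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- init
  tree$edge.length <- pmin(pmax(tree$edge.length, 0), 10)
  mk <- make_lnL_fun(tree, alignment, model)
  po <- mk$po
  l <- po$edge.length
  cur <- mk$fn(l)
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_along(l)) {
      opt <- optimize(function(x) { l2 <- l; l2[e] <- x; mk$fn(l2) },
                      interval = c(0, 10), maximum = TRUE, tol = xtol)
      if (opt$objective > cur) { l[e] <- opt$maximum; cur <- opt$objective }
    }
    if (cur - prev < tol) break
  }
  # map optimized postorder lengths back onto the input edge order
  key_in <- paste(tree$edge[, 1L], tree$edge[, 2L])
  key_po <- paste(po$edge[, 1L], po$edge[, 2L])
  tree$edge.length <- l[match(key_in, key_po)]
  attr(tree, "lnL") <- cur
  tree
}

# One coarse sweep used when screening NNI candidates.
coarse_branch_sweep <- function(tree, alignment, model, n_sweeps = 1L) {
  optimize_branch_lengths(tree, alignment, model, tol = 1e-3,
                          max_sweeps = n_sweeps)
}

#' NNI hill-climbing search for the maximum-likelihood tree
#'
#' From a binary start tree, all nearest-neighbor-interchange rearrangements
#' of every internal edge are evaluated (each with branch-length
#' re-optimization); the best strictly improving rearrangement is accepted and
#' the process repeats until a local optimum or `max_rounds`. Ties are broken
#' by the lexicographically smallest canonical Newick, so the search is
#' deterministic.
#'
#' @inheritParams log_likelihood
#' @param start_tree Binary start tree (lengths optional; optimized first).
#' @param max_rounds Maximum accepted rearrangements.
#' @return The locally optimal tree with optimized lengths and attribute
#'   `"lnL"`.
#' @export
nni_search <- function(start_tree, alignment, model, max_rounds = 20L) {
  cur <- optimize_branch_lengths(start_tree, alignment, model)
  cur_lnL <- attr(cur, "lnL")
  small <- length(cur$tip.label) <= 8L
  for (round in seq_len(max_rounds)) {
    cands <- nni_neighbors(cur)
    if (!length(cands)) break
    cur_keys <- names(tree_splits(cur))
    best <- NULL; best_lnL <- cur_lnL; best_key <- NULL
    for (cand in cands) {
      cand$edge.length[is.na(cand$edge.length)] <- 0.05
      if (small) {
        sc <- optimize_branch_lengths(cand, alignment, model, tol = 1e-5,
                                      max_sweeps = 10L)
      } else {
        # only the central (rearranged) edge changes its bipartition: a
        # one-edge optimization screens candidates; the winner is fully
        # re-optimized below
        sc <- optimize_single_split_edge(cand, alignment, model, cur_keys)
      }
      lnL <- attr(sc, "lnL")
      if (lnL > best_lnL + 1e-8 ||
          (!is.null(best) && abs(lnL - best_lnL) <= 1e-8 &&
           canonical_newick(sc) < best_key)) {
        best <- sc; best_lnL <- lnL; best_key <- canonical_newick(sc)
      }
    }
    if (is.null(best)) break
    cand_opt <- optimize_branch_lengths(best, alignment, model)
    if (attr(cand_opt, "lnL") <= cur_lnL + 1e-8) break
    cur <- cand_opt
    cur_lnL <- attr(cur, "lnL")
  }
  attr(cur, "lnL") <- cur_lnL
  cur
}

# Optimize only the edge whose bipartition is new relative to `ref_keys`.
optimize_single_split_edge <- function(tree, alignment, model, ref_keys) {
  mk <- make_lnL_fun(tree, alignment, model)
  po <- mk$po
  l <- po$edge.length
  ntip <- length(tree$tip.label)
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  target <- NULL
  for (r in seq_len(nrow(po$edge))) {
    pa <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    tips_below[[pa]] <- c(tips_below[[pa]], tips_below[[ch]])
    if (ch > ntip) {
      side <- tips_below[[ch]]
      if (length(side) >= 2L && length(side) <= ntip - 2L &&
          !(split_key(side, tree$tip.label) %in% ref_keys)) {
        target <- r
      }
    }
  }
  if (is.null(target)) {
    cur <- mk$fn(l)
    attr(tree, "lnL") <- cur
    return(tree)
  }
  opt <- optimize(function(x) { l2 <- l; l2[target] <- x; mk$fn(l2) },
                  interval = c(0, 10), maximum = TRUE, tol = 1e-5)
  l[target] <- opt$maximum
  key_in <- paste(tree$edge[, 1L], tree$edge[, 2L])
  key_po <- paste(po$edge[, 1L], po$edge[, 2L])
  tree$edge.length <- l[match(key_in, key_po)]
  attr(tree, "lnL") <- opt$objective
  tree
}

MODEL_LADDER <- as.vector(outer(c("JC69", "K80", "HKY85", "GTR"),
                                c("", "+I", "+G"), paste0))

parse_model_spec <- function(id) {
  has_I <- grepl("\\+I", id)
  has_G <- grepl("\\+G", id)
  family <- sub("\\+.*$", "", id)
  if (!family %in% MODEL_FAMILIES) stop("unknown model family: ", family)
  list(family = family, has_I = has_I, has_G = has_G)
}

empirical_base_freqs <- function(alignment) {
  m <- unclass(alignment)
  counts <- vapply(ALN_STATES, function(s) sum(m == s), numeric(1L)) + 1
  counts / sum(counts)
}

# Transformed parameter vector <-> substitution model.
theta_init <- function(spec, emp_freqs) {
  th <- numeric(0)
  if (spec$family %in% c("HKY85", "TN93", "GTR")) {
    th <- c(th, log(emp_freqs[1:3] / emp_freqs[4]))
  }
  th <- c(th, switch(spec$family,
                     JC69 = numeric(0), K80 = log(2), HKY85 = log(2),
                     TN93 = c(log(2), log(2)),
                     GTR = rep(0, 5)))
  if (spec$has_I) th <- c(th, stats::qlogis(0.1))
  if (spec$has_G) th <- c(th, log(0.5))
  th
}

model_from_theta <- function(spec, theta) {
  i <- 0L
  freqs <- rep(0.25, 4)
  if (spec$family %in% c("HKY85", "TN93", "GTR")) {
    r <- exp(pmin(theta[i + 1:3], 30)); i <- i + 3L
    freqs <- c(r, 1) / (sum(r) + 1)
  }
  kappa <- 2; kappa1 <- 2; kappa2 <- 2; rates <- rep(1, 6)
  if (spec$family %in% c("K80", "HKY85")) { kappa <- exp(theta[i + 1L]); i <- i + 1L }
  if (spec$family == "TN93") {
    kappa1 <- exp(theta[i + 1L]); kappa2 <- exp(theta[i + 2L]); i <- i + 2L
  }
  if (spec$family == "GTR") {
    rates <- c(exp(pmin(theta[i + 1:5], 30)), 1); i <- i + 5L
  }
  p_inv <- 0
  if (spec$has_I) { p_inv <- stats::plogis(theta[i + 1L]) * 0.999; i <- i + 1L }
  alpha <- NULL
  if (spec$has_G) alpha <- max(exp(theta[i + 1L]), 1e-3)
  substitution_model(spec$family, base_freqs = freqs, kappa = kappa,
                     kappa1 = kappa1, kappa2 = kappa2, rates = rates,
                     p_inv = p_inv, alpha = alpha)
}

#' AIC model selection on a fixed base topology
#'
#' Each candidate model's free parameters (frequencies, exchangeabilities,
#' invariant proportion, gamma shape) are optimized by Nelder-Mead on a
#' transformed scale, alternating with branch-length re-optimization on the
#' fixed base topology. Candidates are ranked by AIC = 2k - 2 lnL, where k
#' counts substitution-model parameters.
#'
#' @param alignment An [aln()] object.
#' @param base_topology Fixed tree; default is the neighbor-joining tree on
#'   K2P distances (p-distances if K2P is saturated).
#' @param candidate_set Character vector of model ids; default is the
#'   twelve-model ladder `{JC69, K80, HKY85, GTR} x {none, +I, +G}`.
#' @return A list of fits sorted by AIC ascending, each with elements
#'   `model_id`, `lnL`, `n_params`, `aic`, `model` (fitted), `tree`
#'   (branch-length-optimized base topology). Class `"model_sel"`.
#' @export
select_model_aic <- function(alignment, base_topology = NULL,
                             candidate_set = MODEL_LADDER) {
  stopifnot(length(candidate_set) >= 1L)
  if (is.null(base_topology)) {
    d <- tryCatch(pairwise_distance_matrix(alignment, "k2p"),
                  error = function(e) pairwise_distance_matrix(alignment, "p_distance"))
    base_topology <- nj_tree(d)
    base_topology$edge.length <- pmax(base_topology$edge.length, 1e-6)
  }
  emp <- empirical_base_freqs(alignment)
  check_tree_aln(base_topology, alignment)
  po <- stats::reorder(base_topology, "postorder")
  pat <- lik_patterns(alignment, base_topology$tip.label)
  root <- length(base_topology$tip.label) + 1L
  nnode <- base_topology$Nnode
  lnL_of <- function(lengths, model, eig, cls) {
    sum(pat$weights * log(pattern_lik(pat, model, po$edge, lengths, nnode,
                                      root, eig = eig, cls = cls)))
  }
  sweep_lengths <- function(l, model, n_sweeps, tol, xtol) {
    eig <- model_eigen(model); cls <- model_rate_classes(model)
    cur <- lnL_of(l, model, eig, cls)
    for (s in seq_len(n_sweeps)) {
      prev <- cur
      for (e in seq_along(l)) {
        opt <- optimize(function(x) { l2 <- l; l2[e] <- x
                                      lnL_of(l2, model, eig, cls) },
                        interval = c(0, 10), maximum = TRUE, tol = xtol)
        if (opt$objective > cur) { l[e] <- opt$maximum; cur <- opt$objective }
      }
      if (cur - prev < tol) break
    }
    attr(l, "lnL") <- cur
    l
  }
  l <- po$edge.length
  if (is.null(l)) l <- rep(0.1, nrow(po$edge))
  l[is.na(l)] <- 0.1
  l <- pmin(pmax(l, 0), 10)
  fits <- vector("list", length(candidate_set))
  for (ci in seq_along(candidate_set)) {
    id <- candidate_set[ci]
    spec <- parse_model_spec(id)
    th <- theta_init(spec, emp)
    l <- sweep_lengths(l, model_from_theta(spec, th),
                       n_sweeps = if (ci == 1L) 3L else 1L, tol = 1e-3,
                       xtol = 1e-3)
    if (length(th)) {
      mkf <- function(theta) {
        m <- model_from_theta(spec, theta)
        -lnL_of(l, m, model_eigen(m), model_rate_classes(m))
      }
      run_optim <- function(th, maxit) {
        if (length(th) == 1L) {
          optim(th, mkf, method = "Brent", lower = -12, upper = 12)
        } else {
          optim(th, mkf, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-7))
        }
      }
      th <- run_optim(th, 300L)$par
      l <- sweep_lengths(l, model_from_theta(spec, th), 1L, 1e-3, 1e-3)
      th <- run_optim(th, 120L)$par
    }
    model <- model_from_theta(spec, th)
    l <- sweep_lengths(l, model, 3L, 1e-4, 1e-4)
    lnL <- attr(l, "lnL")
    tr <- base_topology
    key_in <- paste(tr$edge[, 1L], tr$edge[, 2L])
    key_po <- paste(po$edge[, 1L], po$edge[, 2L])
    tr$edge.length <- as.numeric(l)[match(key_in, key_po)]
    attr(tr, "lnL") <- lnL
    k <- model_n_params(model, has_inv = spec$has_I)
    fits[[ci]] <- list(model_id = id, lnL = lnL, n_params = k,
                       aic = 2 * k - 2 * lnL, model = model, tree = tr)
  }
  fits <- fits[order(vapply(fits, `[[`, numeric(1L), "aic"))]
  class(fits) <- "model_sel"
  fits
}

#' @export
print.model_sel <- function(x, ...) {
  tab <- data.frame(model = vapply(x, `[[`, character(1L), "model_id"),
                    lnL = vapply(x, `[[`, numeric(1L), "lnL"),
                    k = vapply(x, `[[`, numeric(1L), "n_params"),
                    AIC = vapply(x, `[[`, numeric(1L), "aic"))
  print(tab, row.names = FALSE)
  invisible(x)
}
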