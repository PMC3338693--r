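# Topology incongruence tests from site-wise log-likelihoods:
# Shimodaira-Hasegawa and Kishino-Hasegawa tests via RELL resampling.

#' Build a site log-likelihood matrix
#'
#' @param values A numeric matrix (sites x topologies) of per-site
#'   log-likelihoods, or a list of equal-length vectors.
#' @param topology_ids Column names; defaults to existing names or `T1`,
#'   `T2`, ...
#' @return A `"site_lnl"` matrix object.
#' @export
site_lnl_matrix <- function(values, topology_ids = NULL) {
  if (is.list(values)) values <- do.call(cbind, values)
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("need at least one site")
  if (any(!is.finite(values))) stop("site log-likelihoods must be finite")
  if (is.null(topology_ids)) {
    topology_ids <- colnames(values)
    if (is.null(topology_ids)) topology_ids <- paste0("T", seq_len(ncol(values)))
  }
  colnames(values) <- topology_ids
  structure(values, class = c("site_lnl", "matrix"))
}

# RELL replicate totals: B x ntopo matrix of resampled lnL sums, derived
# deterministically from the master seed.
rell_totals <- function(values, B, seed) {
  n <- nrow(values)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  tot <- matrix(0, B, ncol(values))
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    tot[b, ] <- as.numeric(w %*% values)
  }
  tot
}

#' Shimodaira-Hasegawa topology test (RELL)
#'
#' Compares candidate topologies by their total log-likelihoods with the
#' conservative simultaneous SH procedure: site indices are resampled with
#' replacement `B` times (RELL: no re-optimization); per replicate each
#' topology's resampled total is centered by its own mean across replicates;
#' the null statistic for a topology is the difference between the replicate
#' maximum of the centered totals and its own centered total; the p-value is
#' the fraction of replicates whose null statistic is at least the observed
#' delta (lnL of the best topology minus this topology's lnL). The
#' maximum-likelihood topology always has delta 0 and p = 1.
#'
#' @param matrix A [site_lnl_matrix()] (sites x topologies), at least two
#'   topologies.
#' @param B Number of RELL resamples (default 10000); fewer than 100 earns a
#'   warning.
#' @param seed Master seed.
#' @return A data.frame, one row per topology: `topology_id`, `lnL`, `delta`,
#'   `p_value`, `n_resamples`; best topology first.
#' @export
sh_test <- function(matrix, B = 10000L, seed = 1L) {
  m <- site_lnl_matrix(matrix)
  if (ncol(m) < 2L) stop("SH test needs at least 2 topologies")
  if (B < 1L) stop("B must be at least 1")
  if (B < 100L) warning("B < 100 gives unstable p-values")
  lnL <- colSums(m)
  delta <- max(lnL) - lnL
  tot <- rell_totals(unclass(m), B, seed)
  centered <- sweep(tot, 2L, colMeans(tot))
  rowmax <- do.call(pmax, as.data.frame(centered))
  p <- vapply(seq_len(ncol(m)), function(i) {
    mean((rowmax - centered[, i]) >= delta[i])
  }, numeric(1L))
  out <- data.frame(topology_id = colnames(m), lnL = lnL, delta = delta,
                    p_value = p, n_resamples = B, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$delta), , drop = FALSE]
}

#' Kishino-Hasegawa paired test (RELL, two-sided)
#'
#' For exactly two topologies: the observed total lnL difference is compared
#' with the RELL null distribution of the centered per-replicate differences;
#' the two-sided p-value is the fraction of replicates whose |centered
#' difference| is at least the observed |difference|. Symmetric under
#' swapping the two topologies.
#'
#' @inheritParams sh_test
#' @return A data.frame as in [sh_test()] with a shared two-sided `p_value`.
#' @export
kh_test <- function(matrix, B = 10000L, seed = 1L) {
  m <- site_lnl_matrix(matrix)
  if (ncol(m) != 2L) stop("KH test needs exactly 2 topologies")
  if (B < 1L) stop("B must be at least 1")
  if (B < 100L) warning("B < 100 gives unstable p-values")
  lnL <- colSums(m)
  obs <- lnL[1L] - lnL[2L]
  tot <- rell_totals(unclass(m), B, seed)
  diffs <- tot[, 1L] - tot[, 2L]
  p <- mean(abs(diffs - mean(diffs)) >= abs(obs))
  delta <- max(lnL) - lnL
  data.frame(topology_id = colnames(m), lnL = lnL, delta = delta,
             p_value = p, n_resamples = B, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Site log-likelihoods for a set of candidate topologies
#'
#' Convenience wrapper: optimizes branch lengths for each candidate topology
#' on the alignment under the given model and returns the site-wise
#' log-likelihood matrix ready for [sh_test()] / [kh_test()].
#'
#' @param alignment An [aln()] object.
#' @param trees Named list of candidate topologies.
#' @param model A [substitution_model()].
#' @return A [site_lnl_matrix()].
#' @export
topology_site_lnls <- function(alignment, trees, model) {
  if (is.null(names(trees))) names(trees) <- paste0("T", seq_along(trees))
  cols <- lapply(trees, function(tr) {
    tr <- optimize_branch_lengths(tr, alignment, model)
    sitewise_lnL(tr, alignment, model)
  })
  site_lnl_matrix(cols)
}
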