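# GTR-family substitution models with +I (invariant sites) and +G (discrete
# gamma among-site rate variation), and their transition-probability matrices.

MODEL_FAMILIES <- c("JC69", "K80", "HKY85", "TN93", "GTR")

#' Construct a substitution model
#'
#' Time-reversible nucleotide models on the state order A, C, G, T. The rate
#' matrix is `Q[i,j] = s[i,j] * pi[j]` with the six exchangeabilities `s`
#' constrained per family, scaled so the expected substitution rate at
#' stationarity is 1 (branch lengths are then expected substitutions per
#' site). `+I` adds a zero-rate class of weight `p_inv`; `+G` spreads the
#' remaining sites over `n_categories` equal-probability discrete-gamma rate
#' classes with shape `alpha`.
#'
#' @param family One of `"JC69"`, `"K80"`, `"HKY85"`, `"TN93"`, `"GTR"`.
#' @param base_freqs Stationary base frequencies (A, C, G, T); must sum to 1.
#'   Forced to 1/4 each for JC69 and K80.
#' @param kappa Transition/transversion rate ratio (K80, HKY85).
#' @param kappa1,kappa2 Purine (A-G) and pyrimidine (C-T) transition ratios
#'   (TN93).
#' @param rates Six exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (GTR; GT is the reference rate).
#' @param p_inv Proportion of invariant sites, in `[0, 1)`.
#' @param alpha Gamma shape; `NULL` means no gamma rate variation.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @return An object of class `"submodel"`.
#' @examples
#' substitution_model("HKY85", base_freqs = c(.3, .2, .2, .3), kappa = 4,
#'                    alpha = 0.7)
#' @export
substitution_model <- function(family = c("JC69", "K80", "HKY85", "TN93", "GTR"),
                               base_freqs = rep(0.25, 4), kappa = 2,
                               kappa1 = 2, kappa2 = 2,
                               rates = rep(1, 6), p_inv = 0, alpha = NULL,
                               n_categories = 4L) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) base_freqs <- rep(0.25, 4)
  stopifnot(length(base_freqs) == 4L, all(base_freqs > 0))
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  base_freqs <- base_freqs / sum(base_freqs)
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  ex <- switch(family,
    JC69 = rep(1, 6),
    K80 = c(1, kappa, 1, 1, kappa, 1),
    HKY85 = c(1, kappa, 1, 1, kappa, 1),
    TN93 = c(1, kappa1, 1, 1, kappa2, 1),
    GTR = rates
  )
  if (any(ex <= 0)) stop("exchangeabilities must be positive")
  structure(list(family = family, base_freqs = base_freqs,
                 exchangeabilities = ex, p_inv = p_inv, alpha = alpha,
                 n_categories = as.integer(n_categories)),
            class = "submodel")
}

#' @export
print.submodel <- function(x, ...) {
  cat(sprintf("%s model%s%s\n", x$family,
              if (x$p_inv > 0) sprintf(" +I (I=%.4g)", x$p_inv) else "",
              if (!is.null(x$alpha)) sprintf(" +G (alpha=%.4g, k=%d)",
                                             x$alpha, x$n_categories) else ""))
  cat("  base freqs:", sprintf("%.4f", x$base_freqs), "\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      sprintf("%.4g", x$exchangeabilities), "\n")
  invisible(x)
}

#' Model identifier string, e.g. "HKY85+I+G"
#' @param model A [substitution_model()].
#' @return Character scalar.
#' @export
model_id <- function(model) {
  paste0(model$family,
         if (model$p_inv > 0) "+I" else "",
         if (!is.null(model$alpha)) "+G" else "")
}

# Unscaled rate matrix from exchangeabilities and frequencies; then scaled so
# -sum_i pi_i Q_ii = 1 (mean rate one at stationarity).
model_Q <- function(model) {
  pi <- model$base_freqs
  s <- model$exchangeabilities  # AC AG AT CG CT GT
  Q <- matrix(0, 4, 4, dimnames = list(ALN_STATES, ALN_STATES))
  Q[1, 2] <- s[1] * pi[2]; Q[1, 3] <- s[2] * pi[3]; Q[1, 4] <- s[3] * pi[4]
  Q[2, 3] <- s[4] * pi[3]; Q[2, 4] <- s[5] * pi[4]
  Q[3, 4] <- s[6] * pi[4]
  Q[2, 1] <- s[1] * pi[1]; Q[3, 1] <- s[2] * pi[1]; Q[4, 1] <- s[3] * pi[1]
  Q[3, 2] <- s[4] * pi[2]; Q[4, 2] <- s[5] * pi[2]
  Q[4, 3] <- s[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigen-decomposition of the reversible Q via the symmetrized form; cached on
# the model between calls would be possible but construction is cheap.
model_eigen <- function(model) {
  Q <- model_Q(model)
  pi <- model$base_freqs
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(vals = e$values,
       right = diag(1 / sp) %*% e$vectors,   # columns: right eigenvectors of Q
       left = t(e$vectors) %*% diag(sp))     # rows: left eigenvectors
}

# P(t) for a set of branch length x rate products; returns 4 x 4 matrix.
prob_matrix <- function(eig, t) {
  P <- eig$right %*% (exp(eig$vals * t) * eig$left)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate categories
#'
#' Mean-of-category discretization of a Gamma(shape = alpha, rate = alpha)
#' distribution into `k` equal-probability bins: category i's rate is the
#' conditional mean of the distribution on its bin, computed from the
#' incomplete-gamma function. Rates are sorted ascending and average exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0); small values mean strong
#'   among-site rate heterogeneity.
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` relative rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k == 1L) return(1)
  cuts <- qgamma((0:k) / k, shape = alpha, rate = alpha)
  # E[X | bin] * P(bin)^-1 via the shape+1 incomplete gamma identity
  upper <- pgamma(cuts[-1L], shape = alpha + 1, rate = alpha)
  lower <- pgamma(cuts[-(k + 1L)], shape = alpha + 1, rate = alpha)
  r <- k * (upper - lower)
  sort(r / mean(r) * 1)  # renormalize exact mean 1 against rounding
}

# Site-rate classes for a model: rates and weights including the +I zero-rate
# class. Weights sum to 1.
model_rate_classes <- function(model) {
  if (is.null(model$alpha)) {
    rates <- 1
    weights <- 1
  } else {
    rates <- discrete_gamma_rates(model$alpha, model$n_categories)
    weights <- rep(1 / model$n_categories, model$n_categories)
  }
  if (model$p_inv > 0) {
    # Rescale so the overall mean rate stays 1 with the zero-rate class mixed in.
    rates <- rates / (1 - model$p_inv)
    rates <- c(0, rates)
    weights <- c(model$p_inv, (1 - model$p_inv) * weights)
  }
  list(rates = rates, weights = weights)
}

# Free-parameter count for AIC (substitution parameters only; branch lengths
# are shared across candidates fitted on the same fixed topology). `has_inv`
# marks a model whose invariant proportion was estimated, even if it landed
# on 0.
model_n_params <- function(model, has_inv = model$p_inv > 0) {
  n <- switch(model$family, JC69 = 0L, K80 = 1L, HKY85 = 4L, TN93 = 5L, GTR = 8L)
  if (has_inv) n <- n + 1L
  if (!is.null(model$alpha)) n <- n + 1L
  n
}
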