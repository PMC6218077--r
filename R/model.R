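#' Discrete gamma rate categories
#'
#' Splits a mean-one Gamma(shape = alpha, rate = alpha) distribution into `k`
#' equal-probability classes and returns the mean rate of each class
#' (the usual "+G" discretisation by class means, not medians). The mean of
#' the category rates is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` increasing rates with mean 1.
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  breaks <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # mean of X over a quantile class of Gamma(a, a) via the shape a+1 identity:
  # E[X ; X in (lo, hi)] = (F_{a+1}(hi) - F_{a+1}(lo))  (since E[X] = 1)
  cum <- pgamma(breaks, shape = alpha + 1, rate = alpha)
  rates <- diff(cum) * k
  rates / mean(rates)
}

#' GTR substitution model with discrete gamma rate variation
#'
#' Builds a time-reversible 4-state substitution model. The rate matrix is
#' scaled so that the expected substitution rate at equilibrium is 1, i.e.
#' branch lengths are in expected substitutions per site.
#'
#' @param rates Six symmetric exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT; the last is fixed to 1 (the vector is rescaled).
#' @param base_freqs Stationary base frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Gamma shape for among-site rate variation.
#' @param n_categories Number of discrete gamma categories.
#' @return An object of class `rh1_model` with the scaled rate matrix `Q`,
#'   its eigendecomposition, and the discretised `category_rates`.
#' @export
substitution_model <- function(rates = c(1, 1, 1, 1, 1, 1),
                               base_freqs = rep(0.25, 4),
                               gamma_shape = 1,
                               n_categories = 4L) {
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rates must be 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  }
  rates <- rates / rates[6L]
  if (length(base_freqs) != 4L || any(base_freqs <= 0)) {
    stop("base_freqs must be 4 positive frequencies")
  }
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- .nuc_letters

  R <- matrix(0, 4, 4, dimnames = list(.nuc_letters, .nuc_letters))
  R[1, 2] <- R[2, 1] <- rates[1]  # AC
  R[1, 3] <- R[3, 1] <- rates[2]  # AG
  R[1, 4] <- R[4, 1] <- rates[3]  # AT
  R[2, 3] <- R[3, 2] <- rates[4]  # CG
  R[2, 4] <- R[4, 2] <- rates[5]  # CT
  R[3, 4] <- R[4, 3] <- rates[6]  # GT
  Q <- R * rep(base_freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu

  # pi-symmetrised eigendecomposition: exact, reversible, and cheap to
  # exponentiate per branch/rate.
  sq <- sqrt(base_freqs)
  S <- Q * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  U <- eig$vectors / sq          # diag(1/sq) %*% V
  Uinv <- t(eig$vectors) * rep(sq, each = 4)  # t(V) %*% diag(sq)

  structure(
    list(rates = rates, base_freqs = base_freqs,
         gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
         category_rates = discretize_gamma(gamma_shape, n_categories),
         Q = Q, eigen_values = eig$values, U = U, Uinv = Uinv),
    class = "rh1_model")
}

#' @export
print.rh1_model <- function(x, ...) {
  cat("GTR+G substitution model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies:", paste(signif(x$base_freqs, 4), collapse = " "), "\n")
  cat(sprintf("  gamma shape %.4g with %d categories\n",
              x$gamma_shape, x$n_categories))
  invisible(x)
}

#' Transition probability matrix
#'
#' @param model An `rh1_model`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @param rate Rate multiplier (e.g. a gamma category rate).
#' @return 4x4 stochastic matrix `exp(Q * t * rate)`.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$U %*% (exp(model$eigen_values * t * rate) * model$Uinv)
  # clip tiny negative values from round-off
  P[P < 0] <- 0
  P
}

# Update category rates / eigensystem after changing parameters in place.
update_model <- function(model, rates = NULL, base_freqs = NULL,
                         gamma_shape = NULL) {
  substitution_model(
    rates = rates %||% model$rates,
    base_freqs = base_freqs %||% model$base_freqs,
    gamma_shape = gamma_shape %||% model$gamma_shape,
    n_categories = model$n_categories)
}
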