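#' Pointwise Bernoulli log-likelihood
#'
#' `x * log(p) + (1 - x) * log(1 - p)` for a dichotomous response.  A
#' degenerate probability that contradicts the observed response yields
#' `-Inf` (flagged by the caller, never an exception), matching the
#' convention used throughout the posterior computations.
#'
#' @param x 0/1 responses (vectorized).
#' @param p probabilities (recycled against `x`).
#' @return numeric vector of log-likelihood contributions.
#' @export
loglik_point <- function(x, p) {
  if (!all(x %in% c(0, 1))) stop("'x' must be 0/1")
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  ifelse(x == 1, log(p), log1p(-p))
}

#' Half-Cauchy density
#'
#' Density of the Cauchy(0, `scale`) distribution folded onto the positive
#' half-line, the prior used for the difficulty and shape scale parameters.
#' @param x nonnegative quantiles.
#' @param scale positive scale (default 5).
#' @param log return the log density?
#' @return density values; 0 (or `-Inf`) for negative `x`.
#' @export
dhalfcauchy <- function(x, scale = 5, log = FALSE) {
  out <- ifelse(x < 0, -Inf,
                log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
  if (log) out else exp(out)
}

# Truncated-normal log density, N(0, sd^2) restricted to (-1, Inf).
log_dtnorm <- function(x, sd) {
  ifelse(x <= -1, -Inf,
         stats::dnorm(x, 0, sd, log = TRUE) -
           stats::pnorm(-1 / sd, lower.tail = FALSE, log.p = TRUE))
}

#' Joint log prior density
#'
#' Log prior for the generalized-logit IRT parameter blocks:
#' `beta_j ~ N(0, sigma_beta^2)`, `lambda_{1j}, lambda_{2j} ~
#' N(0, sigma_lambda^2)` truncated to `(-1, Inf)` (with the correct
#' truncation normalizer), `theta_i ~ N(0, 1)`, and half-Cauchy(0, 5)
#' priors on both scales.  Any block absent from `params` contributes
#' nothing; values outside the support give `-Inf`.
#'
#' @param params list with any of the components `theta`, `beta`,
#'   `lambda1`, `lambda2`, `sigma_beta`, `sigma_lambda`.
#' @return scalar log prior density.
#' @export
log_prior <- function(params) {
  sb <- params$sigma_beta %||% 1
  sl <- params$sigma_lambda %||% 0.5
  if (sb <= 0 || sl <= 0) return(-Inf)
  lp <- 0
  if (!is.null(params$theta))
    lp <- lp + sum(stats::dnorm(params$theta, 0, 1, log = TRUE))
  if (!is.null(params$beta))
    lp <- lp + sum(stats::dnorm(params$beta, 0, sb, log = TRUE))
  for (blk in c("lambda1", "lambda2"))
    if (!is.null(params[[blk]]))
      lp <- lp + sum(log_dtnorm(params[[blk]], sl))
  if (!is.null(params$sigma_beta))
    lp <- lp + dhalfcauchy(params$sigma_beta, 5, log = TRUE)
  if (!is.null(params$sigma_lambda))
    lp <- lp + dhalfcauchy(params$sigma_lambda, 5, log = TRUE)
  lp
}

#' Unnormalized log posterior
#'
#' Sum of the observed-cell Bernoulli log-likelihood and [log_prior()].
#' Missing cells (`NA`) contribute nothing; `-Inf` from either term
#' propagates.
#'
#' @param params parameter list as in [log_prior()]; `theta` must have one
#'   entry per row of `responses` and `beta` (plus shapes) one per column.
#' @param responses integer matrix of 0/1 responses with `NA` for missing;
#'   may have zero rows/columns, in which case the prior alone is returned.
#' @param family model family (a generalized-logit variant).
#' @return scalar unnormalized log posterior.
#' @export
log_posterior_unnorm <- function(params, responses, family = "glogit_free") {
  responses <- as.matrix(responses)
  N <- nrow(responses); J <- ncol(responses)
  lp <- log_prior(params)
  if (!is.finite(lp) || N == 0L || J == 0L || all(is.na(responses)))
    return(lp)
  if (length(params$theta) != N || length(params$beta) != J)
    stop("parameter dimensions do not match the response matrix")
  l1 <- rep_len(params$lambda1 %||% 0, J)
  l2 <- rep_len(params$lambda2 %||% 0, J)
  ll <- 0
  for (j in seq_len(J)) {
    o <- !is.na(responses[, j])
    if (!any(o)) next
    p <- icc(family, params$theta[o],
             list(beta = params$beta[j], lambda1 = l1[j], lambda2 = l2[j]))
    ll <- ll + sum(loglik_point(responses[o, j], p))
  }
  lp + ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a
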