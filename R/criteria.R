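# Bayesian model-assessment criteria computed from the pointwise
# log-likelihood matrix (rows = retained draws, columns = observed cells).
# Reporting conventions: DIC, WAIC and LOO on the deviance scale (smaller
# is better); LPML as a log score (larger is better).

as_pointwise <- function(x) {
  if (inherits(x, "girt")) {
    if (is.null(x$pointwise))
      stop("fit was run with store_loglik = FALSE; pointwise matrix unavailable")
    return(x$pointwise)
  }
  as.matrix(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

col_log_mean_exp <- function(m) {
  apply(m, 2, function(x) log_sum_exp(x) - log(length(x)))
}

.dic_parts <- function(dev_draws, dev_plugin) {
  bad <- !is.finite(dev_draws)
  if (any(bad)) {
    warning(sum(bad), " draws with non-finite deviance excluded from DIC")
    dev_draws <- dev_draws[!bad]
  }
  dbar <- mean(dev_draws)
  p_dic <- dbar - dev_plugin
  c(dic = dbar + p_dic, p_dic = p_dic)
}

# Deviance at the plug-in parameter values: posterior means taken on the
# sampling (unconstrained-transform) scale and back-transformed, so means
# of truncated/positive parameters stay inside their support.
dev_at_plugin <- function(fit) {
  J <- fit$dims[["n_items"]]
  items <- data.frame(beta = colMeans(param_matrix(fit, "beta")))
  if (!is.null(fit$draws$lambda1)) {
    items$lambda1 <- expm1(colMeans(log1p(param_matrix(fit, "lambda1"))))
    items$lambda2 <- expm1(colMeans(log1p(param_matrix(fit, "lambda2"))))
  } else if (!is.null(fit$shape)) {
    items$lambda1 <- rep(fit$shape[1], J)
    items$lambda2 <- rep(fit$shape[2], J)
  }
  if (!is.null(fit$draws$alpha)) {
    items$alpha <- exp(colMeans(log(param_matrix(fit, "alpha"))))
    items$c <- colMeans(param_matrix(fit, "c"))
    items$d <- if (is.null(fit$draws$d)) rep(1, J)
               else colMeans(param_matrix(fit, "d"))
  }
  theta <- colMeans(param_matrix(fit, "theta"))
  fam <- eval_family(fit)
  dev <- 0
  for (j in seq_len(J)) {
    o <- !is.na(fit$data[, j])
    if (!any(o)) next
    p <- icc(fam, theta[o], as.list(items[j, ]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dev <- dev - 2 * sum(loglik_point(fit$data[o, j], p))
  }
  dev
}

#' Deviance information criterion
#'
#' Plug-in form: `Dbar` is the posterior mean deviance over retained
#' draws, `D(theta_bar)` the deviance at the posterior-mean parameters
#' (means taken on the unconstrained sampling scale and back-transformed),
#' `p_dic = Dbar - D(theta_bar)` and `DIC = Dbar + p_dic`.  Draws with
#' non-finite deviance are excluded with a warning.
#'
#' @param fit a [girt()] fit.
#' @return named numeric `c(dic = , p_dic = )`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "girt"))
  .dic_parts(fit$dev_draws, dev_at_plugin(fit))
}

#' Log pseudo-marginal likelihood
#'
#' The conditional predictive ordinate of cell `i` is the harmonic mean of
#' its likelihood over draws, `CPO_i = [S^{-1} \sum_s exp(-l_si)]^{-1}`,
#' evaluated stably in log space; `LPML = sum_i log CPO_i`.  Reported as a
#' log score: larger is better.
#'
#' @param x a [girt()] fit (with stored pointwise log-likelihood) or a
#'   draws x cells matrix of pointwise log-likelihoods.
#' @return scalar LPML; `-Inf` with a warning if some cell has zero
#'   likelihood in every draw.
#' @export
lpml <- function(x) {
  pw <- as_pointwise(x)
  if (nrow(pw) < 2L) stop("need at least 2 draws")
  log_cpo <- -apply(-pw, 2, function(z) log_sum_exp(z) - log(length(z)))
  if (any(!is.finite(log_cpo)))
    warning("cells with zero likelihood in all draws; LPML is -Inf")
  sum(log_cpo)
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(l_si)`, `p_waic = sum_i var_s(l_si)`
#' (sample variance, denominator S-1), `WAIC = -2 (lppd - p_waic)`.
#'
#' @inheritParams lpml
#' @return named numeric `c(waic = , p_waic = , lppd = )`.
#' @export
waic <- function(x) {
  pw <- as_pointwise(x)
  if (nrow(pw) < 2L) stop("need at least 2 draws")
  lppd_i <- col_log_mean_exp(pw)
  p_i <- apply(pw, 2, stats::var)
  c(waic = -2 * (sum(lppd_i) - sum(p_i)),
    p_waic = sum(p_i), lppd = sum(lppd_i))
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 empirical
# Bayes estimator, with the weak prior pulling k toward 0.5).
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  if (x[n] <= 0 || stats::sd(x) < 1e-12) return(c(k = NA_real_, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(t) -mean(log1p(-t * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j)); w <- w / sum(w)
  th <- sum(theta * w)
  k <- -mean(log1p(-th * x))
  sigma <- k / th
  k <- (n * k + 10 * 0.5) / (n + 10)
  c(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) sigma * -expm1(k * log1p(-p)) / k

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Importance ratios `r_si = exp(-l_si)` are tail-smoothed per cell by a
#' generalized-Pareto fit to the largest 20% of ratios (PSIS); the
#' smoothed weights give `elpd_loo_i = log(sum_s w_si exp(l_si) /
#' sum_s w_si)`.  LOO is reported on the deviance scale,
#' `-2 sum_i elpd_loo_i`, so that smaller is better, and the per-cell
#' Pareto shape diagnostics are returned (values above ~0.7 indicate an
#' unreliable cell).  With fewer than 100 draws the tail is too short to
#' smooth and plain importance sampling is used with a warning.
#'
#' @inheritParams lpml
#' @return list with `loo` (deviance scale), `elpd_loo`, `pareto_k`
#'   (per-cell; `NA` where the tail is degenerate, e.g. constant
#'   likelihood) and `pareto_k_max`.
#' @export
loo_psis <- function(x) {
  pw <- as_pointwise(x)
  S <- nrow(pw)
  if (S < 2L) stop("need at least 2 draws")
  smooth <- S >= 100L
  if (!smooth)
    warning("fewer than 100 draws: returning unsmoothed importance sampling")
  tail_len <- ceiling(0.2 * S)
  res <- apply(pw, 2, function(l) {
    lw <- -l                      # log importance ratios, up to a constant
    lw <- lw - max(lw)
    k <- NA_real_
    if (smooth) {
      ord <- order(lw)
      tail_ids <- ord[(S - tail_len + 1L):S]
      cutoff <- lw[ord[S - tail_len]]
      exceed <- exp(lw[tail_ids]) - exp(cutoff)
      fit <- gpd_fit(exceed)
      if (is.finite(fit["k"])) {
        k <- unname(fit["k"])
        qq <- qgpd((seq_len(tail_len) - 0.5) / tail_len, fit["k"], fit["sigma"])
        sm <- log(exp(cutoff) + qq)
        sm <- pmin(sm, max(lw))
        lw[tail_ids[order(lw[tail_ids])]] <- sort(sm)
      }
    }
    elpd <- log_sum_exp(lw + l) - log_sum_exp(lw)
    c(elpd, k)
  })
  elpd_loo <- res[1, ]
  pareto_k <- res[2, ]
  list(loo = -2 * sum(elpd_loo), elpd_loo = elpd_loo,
       pareto_k = pareto_k,
       pareto_k_max = if (all(is.na(pareto_k))) NA_real_
                      else max(pareto_k, na.rm = TRUE))
}

#' All four model-comparison criteria for a fit
#'
#' One-row data frame with DIC (and its effective-parameter count), LPML,
#' WAIC (and p_waic), PSIS-LOO on the deviance scale, and the maximum
#' Pareto-k diagnostic — the layout used in the model-comparison tables.
#' DIC/WAIC/LOO are minimized, LPML maximized.
#'
#' @param fit a [girt()] fit with stored pointwise log-likelihood.
#' @return data.frame with columns dic, p_dic, lpml, waic, p_waic, loo,
#'   pareto_k_max.
#' @export
criteria_report <- function(fit) {
  d <- dic(fit)
  w <- waic(fit)
  l <- loo_psis(fit)
  data.frame(dic = unname(d["dic"]), p_dic = unname(d["p_dic"]),
             lpml = lpml(fit),
             waic = unname(w["waic"]), p_waic = unname(w["p_waic"]),
             loo = l$loo, pareto_k_max = l$pareto_k_max)
}
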