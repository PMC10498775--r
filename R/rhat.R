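#' Split-chain potential scale reduction factor
#'
#' Classic (non-rank-normalized) split R-hat: each chain is halved, and
#' the Brooks–Gelman between/within variance ratio is computed over the
#' resulting half-chains,
#' \deqn{\hat R = \sqrt{\frac{(L-1)/L\, W + B/L}{W}},}
#' where `L` is the half-chain length, `W` the mean within-half variance
#' and `B` the between-half variance of the means.  Values near 1 indicate
#' convergence; the simulation studies use the conventional 1.05 cutoff.
#' Chains with zero total variance (degenerate draws) return 1.
#'
#' @param x iterations x chains matrix of draws for one scalar parameter.
#' @return scalar R-hat.
#' @export
rhat_split <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 chains for R-hat")
  if (nrow(x) < 4L) stop("need at least 4 retained iterations per chain")
  L <- nrow(x) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch)
    cbind(x[seq_len(L), ch], x[L + seq_len(L), ch])))
  m <- ncol(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- L * stats::var(colMeans(halves))
  if (!is.finite(W) || W <= 0) {
    if (isTRUE(all.equal(min(halves), max(halves)))) return(1)
    return(Inf)
  }
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' R-hat for every sampled parameter of a fit
#'
#' @param fit a [girt()] fit (or any list with a `draws` component of
#'   iteration x chain x parameter arrays).
#' @return named numeric vector of split R-hat values.  With a single
#'   chain, R-hat is undefined and a vector of `NA` is returned with a
#'   warning.
#' @export
compute_rhat <- function(fit) {
  draws <- fit$draws
  nm <- unlist(lapply(names(draws), function(b)
    param_names(b, dim(draws[[b]])[3])), use.names = FALSE)
  if (dim(draws[[1]])[2] < 2L) {
    warning("R-hat requires at least 2 chains")
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  out <- unlist(lapply(names(draws), function(b) {
    a <- draws[[b]]
    vapply(seq_len(dim(a)[3]), function(k) rhat_split(a[, , k]), numeric(1))
  }), use.names = FALSE)
  stats::setNames(out, nm)
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass, computed from the
#' pooled draws (empirical-quantile window method).
#' @param x numeric draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
hpdi <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  lo <- seq_len(n - k)
  w <- x[lo + k] - x[lo]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Posterior summary table
#'
#' Per-parameter posterior mean (the point estimate used throughout the
#' recovery studies), posterior SD, highest-posterior-density interval of
#' the requested mass, and split R-hat — the layout used for real-data
#' item reporting.
#'
#' @param fit a [girt()] fit.
#' @param mass HPDI mass, default 0.95.
#' @param pars parameter blocks to include; default is every item-level
#'   block plus the scales (`"all"` adds the abilities `theta`).
#' @return data.frame with columns parameter, Estimate, SD, HPDI_lower,
#'   HPDI_upper, Rhat.
#' @export
posterior_summary <- function(fit, mass = 0.95, pars = NULL) {
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)")
  blocks <- names(fit$draws)
  if (is.null(pars)) blocks <- setdiff(blocks, "theta")
  else if (identical(pars, "all")) blocks <- blocks
  else blocks <- intersect(pars, blocks)
  rows <- lapply(blocks, function(b) {
    m <- param_matrix(fit, b)
    t(vapply(seq_len(ncol(m)), function(k) {
      x <- m[, k]
      h <- hpdi(x, mass)
      c(mean(x), stats::sd(x), h[1], h[2])
    }, numeric(4)))
  })
  tab <- do.call(rbind, rows)
  nm <- unlist(lapply(blocks, function(b)
    param_names(b, dim(fit$draws[[b]])[3])), use.names = FALSE)
  out <- data.frame(parameter = nm, Estimate = tab[, 1], SD = tab[, 2],
                    HPDI_lower = tab[, 3], HPDI_upper = tab[, 4],
                    Rhat = unname(fit$rhat[nm]))
  rownames(out) <- NULL
  out
}
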