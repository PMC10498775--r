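# Parameter-recovery accuracy criteria across replications.

#' Recovery criteria for a single parameter
#'
#' Given the point estimates of one parameter across `R` replications, its
#' true value, and the posterior SDs from each replication:
#' `bias = mean(est - truth)`, `mse = mean((est - truth)^2)` (mean squared
#' error — the tabulated criterion satisfies the exact decomposition
#' `mse = se^2 + bias^2`; the root form is available via [rmse()]),
#' `se = sqrt(mean((est - mean(est))^2))` (replication SD, population
#' denominator), `sd = mean(posterior_sds)`.
#'
#' @param estimates numeric vector of length R (posterior means).
#' @param truth scalar true value.
#' @param posterior_sds numeric vector of length R.
#' @return named numeric `c(bias, mse, se, sd)`.
#' @export
recovery_for_parameter <- function(estimates, truth, posterior_sds) {
  R <- length(estimates)
  if (R < 1L) stop("need at least one replication")
  stopifnot(length(posterior_sds) == R, length(truth) == 1L)
  err <- estimates - truth
  c(bias = mean(err),
    mse = mean(err^2),
    se = sqrt(mean((estimates - mean(estimates))^2)),
    sd = mean(posterior_sds))
}

#' Root mean squared error accessor
#' @param recovery a vector or table containing an `mse` component.
#' @return `sqrt(mse)`.
#' @export
rmse <- function(recovery) {
  if (is.null(dim(recovery))) sqrt(recovery[["mse"]])
  else sqrt(recovery[, "mse"])
}

#' Average recovery criteria over a parameter block
#'
#' Arithmetic mean of each criterion across the items of a block (or the
#' persons, for the abilities — the same formulas applied symmetrically).
#'
#' @param block_results matrix with one row per parameter and columns
#'   bias/mse/se/sd (as produced by stacking [recovery_for_parameter()]).
#' @return named numeric with the four averaged criteria.
#' @export
average_recovery <- function(block_results) {
  block_results <- rbind(block_results)
  if (nrow(block_results) < 1L) stop("empty block")
  colMeans(block_results[, c("bias", "mse", "se", "sd"), drop = FALSE])
}
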