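# S3 methods for "girt" fits.

# Posterior-mean item parameters on the natural scale, one row per item,
# with the fixed link constants filled in for the fixed-shape families.
plugin_items <- function(fit) {
  J <- fit$dims[["n_items"]]
  out <- data.frame(beta = colMeans(param_matrix(fit, "beta")))
  if (!is.null(fit$draws$lambda1)) {
    out$lambda1 <- colMeans(param_matrix(fit, "lambda1"))
    out$lambda2 <- colMeans(param_matrix(fit, "lambda2"))
  } else if (!is.null(fit$shape)) {
    out$lambda1 <- rep(fit$shape[1], J)
    out$lambda2 <- rep(fit$shape[2], J)
  }
  if (!is.null(fit$draws$alpha)) {
    out$alpha <- colMeans(param_matrix(fit, "alpha"))
    out$c <- colMeans(param_matrix(fit, "c"))
    out$d <- if (is.null(fit$draws$d)) rep(1, J)
             else colMeans(param_matrix(fit, "d"))
  }
  rownames(out) <- colnames(fit$data) %||% paste0("I", seq_len(J))
  out
}

# Family string under which plug-in items evaluate with icc().
eval_family <- function(fit) {
  switch(fit$family,
         rasch = , pno_glogit = , cllm_glogit = , glogit_free = "glogit_free",
         fit$family)
}

#' @export
print.girt <- function(x, ...) {
  cat("Bayesian one-parameter IRT fit (family: ", x$family, ")\n", sep = "")
  cat(sprintf("  %d persons x %d items, %d observed responses\n",
              x$dims[["n_persons"]], x$dims[["n_items"]],
              length(x$obs_index)))
  cat(sprintf("  %d chains x %d iterations (%d burn-in), %d retained draws\n",
              x$config$chains, x$config$iter, x$config$burnin,
              length(x$dev_draws)))
  if (!anyNA(x$rhat))
    cat(sprintf("  max split R-hat: %.3f\n", max(x$rhat)))
  cat(sprintf("  sampling time: %.1f s\n", x$time))
  invisible(x)
}

#' @export
summary.girt <- function(object, mass = 0.95, pars = NULL, ...) {
  out <- list(family = object$family,
              table = posterior_summary(object, mass = mass, pars = pars),
              mass = mass, dims = object$dims)
  class(out) <- "summary.girt"
  out
}

#' @export
print.summary.girt <- function(x, digits = 4, ...) {
  cat("Posterior summary (family: ", x$family, ")\n", sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.girt <- function(object, ...) {
  out <- as.matrix(plugin_items(object))
  for (s in c("sigma_beta", "sigma_lambda"))
    if (!is.null(object$draws[[s]]))
      attr(out, s) <- mean(param_matrix(object, s))
  out
}

#' Posterior-mean response probabilities on an ability grid
#'
#' Evaluates each item's characteristic curve at the supplied abilities
#' using the posterior-mean item parameters (plug-in ICC).
#' @param object a [girt()] fit.
#' @param newtheta ability grid.
#' @param ... unused.
#' @return length(newtheta) x J matrix of probabilities.
#' @export
predict.girt <- function(object, newtheta = seq(-4, 4, length.out = 81), ...) {
  items <- plugin_items(object)
  fam <- eval_family(object)
  out <- vapply(seq_len(nrow(items)),
                function(j) icc(fam, newtheta, as.list(items[j, ])),
                numeric(length(newtheta)))
  dimnames(out) <- list(NULL, rownames(items))
  out
}

#' @export
plot.girt <- function(x, newtheta = seq(-4, 4, length.out = 81),
                      items = NULL, ...) {
  P <- predict(x, newtheta)
  if (!is.null(items)) P <- P[, items, drop = FALSE]
  graphics::matplot(newtheta, P, type = "l", lty = 1,
                    xlab = expression(theta),
                    ylab = "P(correct)", ylim = c(0, 1),
                    main = paste0("Item characteristic curves (",
                                  x$family, ")"), ...)
  invisible(P)
}

#' @export
fitted.girt <- function(object, ...) {
  items <- plugin_items(object)
  theta <- colMeans(param_matrix(object, "theta"))
  fam <- eval_family(object)
  P <- vapply(seq_len(nrow(items)),
              function(j) icc(fam, theta, as.list(items[j, ])),
              numeric(length(theta)))
  dimnames(P) <- dimnames(object$data)
  P
}

#' @export
residuals.girt <- function(object, ...) {
  object$data - fitted(object)
}

#' Posterior predictive response matrices
#'
#' Draws `nsim` replicated datasets: for each, one retained posterior draw
#' is selected at random and a full response matrix is simulated from it.
#' @param object a [girt()] fit.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of N x J integer matrices.
#' @export
simulate.girt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$dev_draws)
  fam <- eval_family(object)
  th <- param_matrix(object, "theta")
  items0 <- plugin_items(object)
  lapply(seq_len(nsim), function(s) {
    k <- sample.int(S, 1)
    items <- items0
    items$beta <- param_matrix(object, "beta")[k, ]
    if (!is.null(object$draws$lambda1)) {
      items$lambda1 <- param_matrix(object, "lambda1")[k, ]
      items$lambda2 <- param_matrix(object, "lambda2")[k, ]
    }
    if (!is.null(object$draws$alpha)) {
      items$alpha <- param_matrix(object, "alpha")[k, ]
      items$c <- param_matrix(object, "c")[k, ]
      if (!is.null(object$draws$d)) items$d <- param_matrix(object, "d")[k, ]
    }
    truth <- list(theta = th[k, ], items = items, family = fam)
    simulate_responses(truth, family = fam)
  })
}
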