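#' Simulation design
#'
#' Container for a parameter-recovery or model-comparison design: numbers
#' of persons, items and replications, the generating family and a base
#' seed.  Replication `r` uses seed `base_seed + r`, reproducible yet
#' independent across replications.
#'
#' @param n_persons,n_items,n_reps positive integers.
#' @param family generating family, see [girt_families()].
#' @param base_seed integer seed offset.
#' @return list of class `"girt_design"`.
#' @export
sim_design <- function(n_persons, n_items, n_reps = 1,
                       family = "rasch", base_seed = 1L) {
  stopifnot(n_persons >= 1, n_items >= 1, n_reps >= 1)
  family <- match.arg(family, girt_families())
  structure(list(n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 n_reps = as.integer(n_reps),
                 family = family, base_seed = as.integer(base_seed)),
            class = "girt_design")
}

# Truncated-normal sampler by rejection: N(mean, sd^2) restricted to
# (lower, Inf).  Acceptance is ~0.977 for sd = 0.5 and lower = -1, so
# rejection is cheap and exact.
rtnorm <- function(n, mean = 0, sd = 1, lower = -1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Draw true parameters for a simulation design
#'
#' Abilities are `theta ~ N(0, 1)` and difficulties `beta ~ N(0, 1)`.  For
#' the free-shape generalized-logit family the shapes are drawn from
#' `N(0, 0.5^2)` truncated below at -1 (by rejection); the fixed-shape
#' families use their link constants.  For the 3PL/4PL,
#' `alpha ~ U(0.5, 2)`, `c ~ Beta(5, 17)` and `d ~ Beta(17, 5)` (`d = 1`
#' for the 3PL).
#'
#' @param design a [sim_design()].
#' @param seed optional seed applied via `set.seed()` before drawing (the
#'   study drivers pass `base_seed + rep`).
#' @return list with components `theta` (length N) and `items` (data frame
#'   with one row per item: beta, lambda1, lambda2, alpha, c, d).
#' @export
draw_true_parameters <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- design$n_persons; J <- design$n_items
  fam <- design$family
  theta <- stats::rnorm(N)
  beta <- stats::rnorm(J)
  lambda1 <- lambda2 <- rep(0, J)
  alpha <- rep(1, J); cc <- rep(0, J); dd <- rep(1, J)
  if (fam == "glogit_free") {
    lambda1 <- rtnorm(J, 0, 0.5, -1)
    lambda2 <- rtnorm(J, 0, 0.5, -1)
  } else if (fam %in% c("rasch", "pno_glogit", "cllm_glogit")) {
    sh <- fixed_shape_constants(fam)
    lambda1 <- rep(sh[1], J); lambda2 <- rep(sh[2], J)
  } else if (fam %in% c("threepl", "fourpl")) {
    alpha <- stats::runif(J, 0.5, 2)
    cc <- stats::rbeta(J, 5, 17)
    dd <- if (fam == "fourpl") stats::rbeta(J, 17, 5) else rep(1, J)
    bad <- dd <= cc          # vanishingly rare under these Betas
    dd[bad] <- pmin(1, cc[bad] + 0.05)
  }
  list(theta = theta,
       items = data.frame(beta = beta, lambda1 = lambda1, lambda2 = lambda2,
                          alpha = alpha, c = cc, d = dd),
       family = fam)
}

#' Simulate a dichotomous response matrix
#'
#' Independent Bernoulli draws `x_ij ~ Bernoulli(icc(family, theta_i,
#' item_j))` for every cell; no missing entries are generated.
#'
#' @param truth a truth set from [draw_true_parameters()].
#' @param family generating family; defaults to the family recorded in
#'   `truth`.
#' @param seed optional seed applied before drawing.
#' @return integer N x J matrix with dimnames `P1..PN` / `I1..IJ`.
#' @export
simulate_responses <- function(truth, family = truth$family, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(truth$theta); J <- nrow(truth$items)
  X <- matrix(0L, N, J,
              dimnames = list(paste0("P", seq_len(N)), paste0("I", seq_len(J))))
  for (j in seq_len(J)) {
    p <- icc(family, truth$theta, as.list(truth$items[j, ]))
    X[, j] <- as.integer(stats::runif(N) < p)
  }
  X
}

#' Packaged toy datasets
#'
#' Deterministic fixtures regenerated in code (byte-identical across runs;
#' the caller's RNG state is preserved):
#' * `"rasch_toy"` — a 50 x 5 Rasch response matrix plus its truth;
#' * `"pisa_like"` — a synthetic stand-in for an 11-item large-scale
#'   assessment extract: 685 persons of whom exactly 76 carry a
#'   missing-data code (6 = not reached, 9 = no response) in at least one
#'   cell, so the drop-person cleaning policy retains 609.  It is simulated
#'   from a free-shape generalized-logit truth and shares only the shape
#'   of the real assessment data, not its values.
#'
#' @param name fixture name.
#' @return list with `responses` (matrix) and `truth`.
#' @export
make_fixture <- function(name = c("rasch_toy", "pisa_like")) {
  name <- match.arg(name)
  with_preserved_seed({
    if (name == "rasch_toy") {
      design <- sim_design(50, 5, family = "rasch", base_seed = 20230830L)
      truth <- draw_true_parameters(design, seed = design$base_seed)
      X <- simulate_responses(truth, seed = design$base_seed + 1L)
      list(responses = X, truth = truth)
    } else {
      design <- sim_design(685, 11, family = "glogit_free",
                           base_seed = 20150901L)
      truth <- draw_true_parameters(design, seed = design$base_seed)
      X <- simulate_responses(truth, seed = design$base_seed + 1L)
      # storage mode double so the 6/9 codes survive round-trips
      X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
      set.seed(design$base_seed + 2L)
      miss_persons <- sample(nrow(X), 76L)
      for (i in miss_persons) {
        k <- sample(ncol(X), sample(1:3, 1))
        X[i, k] <- sample(c(6, 9), length(k), replace = TRUE)
      }
      list(responses = X, truth = truth)
    }
  })
}

# Run `expr` under the package's own seeds without disturbing the caller's
# RNG state.
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
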