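test_that("DIC components follow the plug-in definition", {
  # two draws with deviances 10 and 14, plug-in deviance 11
  parts <- glogitIRT:::.dic_parts(c(10, 14), 11)
  expect_equal(unname(parts), c(13, 1))
  # single draw: Dbar equals the plug-in deviance when the chain is stuck
  expect_equal(unname(glogitIRT:::.dic_parts(12, 12)), c(12, 0))
  # adding a constant to all log-likelihoods shifts DIC by -2 * constant
  k <- 3.7
  expect_equal(unname(glogitIRT:::.dic_parts(c(10, 14) - 2 * k, 11 - 2 * k)[1]),
               13 - 2 * k)
  # non-finite draws are excluded with a warning
  expect_warning(p2 <- glogitIRT:::.dic_parts(c(10, 14, Inf), 11), "excluded")
  expect_equal(unname(p2[1]), 13)
})

test_that("dic() on a fit is consistent with its parts", {
  fit <- tiny_rasch_fit()
  d <- dic(fit)
  expect_equal(unname(d["dic"]),
               mean(fit$dev_draws) + unname(d["p_dic"]))
  expect_gt(d["p_dic"], 0)  # effective parameters positive for a real fit
})

test_that("LPML is the sum of log harmonic-mean CPOs", {
  pw <- matrix(log(c(0.5, 0.25)), 2, 1)
  expect_equal(lpml(pw), log(1 / 3))
  # constant likelihood: CPO recovers it exactly
  pw2 <- matrix(log(0.37), 5, 3)
  expect_equal(lpml(pw2), 3 * log(0.37))
  # Jensen: harmonic mean <= arithmetic mean, so LPML <= lppd
  set.seed(1)
  pw3 <- matrix(log(runif(200)), 20, 10)
  lppd <- sum(glogitIRT:::col_log_mean_exp(pw3))
  expect_lte(lpml(pw3), lppd)
  expect_warning(expect_identical(lpml(matrix(-Inf, 3, 1)), -Inf), "-Inf")
})

test_that("WAIC matches its closed form on micro-examples", {
  # degenerate draws: no variance penalty
  pw <- matrix(rep(c(-1.2, -0.4), each = 3), 3, 2)
  w <- waic(pw)
  expect_equal(unname(w["p_waic"]), 0)
  expect_equal(unname(w["waic"]), -2 * (-1.2 - 0.4))
  # two-point sample variance (log 2)^2 / 2 per cell
  pw2 <- matrix(log(c(0.5, 0.25)), 2, 1)
  expect_equal(unname(waic(pw2)["p_waic"]), log(2)^2 / 2)
  # invariant to draw order
  set.seed(2)
  pw3 <- matrix(log(runif(300)), 30, 10)
  expect_equal(waic(pw3), waic(pw3[sample(30), ]))
})

test_that("criteria decompose exactly over observation columns", {
  fit <- tiny_rasch_fit()
  pw <- fit$pointwise
  split_cols <- list(1:100, 101:400, 401:ncol(pw))
  expect_equal(sum(vapply(split_cols, function(k) lpml(pw[, k]), numeric(1))),
               lpml(pw))
  expect_equal(sum(vapply(split_cols, function(k) unname(waic(pw[, k])["waic"]),
                          numeric(1))),
               unname(waic(pw)["waic"]))
  expect_equal(sum(vapply(split_cols, function(k) loo_psis(pw[, k])$loo,
                          numeric(1))),
               loo_psis(pw)$loo)
})

test_that("PSIS-LOO matches exact leave-one-out on a conjugate toy", {
  # Bernoulli cells with a Beta(2,2) prior: the posterior and every
  # leave-one-out posterior are Beta, so exact LOO is available in closed
  # form as the mean of the leave-one-out posterior.
  x <- c(1, 1, 0, 1, 0)
  n <- length(x); k <- sum(x)
  set.seed(5)
  p_draws <- rbeta(4000, 2 + k, 2 + n - k)
  pw <- vapply(x, function(xi) if (xi == 1) log(p_draws) else log(1 - p_draws),
               numeric(length(p_draws)))
  res <- loo_psis(pw)
  exact <- vapply(seq_len(n), function(i) {
    a <- 2 + k - x[i]; b <- 2 + (n - 1) - (k - x[i])
    m <- a / (a + b)
    log(if (x[i] == 1) m else 1 - m)
  }, numeric(1))
  expect_equal(res$elpd_loo, exact, tolerance = 0.01, ignore_attr = TRUE)
  # constant likelihood: elpd is the likelihood itself, k flagged NA
  pwc <- matrix(log(0.4), 200, 2)
  resc <- loo_psis(pwc)
  expect_equal(resc$elpd_loo, rep(log(0.4), 2), ignore_attr = TRUE)
  expect_true(all(is.na(resc$pareto_k)))
  # too few draws for the tail fit: unsmoothed with a warning
  expect_warning(loo_psis(pw[1:50, ]), "100 draws")
})

test_that("LOO and WAIC agree on a well-behaved fit", {
  fit <- tiny_rasch_fit()
  w <- unname(waic(fit)["waic"])
  l <- loo_psis(fit)
  expect_lt(abs(l$loo - w) / abs(w), 0.01)
  expect_lt(l$pareto_k_max, 0.7)
  rep <- criteria_report(fit)
  expect_named(rep, c("dic", "p_dic", "lpml", "waic", "p_waic", "loo",
                      "pareto_k_max"))
  # reporting scales: LPML is a log score (negative here), others deviances
  expect_lt(rep$lpml, 0)
  expect_gt(rep$waic, 0)
})
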