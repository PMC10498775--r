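test_that("split R-hat behaves at its reference points", {
  set.seed(101)
  x <- rnorm(1000)
  # identical chains add no between-chain variance beyond the split
  # halves of the one sequence: ~1 for a well-mixed sequence
  expect_lt(rhat_split(cbind(x, x, x, x)), 1.01)
  expect_gt(rhat_split(cbind(x, x, x, x)), 0.99)
  # gross nonconvergence
  expect_gt(rhat_split(cbind(rnorm(1000), rnorm(1000, 10))), 3)
  # i.i.d. chains at convergence
  m <- matrix(rnorm(4000), 1000, 4)
  expect_gt(rhat_split(m), 0.99)
  expect_lt(rhat_split(m), 1.01)
  # degenerate draws
  expect_equal(rhat_split(matrix(2.2, 50, 4)), 1)
  expect_error(rhat_split(matrix(1:100, 100, 1)), "chains")
})

test_that("HPDI is the shortest mass-covering interval", {
  expect_equal(hpdi(rep(3.3, 100)), c(3.3, 3.3))
  set.seed(7)
  x <- rnorm(2e5)
  h <- hpdi(x, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.03)
  expect_equal(h[2], 1.96, tolerance = 0.03)
  # for a right-skewed density the HPDI hugs the mode, unlike equal tails
  y <- rexp(2e5)
  expect_lt(hpdi(y, 0.9)[1], 0.01)
  expect_error(hpdi(x, 1.2), "mass")
})

test_that("posterior_summary has the reporting layout and degenerate limits", {
  fit <- tiny_rasch_fit()
  tab <- posterior_summary(fit)
  expect_named(tab, c("parameter", "Estimate", "SD", "HPDI_lower",
                      "HPDI_upper", "Rhat"))
  expect_true(all(tab$HPDI_lower <= tab$Estimate & tab$Estimate <= tab$HPDI_upper))
  full <- posterior_summary(fit, pars = "all")
  expect_equal(nrow(full), 120 + 6 + 1)  # theta + beta + sigma_beta
  expect_error(posterior_summary(fit, mass = 0), "mass")
  # degenerate draws: mean v, SD 0, HPDI [v, v]
  fake <- list(draws = list(beta = array(2.5, c(40, 2, 1))))
  fake$rhat <- compute_rhat(fake)
  row <- posterior_summary(structure(fake, class = "girt"))
  expect_equal(row$Estimate, 2.5)
  expect_equal(row$SD, 0)
  expect_equal(c(row$HPDI_lower, row$HPDI_upper), c(2.5, 2.5))
  expect_equal(row$Rhat, 1)
})

test_that("sampler matches dense-grid quadrature on a two-parameter toy", {
  # one person, one item, x = 1, sigma_beta fixed at 1:
  # posterior(theta, beta) ~ plogis(theta - beta) N(theta) N(beta)
  g <- seq(-8, 8, length.out = 401)
  w <- outer(dnorm(g), dnorm(g)) * plogis(outer(g, g, "-"))
  w <- w / sum(w)
  contrast_exact <- sum(outer(g, g, function(t, b) b - t) * w)
  X <- matrix(1L, 1, 1)
  fit <- girt(X, "rasch", chains = 4, iter = 26000, burnin = 1000, seed = 3,
              fix_sigma_beta = 1, store_loglik = FALSE)
  contrast_mcmc <- mean(glogitIRT:::param_matrix(fit, "beta") -
                          glogitIRT:::param_matrix(fit, "theta"))
  expect_equal(contrast_mcmc, contrast_exact, tolerance = 0.02)
  # posterior SDs agree too
  sd_exact <- sqrt(sum(outer(g, g, function(t, b) (b - t - contrast_exact)^2) * w))
  sd_mcmc <- sd(glogitIRT:::param_matrix(fit, "beta") -
                  glogitIRT:::param_matrix(fit, "theta"))
  expect_equal(sd_mcmc, sd_exact, tolerance = 0.05)
})

test_that("fits are reproducible and respect parameter supports", {
  s <- small_sim("glogit_free", N = 150, J = 5, seed = 21)
  f1 <- girt(s$X, "glogit_free", chains = 2, iter = 500, burnin = 250, seed = 77)
  f2 <- girt(s$X, "glogit_free", chains = 2, iter = 500, burnin = 250, seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(glogitIRT:::param_matrix(f1, "lambda1") > -1))
  expect_true(all(glogitIRT:::param_matrix(f1, "lambda2") > -1))
  expect_true(all(glogitIRT:::param_matrix(f1, "sigma_beta") > 0))
  expect_true(all(glogitIRT:::param_matrix(f1, "sigma_lambda") > 0))
  expect_true(all(is.finite(f1$pointwise)))
  expect_equal(ncol(f1$pointwise), sum(!is.na(s$X)))
})

test_that("difficulties are recovered without systematic bias", {
  s <- small_sim("rasch", N = 600, J = 10, seed = 33)
  fit <- girt(s$X, "rasch", chains = 2, iter = 1000, burnin = 500, seed = 33,
              store_loglik = FALSE)
  bhat <- colMeans(glogitIRT:::param_matrix(fit, "beta"))
  expect_lt(mean(abs(bhat - s$truth$items$beta)), 0.15)
})

test_that("invalid data are rejected up front", {
  expect_error(girt(matrix(c(0, 2), 1, 2)), "0/1")
  X <- matrix(c(1L, NA, 0L, NA), 2, 2)
  X[2, ] <- NA
  expect_error(girt(X, "rasch"), "persons")
  X2 <- matrix(c(1L, 0L, NA, NA), 2, 2)
  expect_error(girt(X2, "rasch"), "items")
})
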