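test_that("true-parameter draws follow the design distributions", {
  design <- sim_design(30, 4000, family = "glogit_free", base_seed = 5)
  truth <- draw_true_parameters(design, seed = 5)
  # truncation support is exact
  expect_true(all(truth$items$lambda1 > -1))
  expect_true(all(truth$items$lambda2 > -1))
  # truncated-normal moments (sd 0.5, bound -1): closed form via Mills ratio
  a <- -1 / 0.5
  mu_tr <- 0.5 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(truth$items$lambda1), mu_tr, tolerance = 4 * 0.5 / sqrt(4000))
  design4 <- sim_design(10, 4000, family = "fourpl", base_seed = 6)
  truth4 <- draw_true_parameters(design4, seed = 6)
  # Beta(17, 5) upper asymptotes: mean 17/22 within MC error
  se <- sqrt(17 * 5 / (22^2 * 23)) / sqrt(4000)
  expect_equal(mean(truth4$items$d), 17 / 22, tolerance = 3 * se)
  expect_true(all(truth4$items$alpha >= 0.5 & truth4$items$alpha <= 2))
  expect_true(all(truth4$items$c < truth4$items$d))
  # fixed-shape families carry their link constants
  tr_pno <- draw_true_parameters(sim_design(5, 3, family = "pno_glogit"), seed = 1)
  expect_equal(unique(tr_pno$items$lambda1), 0.165)
})

test_that("same seed gives identical truths and responses", {
  design <- sim_design(50, 6, family = "glogit_free", base_seed = 9)
  t1 <- draw_true_parameters(design, seed = 9)
  t2 <- draw_true_parameters(design, seed = 9)
  expect_identical(t1, t2)
  expect_identical(simulate_responses(t1, seed = 10), simulate_responses(t2, seed = 10))
})

test_that("response simulation matches the model probabilities", {
  # forced success: huge theta - beta with lambda1 = 1
  truth <- list(theta = rep(20, 30),
                items = data.frame(beta = rep(0, 3), lambda1 = 1, lambda2 = 0,
                                   alpha = 1, c = 0, d = 1),
                family = "glogit_free")
  expect_true(all(simulate_responses(truth, seed = 1) == 1L))
  # theta = beta: grand mean near 1/2 within binomial error
  n <- 400; j <- 10
  truth2 <- list(theta = rep(0.3, n),
                 items = data.frame(beta = rep(0.3, j), lambda1 = 0.5,
                                    lambda2 = -0.2, alpha = 1, c = 0, d = 1),
                 family = "glogit_free")
  X <- simulate_responses(truth2, seed = 2)
  expect_lt(abs(mean(X) - 0.5), 3 * sqrt(0.25 / (n * j)))
})

test_that("item proportions converge to the average ICC for every family", {
  for (fam in c("rasch", "cllm_glogit", "pno_exact", "cllm_exact", "threepl")) {
    # exact-link families share the one-parameter truth structure
    base_fam <- if (fam %in% c("pno_exact", "cllm_exact")) "rasch" else fam
    truth <- draw_true_parameters(sim_design(3000, 3, family = base_fam), seed = 31)
    X <- simulate_responses(truth, family = fam)
    for (j in 1:3) {
      pbar <- mean(icc(fam, truth$theta, as.list(truth$items[j, ])))
      expect_lt(abs(mean(X[, j]) - pbar), 4 * sqrt(pbar * (1 - pbar) / 3000))
    }
  }
})

test_that("fixtures are deterministic and shaped as documented", {
  fx1 <- make_fixture("rasch_toy")
  fx2 <- make_fixture("rasch_toy")
  expect_identical(fx1, fx2)
  expect_equal(dim(fx1$responses), c(50, 5))
  expect_true(all(fx1$responses %in% c(0L, 1L)))

  px <- make_fixture("pisa_like")
  expect_equal(dim(px$responses), c(685, 11))
  n_missing_persons <- sum(apply(px$responses, 1, function(r) any(r %in% c(6, 9))))
  expect_equal(n_missing_persons, 76)
  expect_error(make_fixture("unknown_fixture"))
})

test_that("fixture generation leaves the caller RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(make_fixture("rasch_toy"))
  expect_identical(.Random.seed, before)
})
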