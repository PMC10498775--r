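test_that("model-selection counting ranks replications correctly", {
  v <- rbind(c(1, 2), c(2, 1))
  colnames(v) <- c("A", "B")
  ct <- count_model_selections(v, minimize = TRUE)
  expect_equal(unname(ct$best), c(1L, 1L))
  expect_equal(unname(ct$second), c(1L, 1L))
  # direct ranking of a single replication over three families
  ct3 <- count_model_selections(matrix(c(3, 1, 2), 1), minimize = TRUE)
  expect_equal(unname(ct3$best), c(0L, 1L, 0L))
  expect_equal(unname(ct3$second), c(0L, 0L, 1L))
  # maximizing flips the direction (LPML convention)
  ctm <- count_model_selections(matrix(c(3, 1, 2), 1), minimize = FALSE)
  expect_equal(unname(ctm$best), c(1L, 0L, 0L))
  # identical ordering in all replications: constant runner-up
  vv <- matrix(rep(c(5, 1, 3), 4), 4, 3, byrow = TRUE)
  ctv <- count_model_selections(vv)
  expect_equal(unname(ctv$second), c(0L, 0L, 4L))
  # non-finite replications dropped with a warning
  vna <- rbind(c(1, 2), c(NA, 1))
  expect_warning(ctn <- count_model_selections(vna), "excluded")
  expect_equal(sum(ctn$best), 1L)
  expect_error(count_model_selections(matrix(1, 2, 1)), "families")
})

test_that("recovery study aggregates across replications and conditions", {
  rs <- run_recovery_study("rasch", n_persons = 150, n_items = 5, n_reps = 2,
                           chains = 2, iter = 400, burnin = 200, base_seed = 3)
  expect_s3_class(rs, "girt_recovery")
  expect_equal(rownames(rs$table), c("beta", "theta"))
  expect_equal(colnames(rs$table), c("Bias", "MSE", "SE", "SD"))
  expect_true(all(is.finite(rs$table)))
  expect_true(all(rs$table[, c("MSE", "SE", "SD")] >= 0))
  # free-shape variant reports all four parameter blocks
  rs2 <- run_recovery_study("glogit_free", n_persons = 100, n_items = 4,
                            n_reps = 2, chains = 2, iter = 400, burnin = 200,
                            base_seed = 4)
  expect_equal(rownames(rs2$table), c("beta", "lambda1", "lambda2", "theta"))
  expect_output(print(rs), "Parameter recovery")
})

test_that("a degenerate one-person one-item design still runs", {
  rs <- run_recovery_study("rasch", n_persons = 1, n_items = 1, n_reps = 1,
                           chains = 2, iter = 300, burnin = 150, base_seed = 8)
  expect_true(is.finite(rs$table["beta", "MSE"]))
  expect_gt(rs$table["beta", "SD"], 0.5)  # posterior stays wide
})

test_that("comparison study shapes, pairing, and reproducibility", {
  fams <- c("rasch", "cllm_glogit")
  cs1 <- run_comparison_study("rasch", fams, n_persons = 120, n_items = 5,
                              n_reps = 2, chains = 2, iter = 400, burnin = 200,
                              base_seed = 5)
  expect_s3_class(cs1, "girt_comparison")
  expect_equal(dim(cs1$mean_table), c(2L, 4L))
  expect_equal(colnames(cs1$mean_table), c("dic", "lpml", "waic", "loo"))
  for (ct in cs1$counts) {
    expect_equal(sum(ct$best), 2L)
    expect_equal(sum(ct$second), 2L)
  }
  cs2 <- run_comparison_study("rasch", fams, n_persons = 120, n_items = 5,
                              n_reps = 2, chains = 2, iter = 400, burnin = 200,
                              base_seed = 5)
  expect_identical(cs1$mean_table, cs2$mean_table)
  expect_output(print(cs1), "Model comparison")
})

test_that("real-data workflow produces the comparison and summary tables", {
  fx <- make_fixture("rasch_toy")
  rd <- run_real_data(fx$responses, families = c("rasch", "cllm_glogit"),
                      chains = 2, iter = 500, burnin = 250, seed = 2)
  expect_equal(rownames(rd$criteria), c("rasch", "cllm_glogit"))
  expect_equal(colnames(rd$criteria), c("dic", "lpml", "waic", "loo"))
  expect_true(rd$winner %in% c("rasch", "cllm_glogit"))
  expect_named(rd$summary, c("parameter", "Estimate", "SD", "HPDI_lower",
                             "HPDI_upper", "Rhat"))
  expect_equal(length(rd$person_estimates), 50)
  expect_true(all(c("item", "theta", "p") %in% names(rd$icc_curves)))
})
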