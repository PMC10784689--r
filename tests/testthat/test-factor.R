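test_that("principal-axis factoring recovers the equicorrelated closed form", {
  # equicorrelated off-diagonal 0.64 = 0.8^2: loadings are exactly 0.8
  R <- matrix(0.64, 3, 3)
  diag(R) <- 1
  W <- exact_corr_data(R, n = 60, seed = 2)
  fit <- extract_single_factor(W)
  expect_equal(as.numeric(fit$loadings), rep(0.8, 3), tolerance = 1e-3)
  expect_equal(as.numeric(fit$uniquenesses), rep(1 - 0.64, 3), tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("rank-one-plus-diagonal matrices are recovered against an eigen oracle", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.4)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  W <- exact_corr_data(R, n = 100, seed = 3)
  fit <- extract_single_factor(W)
  expect_equal(as.numeric(fit$loadings), lam, tolerance = 1e-3)

  # independent oracle: eigendecomposition of the reduced matrix with the
  # *known* uniquenesses gives the same loadings
  e <- eigen(R - diag(1 - lam^2), symmetric = TRUE)
  oracle <- sqrt(e$values[1]) * e$vectors[, 1]
  if (sum(oracle) < 0) oracle <- -oracle
  expect_equal(as.numeric(fit$loadings), oracle, tolerance = 1e-3)

  # maximum-likelihood extraction agrees as an independent cross-check
  ml <- extract_single_factor(W, method = "ml")
  expect_equal(as.numeric(ml$loadings), lam, tolerance = 1e-2)

  # uniqueness ~ 1 - loading^2 at convergence
  expect_equal(as.numeric(fit$uniquenesses), 1 - as.numeric(fit$loadings)^2,
               tolerance = 1e-4)
})

test_that("tasks with no common variance yield zero loadings", {
  # exactly-identity sample correlation: the minimal solution has no factor
  W <- exact_corr_data(diag(5), n = 200, seed = 4)
  fit <- extract_single_factor(W)
  expect_true(all(abs(fit$loadings) < 1e-6))
  expect_true(fit$converged)
})

test_that("the loading-sum sign convention is enforced", {
  lam <- c(0.7, 0.7, 0.7)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  W <- exact_corr_data(R, n = 50, seed = 5)
  # flipping every observed variable would flip all loadings; the returned
  # solution must still have a nonnegative loading sum
  fit <- extract_single_factor(-W)
  expect_gte(sum(fit$loadings), 0)
  expect_true(all(fit$loadings > 0.5))
})

test_that("degenerate factor inputs error informatively", {
  W <- exact_corr_data(diag(3), n = 30, seed = 6)
  expect_error(extract_single_factor(W[, 1:2]), "at least 3 tasks")
  W2 <- cbind(W, dead = rep(0.5, 30))
  expect_error(extract_single_factor(W2), "dead")
})

test_that("regression factor scores track the dominant latent", {
  cfg <- battery_config(n_subjects = 300, tasks = default_tasks(loading = 0.8),
                        covariates = NULL, seed = 81)
  sim <- simulate_battery(cfg)
  fit <- extract_single_factor(sim$responses)
  ix <- match(fit$scores$subject_id, sim$truth$subjects)
  r <- cor(fit$scores$score, sim$truth$theta[ix])
  expect_gt(abs(r), 0.8)
  expect_gt(r * sum(fit$loadings), 0) # orientation consistent with loadings
})

test_that("one-factor reconstruction error is small on single-factor batteries", {
  cfg <- battery_config(n_subjects = 400, tasks = default_tasks(loading = 0.7),
                        covariates = NULL, seed = 82)
  sim <- simulate_battery(cfg)
  acc <- accuracy_wide_for_test(sim$responses)
  R <- cor(acc, use = "pairwise.complete.obs")
  fit <- extract_single_factor(sim$responses)
  lam <- fit$loadings[colnames(R)]
  implied <- tcrossprod(lam) + diag(as.numeric(fit$uniquenesses[colnames(R)]))
  err <- abs(R - implied)
  diag(err) <- 0
  expect_lt(max(err), 0.05)
})

test_that("cross-validated factor variance shows ceiling and dissociation patterns", {
  # a task with no shared loading keeps high reliability but near-zero ratio
  tk <- default_tasks(loading = 0.8)
  tk$loading[tk$task_id == "bowling"] <- 0
  cfg <- battery_config(n_subjects = 200, tasks = tk, covariates = NULL, seed = 83)
  sim <- simulate_battery(cfg)
  fv <- crossvalidated_factor_variance(sim$responses, n_iter = 30, n_perm = 30, seed = 8)
  s <- fv$summary
  expect_lt(s$ratio_to_reliability[s$task_id == "bowling"], 0.3)
  expect_gt(s$split_half_z[s$task_id == "bowling"], 0.5)
  expect_true(all(s$p[s$task_id != "bowling"] == 1 / 31))
  # split-half column comes from the identical split stream
  sh <- split_half_reliability(sim$responses, n_iter = 30, n_perm = 0, seed = 8)
  expect_equal(s$split_half_z,
               sh$summary$mean_z[match(s$task_id, sh$summary$task_id)])
})

test_that("permutation p is calibrated when no stable individual differences exist", {
  # zero discrimination removes *all* stable subject variance (shared and
  # task-specific): factor scores then carry nothing that should align with
  # left-out halves
  ps <- vapply(1:8, function(s) {
    cfg <- battery_config(n_subjects = 60, tasks = default_tasks(discrimination = 0)[1:3, ],
                          covariates = NULL, missing_rate = 0, seed = 900 + s)
    sim <- simulate_battery(cfg)
    fv <- suppressWarnings(
      crossvalidated_factor_variance(sim$responses, n_iter = 15, n_perm = 30, seed = s)
    )
    mean(fv$summary$p)
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.9)
  expect_lte(mean(ps < 0.05), 0.25)
})

test_that("reliable but uncorrelated tasks still validate against their own halves", {
  # with zero shared loading the tasks remain individually reliable; any
  # data-driven weighting of them predicts their own left-out halves, so the
  # validation z stays positive -- an interpretive caveat of the design, not
  # evidence of a common factor (ratios remain far below the reliability
  # ceiling of the most reliable task)
  cfg <- battery_config(n_subjects = 60, tasks = default_tasks(loading = 0)[1:3, ],
                        covariates = NULL, missing_rate = 0, seed = 905)
  sim <- simulate_battery(cfg)
  fv <- suppressWarnings(
    crossvalidated_factor_variance(sim$responses, n_iter = 15, n_perm = 30, seed = 5)
  )
  expect_gt(mean(fv$summary$mean_z), 0)
})
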