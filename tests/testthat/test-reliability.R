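test_that("trial splits are balanced, disjoint, and exhaustive", {
  sim <- simulate_battery(battery_config(n_subjects = 5, seed = 1))
  for (s in 1:5) {
    sp <- split_trials(sim$responses, seed = s)
    by_task <- split(sp, sp$task_id)
    for (tk in by_task) {
      a <- tk$trial_id[tk$half == "a"]
      b <- tk$trial_id[tk$half == "b"]
      expect_length(intersect(a, b), 0)
      expect_setequal(c(a, b), unique(tk$trial_id))
      expect_lte(abs(length(a) - length(b)), 1L)
    }
  }
  # 40-trial task -> 20/20; 5-trial task -> {3,2}
  t40 <- toy_responses(matrix(1:0, 4, 40), task_id = "even")
  s40 <- split_trials(t40, seed = 3)
  expect_equal(as.vector(table(s40$half)), c(20L, 20L))
  t5 <- toy_responses(matrix(1:0, 4, 5), task_id = "odd")
  s5 <- split_trials(t5, seed = 3)
  expect_setequal(as.vector(table(s5$half)), c(3L, 2L))

  # deterministic under the same seed, different under seed + 1
  expect_identical(split_trials(t40, seed = 7), split_trials(t40, seed = 7))
  expect_false(identical(split_trials(t40, seed = 7), split_trials(t40, seed = 8)))

  expect_error(split_trials(toy_responses(matrix(1, 3, 1)), seed = 1), "fewer than 2")
})

test_that("iterated split-half mean matches the exhaustive-split oracle", {
  # 4 subjects x 4 trials: only 3 distinct balanced splits exist
  correct <- rbind(
    c(1, 1, 0, 0),
    c(1, 0, 1, 0),
    c(1, 1, 1, 0),
    c(0, 0, 1, 1)
  )
  rm <- toy_responses(correct, task_id = "T")

  # independent oracle: enumerate splits from the raw matrix by hand
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  oracle_z <- vapply(splits, function(a) {
    b <- setdiff(1:4, a)
    accA <- rowMeans(correct[, a])
    accB <- rowMeans(correct[, b])
    r <- suppressWarnings(cor(accA, accB)) # NA on a degenerate split
    atanh(min(max(r, -(1 - 1e-12)), 1 - 1e-12))
  }, numeric(1))

  res <- split_half_reliability(rm, exhaustive = TRUE, seed = 1)
  row <- res$summary[res$summary$task_id == "T", ]
  expect_equal(row$n_used + row$n_degenerate, 3L)
  expect_equal(row$mean_z, mean(oracle_z[!is.na(oracle_z)]), tolerance = 1e-12)

  # sampled engine converges to the same value
  samp <- split_half_reliability(rm, n_iter = 400, n_perm = 0, seed = 5)
  srow <- samp$summary[samp$summary$task_id == "T", ]
  expect_lt(abs(srow$mean_z - row$mean_z), 0.15)
})

test_that("exhaustive-split equality holds on a two-task fixture", {
  withr::with_seed(9, {
    ta <- toy_responses(matrix(rbinom(6 * 4, 1, 0.6), 6, 4), task_id = "A")
    tb <- toy_responses(matrix(rbinom(6 * 6, 1, 0.5), 6, 6), task_id = "B")
  })
  rm <- toy_battery(ta, tb)
  ex <- split_half_reliability(rm, exhaustive = TRUE, seed = 1)
  # 3 splits for the 4-trial task x 10 for the 6-trial task
  expect_equal(ex$n_iter, 30L)
  samp <- split_half_reliability(rm, n_iter = 600, n_perm = 0, seed = 2)
  for (tk in c("A", "B", "combined")) {
    expect_lt(
      abs(samp$summary$mean_z[samp$summary$task_id == tk] -
            ex$summary$mean_z[ex$summary$task_id == tk]),
      0.2
    )
  }
})

test_that("permutation p-values follow the add-one rule and an exhaustive oracle", {
  expect_equal(permutation_pvalue(10, rnorm(999)), 1 / 1000)
  null <- c(-2, -1, 0, 1, 2)
  expect_equal(permutation_pvalue(0, null), (1 + 3) / 6)
  expect_error(permutation_pvalue(1, numeric(0)), "nonempty")

  # 4-subject toy: enumerate all 24 subject permutations as the null
  a <- c(0.2, 0.4, 0.6, 0.8)
  b <- c(0.25, 0.35, 0.7, 0.75)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  null_draws <- apply(perms, 1, function(p) atanh(cor(a, b[p])))
  obs <- atanh(cor(a, b))
  # observed corresponds to the identity permutation, the unique maximum
  expect_equal(permutation_pvalue(obs, null_draws), (1 + 1) / 25)
})

test_that("high-signal batteries reach the permutation floor; null batteries do not", {
  cfg <- battery_config(n_subjects = 300, tasks = default_tasks(loading = 0.7),
                        covariates = NULL, seed = 61)
  sim <- simulate_battery(cfg)
  sh <- split_half_reliability(sim$responses, n_iter = 50, n_perm = 100, seed = 6)
  expect_true(all(sh$summary$p == 1 / 101))
  expect_true(all(sh$summary$mean_z > 0.3))

  nb <- null_battery(n_subjects = 80, seed = 62)
  shn <- split_half_reliability(nb, n_iter = 50, n_perm = 100, seed = 6)
  comb <- shn$summary[shn$summary$task_id == "combined", ]
  expect_lt(abs(comb$mean_z), 3 * comb$sd_z + 0.05)
  expect_gt(comb$p, 1 / 101)
})

test_that("between-task correlations match hand computation and flag degeneracy", {
  # 5-subject toy table, hand-computed Pearson value
  accA <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  accB <- c(0.3, 0.3, 0.6, 0.6, 0.8)
  ta <- toy_responses(outer(accA, rep(1, 10)) >= matrix((1:10 - 0.5) / 10, 5, 10, byrow = TRUE),
                      task_id = "A")
  # deterministic trial patterns reproduce the accuracies exactly
  expect_equal(score_accuracy(ta)$accuracy, accA)
  tb <- toy_responses(outer(accB, rep(1, 10)) >= matrix((1:10 - 0.5) / 10, 5, 10, byrow = TRUE),
                      task_id = "B")
  rm <- toy_battery(ta, tb)
  ct <- between_task_correlations(rm, n_boot = 50, seed = 3)
  expect_equal(ct$r, cor(accA, accB), tolerance = 1e-12)
  expect_equal(ct$z, atanh(cor(accA, accB)), tolerance = 1e-12)

  # duplicated task -> r = 1, clamped z
  tb2 <- toy_responses(outer(accA, rep(1, 10)) >= matrix((1:10 - 0.5) / 10, 5, 10, byrow = TRUE),
                       task_id = "Acopy")
  ct2 <- between_task_correlations(toy_battery(ta, tb2), n_boot = 0, seed = 1)
  expect_equal(ct2$r, 1)
  expect_true(ct2$clamped)
  expect_true(is.finite(ct2$z))

  # zero-variance task named in the error
  tz <- toy_responses(matrix(1, 5, 10), task_id = "allsame")
  expect_error(between_task_correlations(toy_battery(ta, tz), n_boot = 0),
               "allsame")
})

test_that("bootstrap CIs on independent tasks usually cover zero", {
  cfg <- battery_config(n_subjects = 200, tasks = default_tasks(loading = 0)[1:3, ],
                        covariates = NULL, missing_rate = 0, seed = 71)
  sim <- simulate_battery(cfg)
  ct <- between_task_correlations(sim$responses, n_boot = 300, seed = 2)
  covers <- ct$ci_low <= 0 & ct$ci_high >= 0
  expect_gte(sum(covers), 2L) # 3 pairs, ~95% coverage each
})

test_that("correlation difference test is antisymmetric with a valid null case", {
  withr::with_seed(8, {
    d <- tibble::tibble(x = rnorm(100))
    d$y1 <- 0.9 * d$x + rnorm(100, sd = sqrt(1 - 0.81))
    d$y2 <- rnorm(100)
  })
  # identical targets: delta exactly 0, p near 1
  same <- correlation_difference_test(d, c("x", "y1"), c("x", "y1"), n_boot = 200, seed = 4)
  expect_equal(same$delta_z, 0)
  expect_gt(same$p, 0.9)

  strong <- correlation_difference_test(d, c("x", "y1"), c("x", "y2"), n_boot = 200, seed = 4)
  expect_equal(strong$p, 2 / 201) # bootstrap floor
  flipped <- correlation_difference_test(d, c("x", "y2"), c("x", "y1"), n_boot = 200, seed = 4)
  expect_equal(flipped$delta_z, -strong$delta_z)
  expect_equal(flipped$p, strong$p)
})

test_that("longer tasks are more reliable across seeds", {
  diffs <- vapply(1:5, function(s) {
    mk <- function(nt) {
      cfg <- battery_config(
        n_subjects = 120,
        tasks = tibble::tibble(task_id = "T", n_trials = nt, chance = 0.5,
                               loading = 0.6, discrimination = 1.5, difficulty_sd = 1),
        covariates = NULL, missing_rate = 0, seed = 700 + s
      )
      sh <- split_half_reliability(simulate_battery(cfg)$responses,
                                   n_iter = 25, n_perm = 0, seed = s)
      sh$summary$mean_z[sh$summary$task_id == "T"]
    }
    mk(160L) - mk(40L)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.5)
  expect_gt(mean(diffs), 0)
})
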