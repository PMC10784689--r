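test_that("zero discrimination gives the closed-form guessing-floor rate", {
  # a = 0, c = 0.5, b irrelevant: P(correct) = c + (1 - c)/2 = 0.75 everywhere
  cfg <- battery_config(
    n_subjects = 200,
    tasks = tibble::tibble(task_id = "flat", n_trials = 240L, chance = 0.5,
                           loading = 0, discrimination = 0, difficulty_sd = 0),
    covariates = NULL, missing_rate = 0, seed = 11
  )
  sim <- simulate_battery(cfg)
  p_hat <- mean(sim$responses$correct)
  n_obs <- nrow(sim$responses)
  se <- sqrt(0.75 * 0.25 / n_obs)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("per-trial success frequency matches the closed-form probability", {
  # one specific trial at n_subjects = 2000, binomial check against the
  # model probability computed from the drawn latents and difficulty
  cfg <- battery_config(
    n_subjects = 2000,
    tasks = tibble::tibble(task_id = "T", n_trials = 2L, chance = 0.5,
                           loading = 0.6, discrimination = 1.5, difficulty_sd = 1),
    covariates = NULL, missing_rate = 0, seed = 21
  )
  sim <- simulate_battery(cfg)
  b1 <- sim$truth$difficulties$T[1]
  ability <- 0.6 * sim$truth$theta + sqrt(1 - 0.36) * sim$truth$s[, "T"]
  p_i <- 0.5 + 0.5 * stats::plogis(1.5 * (ability - b1))
  obs <- sim$responses$correct[sim$responses$trial_id == "T_t001"]
  ix <- match(sim$responses$subject_id[sim$responses$trial_id == "T_t001"],
              sim$truth$subjects)
  expected <- mean(p_i[ix])
  se <- sqrt(sum(p_i * (1 - p_i))) / length(p_i)
  expect_lt(abs(mean(obs) - expected), 4 * se)
})

test_that("zero loadings give independent tasks", {
  cfg <- battery_config(n_subjects = 500, tasks = default_tasks(loading = 0),
                        covariates = NULL, missing_rate = 0, seed = 31)
  sim <- simulate_battery(cfg)
  ct <- between_task_correlations(sim$responses, n_boot = 0, seed = 1)
  # 3 standard errors of a null correlation at n = 500
  expect_true(all(abs(ct$r) < 3 / sqrt(500 - 3)))
})

test_that("generation is deterministic and stable under roster extension", {
  cfg <- battery_config(n_subjects = 10, seed = 99)
  a <- simulate_battery(cfg)
  b <- simulate_battery(cfg)
  expect_identical(tibble::as_tibble(a$responses), tibble::as_tibble(b$responses))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(a$responses, f1)
  write_responses(b$responses, f2)
  expect_identical(readLines(f1), readLines(f2))

  # counter-based subseeds: adding a sixth task leaves the first five
  # tasks' draws untouched
  tk6 <- dplyr::bind_rows(default_tasks(), tibble::tibble(
    task_id = "extra", n_trials = 20L, chance = 0.5, loading = 0.5,
    discrimination = 1, difficulty_sd = 1
  ))
  cfg6 <- battery_config(n_subjects = 10, tasks = tk6, seed = 99)
  c6 <- simulate_battery(cfg6)
  cols <- c("subject_id", "task_id", "trial_id", "correct", "missing")
  orig <- as.data.frame(a$responses)[, cols]
  ext <- as.data.frame(c6$responses)
  ext <- ext[ext$task_id != "extra", cols]
  ord <- function(d) {
    d <- d[order(d$subject_id, d$task_id, d$trial_id), ]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(ext), ord(orig))
})

test_that("between-task correlation rises with the shared loading", {
  rs <- vapply(c(0, 0.4, 0.8), function(lam) {
    cfg <- battery_config(
      n_subjects = 1000,
      tasks = default_tasks(loading = lam)[c(1, 2), ],
      covariates = NULL, missing_rate = 0, seed = 41
    )
    sim <- simulate_battery(cfg)
    between_task_correlations(sim$responses, n_boot = 0, seed = 1)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("split-half reliability grows with trial count (Spearman-Brown direction)", {
  z_for <- function(n_trials, seed) {
    cfg <- battery_config(
      n_subjects = 150,
      tasks = tibble::tibble(task_id = "T", n_trials = n_trials, chance = 0.5,
                             loading = 0.6, discrimination = 1.5, difficulty_sd = 1),
      covariates = NULL, missing_rate = 0, seed = seed
    )
    sim <- simulate_battery(cfg)
    sh <- split_half_reliability(sim$responses, n_iter = 30, n_perm = 0, seed = seed)
    sh$summary$mean_z[sh$summary$task_id == "T"]
  }
  diffs <- vapply(1:8, function(s) z_for(160L, 500 + s) - z_for(40L, 500 + s), numeric(1))
  expect_gt(mean(diffs > 0), 0.7)
  expect_gt(mean(diffs), 0)
})

test_that("covariate scores follow their loadings", {
  cfg <- battery_config(
    n_subjects = 400,
    covariates = tibble::tibble(
      covariate_id = c("pure_noise", "theta_meter"),
      loading_on_general = c(0, 1), loading_on_spatial = 0, noise_sd = c(1, 0)
    ),
    seed = 51
  )
  sim <- simulate_battery(cfg)
  cv <- simulate_covariates(sim)
  wide <- tidyr::pivot_wider(cv, names_from = "covariate_id", values_from = "score")
  stopifnot(identical(wide$subject_id, sim$truth$subjects))
  # noiseless general covariate is exactly standardized theta
  expect_equal(wide$theta_meter, as.numeric(scale(sim$truth$theta)), tolerance = 1e-12)
  # pure-noise covariate is uncorrelated with battery accuracy at large n
  acc <- score_accuracy(sim$responses) |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(accuracy))
  r <- cor(wide$pure_noise[match(acc$subject_id, wide$subject_id)], acc$m)
  expect_lt(abs(r), 3 / sqrt(400 - 3))
  # determinism
  expect_identical(simulate_covariates(sim), cv)
})

test_that("degenerate covariate configs are rejected", {
  expect_error(battery_config(covariates = tibble::tibble(
    covariate_id = "dead", loading_on_general = 0, loading_on_spatial = 0, noise_sd = 0
  )), "zero variance")
  expect_error(battery_config(tasks = default_tasks(loading = 1.2)), "loading")
  expect_error(battery_config(tasks = default_tasks(discrimination = -1)), ">= 0")
})

test_that("design enumerations reproduce the stimulus tallies", {
  expect_equal(nrow(design_toppling_towers()), 48L)
  expect_equal(as.vector(table(design_toppling_towers()$falls_to)), c(24L, 24L))
  expect_equal(nrow(design_bouncing_discs()), 64L)
  bb <- design_bowling_balls()
  expect_equal(nrow(bb), 240L)
  expect_equal(length(unique(bb$stimulus)), 60L)
  expect_equal(nrow(unique(bb[, c("incoming_lb", "stationary_lb")])), 30L)
  expect_true(all(bb$incoming_lb != bb$stationary_lb))
  expect_equal(nrow(design_weightlifting()), 40L)
  expect_equal(nrow(design_stay_or_go()), 224L)
  ramp <- design_ramp_knock_off()
  expect_equal(nrow(ramp), 58L)
  expect_equal(sum(ramp$knocked_off), 29L) # outcomes balanced 50/50
})
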