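# Shared fixtures, all built in code at test time.

# Tiny long-format response table: `correct` is a subjects x trials 0/1
# matrix (one task), `missing` an optional logical matrix of the same shape.
toy_responses <- function(correct, task_id = "taskA", missing = NULL,
                          chance = 0.5, subjects = NULL) {
  n <- nrow(correct)
  m <- ncol(correct)
  subjects <- subjects %||% sprintf("s%02d", seq_len(n))
  if (is.null(missing)) missing <- matrix(FALSE, n, m)
  trial_ids <- rep(sprintf("%s_t%02d", task_id, seq_len(m)), each = n)
  df <- tibble::tibble(
    subject_id = rep(subjects, times = m),
    task_id = task_id,
    trial_id = trial_ids,
    correct = as.vector(correct),
    missing = as.vector(missing)
  )
  phys_responses(df, chance = stats::setNames(chance, task_id))
}

# Stack several single-task toy tables into one battery.
toy_battery <- function(...) {
  parts <- list(...)
  chance <- unlist(lapply(parts, chance_levels))
  df <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
  phys_responses(df, chance = chance)
}

# Null battery: no subject-level variance (zero discrimination makes every
# trial an independent Bernoulli(c + (1 - c)/2) draw for every subject).
null_battery <- function(n_subjects = 100, seed = 1, missing_rate = 0.02) {
  simulate_battery(battery_config(
    n_subjects = n_subjects,
    tasks = default_tasks(discrimination = 0),
    covariates = NULL,
    missing_rate = missing_rate,
    seed = seed
  ))$responses
}

# Wide subjects x tasks accuracy matrix (mirrors the package-internal
# representation, recomputed independently here).
accuracy_wide_for_test <- function(responses) {
  acc <- score_accuracy(responses)
  wide <- tidyr::pivot_wider(acc[, c("subject_id", "task_id", "accuracy")],
                             names_from = "task_id", values_from = "accuracy")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject_id
  m
}

# Matrix of accuracies whose *sample* correlation matrix is exactly R:
# orthonormal columns remixed through the Cholesky factor of R.
exact_corr_data <- function(R, n = 200, seed = 1) {
  p <- ncol(R)
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    # orthonormal columns that are also orthogonal to the constant vector,
    # hence exactly mean-zero and exactly uncorrelated
    Q <- qr.Q(qr(cbind(1, X)))[, -1, drop = FALSE]
    Z <- scale(Q)
    M <- Z %*% chol(R)
    colnames(M) <- paste0("task", seq_len(p))
    M
  })
}
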