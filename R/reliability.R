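#' Randomly split every task's trials into two balanced halves
#'
#' One joint split per call: each task's trial list is partitioned uniformly
#' at random into disjoint halves whose sizes differ by at most one, and the
#' same split applies to every subject. Downstream analyses (the combined
#' battery measure and the cross-validated factor analysis) rely on all
#' tasks being split within the same iteration.
#'
#' @param x A `phys_responses` object.
#' @param seed Integer seed; the split is reproducible from it.
#' @return A tibble with columns `task_id`, `trial_id`, `half` (`"a"`/`"b"`).
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 5, seed = 1))$responses
#' split_trials(rm, seed = 2)
#' @export
split_trials <- function(x, seed = 1L) {
  bm <- battery_matrix(x)
  sizes <- lengths(bm$task_cols)
  if (any(sizes < 2L)) {
    abort(sprintf("Task '%s' has fewer than 2 trials; cannot split.",
                  names(sizes)[which(sizes < 2L)[1]]))
  }
  halves <- with_seed_(seed, make_split(bm))
  purrr::map_dfr(bm$tasks, function(t) {
    ids <- bm$trial_ids[[t]]
    cols <- bm$task_cols[[t]]
    tibble(
      task_id = t,
      trial_id = ids[match(c(halves[[t]]$a, halves[[t]]$b), cols)],
      half = rep(c("a", "b"), c(length(halves[[t]]$a), length(halves[[t]]$b)))
    )
  })
}

# Draw one balanced split (list of a/b column-index vectors per task).
# Consumes one `sample` call per task from the current RNG stream.
make_split <- function(bm) {
  out <- lapply(bm$task_cols, function(cols) {
    n <- length(cols)
    a <- sort(sample(cols, ceiling(n / 2)))
    b <- setdiff(cols, a)
    stopifnot(length(a) + length(b) == n, abs(length(a) - length(b)) <= 1L)
    list(a = a, b = b)
  })
  names(out) <- bm$tasks
  out
}

# Half accuracies for one split via a single matrix product.
# Returns list(a, b): subjects x tasks accuracy matrices (NaN where a subject
# has no observed trials in a half).
half_accuracies <- function(bm, halves) {
  tcount <- length(bm$tasks)
  S <- matrix(0, ncol(bm$m0), 2L * tcount)
  for (t in seq_len(tcount)) {
    S[halves[[t]]$a, 2L * t - 1L] <- 1
    S[halves[[t]]$b, 2L * t] <- 1
  }
  sums <- bm$m0 %*% S
  cnts <- bm$obs %*% S
  acc <- sums / cnts # 0/0 -> NaN for unobserved cells
  ai <- seq(1L, 2L * tcount, by = 2L)
  list(
    a = matrix(acc[, ai], ncol = tcount, dimnames = list(NULL, bm$tasks)),
    b = matrix(acc[, ai + 1L], ncol = tcount, dimnames = list(NULL, bm$tasks))
  )
}

# z statistics (per task + combined) for one pair of half-accuracy matrices,
# optionally permuting the subject alignment of half b.
split_z_stats <- function(ha, perm = NULL) {
  b <- if (is.null(perm)) ha$b else ha$b[perm, , drop = FALSE]
  zs <- vapply(seq_len(ncol(ha$a)), function(t) cor_z_safe(ha$a[, t], b[, t]), numeric(1))
  comb_a <- rowMeans(ha$a)
  comb_b <- rowMeans(b)
  c(zs, combined = cor_z_safe(comb_a, comb_b))
}

# Enumerate all distinct balanced splits of each task (complement pairs
# counted once for even sizes) and return the per-task x split z matrix plus
# combined, averaging over the full Cartesian product when several tasks are
# present. Only feasible for tiny fixtures; callers guard the size.
exhaustive_split_z <- function(bm) {
  per_task <- lapply(bm$task_cols, function(cols) {
    n <- length(cols)
    ka <- ceiling(n / 2)
    combos <- combn(cols, ka, simplify = FALSE)
    if (n %% 2L == 0L) {
      seen <- character()
      keep <- logical(length(combos))
      for (i in seq_along(combos)) {
        key_a <- paste(combos[[i]], collapse = ",")
        key_b <- paste(setdiff(cols, combos[[i]]), collapse = ",")
        if (!(key_a %in% seen) && !(key_b %in% seen)) keep[i] <- TRUE
        seen <- c(seen, key_a)
      }
      combos <- combos[keep]
    }
    lapply(combos, function(a) list(a = a, b = setdiff(cols, a)))
  })
  grid <- expand.grid(lapply(per_task, seq_along))
  z <- matrix(NA_real_, nrow(grid), length(bm$tasks) + 1L,
              dimnames = list(NULL, c(bm$tasks, "combined")))
  for (g in seq_len(nrow(grid))) {
    halves <- lapply(seq_along(per_task), function(t) per_task[[t]][[grid[g, t]]])
    names(halves) <- bm$tasks
    z[g, ] <- split_z_stats(half_accuracies(bm, halves))
  }
  z
}

#' Iterated split-half reliability with a permutation null
#'
#' For each iteration, every task's trials are split into two random
#' balanced halves, each subject is scored on each half, and subjects'
#' half-A accuracy is correlated with their half-B accuracy (Fisher z) per
#' task. A combined battery measure averages the per-task half accuracies
#' across tasks before correlating. The reported `mean_z` averages the
#' iterated z distribution (so no single unrepresentative split drives the
#' estimate), the confidence interval takes its 2.5th/97.5th percentiles,
#' and the p-value compares `mean_z` to a null distribution built by
#' re-splitting and shuffling the subject correspondence between halves on
#' each of `n_perm` null iterations.
#'
#' Iterations in which a half has zero variance across subjects are flagged
#' and excluded from the mean, with the count reported; if more than half of
#' the iterations degenerate the run errors.
#'
#' Because trials are split in half, this is a conservative estimate of each
#' task's full-length reliability (no Spearman-Brown correction is applied).
#'
#' @param x A `phys_responses` object with at least 3 subjects.
#' @param n_iter Number of random splits (reference analyses use 10,000).
#' @param n_perm Number of null (shuffled) iterations.
#' @param seed Master integer seed; split seeds are drawn from it first, so
#'   engines sharing a seed share splits.
#' @param exhaustive If `TRUE`, enumerate all distinct balanced splits
#'   instead of sampling (tiny fixtures only; errors above
#'   `max_exhaustive` split combinations). No permutation p is computed in
#'   this mode.
#' @param max_exhaustive Cap on the number of enumerated split combinations.
#' @return An object of class `split_half_result`; `tidy()` returns the
#'   per-task summary (tasks plus a `"combined"` row) with columns `task_id`,
#'   `mean_z`, `sd_z`, `ci_low`, `ci_high`, `mean_r`, `r_squared`, `p`,
#'   `n_used`, `n_degenerate`.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 40, seed = 3))$responses
#' res <- split_half_reliability(rm, n_iter = 50, n_perm = 50, seed = 9)
#' tidy(res)
#' @export
split_half_reliability <- function(x, n_iter = 1000L, n_perm = 1000L, seed = 1L,
                                   exhaustive = FALSE, max_exhaustive = 20000L) {
  bm <- battery_matrix(x)
  if (length(bm$subjects) < 3L) abort("Need at least 3 subjects.")
  sizes <- lengths(bm$task_cols)
  if (any(sizes < 2L)) {
    abort(sprintf("Task '%s' has fewer than 2 trials.", names(sizes)[which(sizes < 2L)[1]]))
  }

  if (exhaustive) {
    n_splits <- prod(vapply(sizes, function(n) {
      k <- choose(n, ceiling(n / 2))
      if (n %% 2L == 0L) k / 2 else k
    }, numeric(1)))
    if (n_splits > max_exhaustive) {
      abort(sprintf("Exhaustive enumeration would need %.0f splits (cap %d).",
                    n_splits, max_exhaustive))
    }
    z <- exhaustive_split_z(bm)
    null_z <- NULL
  } else {
    n_iter <- assert_count(n_iter, "n_iter")
    split_seeds <- iteration_seeds(seed, n_iter, "split")
    z <- matrix(NA_real_, n_iter, length(bm$tasks) + 1L,
                dimnames = list(NULL, c(bm$tasks, "combined")))
    for (i in seq_len(n_iter)) {
      halves <- with_seed_(split_seeds[i], make_split(bm))
      z[i, ] <- split_z_stats(half_accuracies(bm, halves))
    }
    null_z <- NULL
    if (n_perm > 0) {
      n_perm <- assert_count(n_perm, "n_perm")
      perm_seeds <- iteration_seeds(seed, n_perm, "perm")
      null_z <- matrix(NA_real_, n_perm, ncol(z), dimnames = dimnames(z))
      n <- length(bm$subjects)
      for (j in seq_len(n_perm)) {
        null_z[j, ] <- with_seed_(perm_seeds[j], {
          halves <- make_split(bm)
          split_z_stats(half_accuracies(bm, halves), perm = sample.int(n))
        })
      }
    }
  }

  summarise_split_half(z, null_z, n_perm = if (is.null(null_z)) 0L else nrow(null_z),
                       seed = seed, exhaustive = exhaustive)
}

summarise_split_half <- function(z, null_z, n_perm, seed, exhaustive = FALSE) {
  cols <- colnames(z)
  summary <- purrr::map_dfr(cols, function(cn) {
    v <- z[, cn]
    ok <- !is.na(v)
    if (mean(ok) <= 0.5) {
      abort(sprintf("More than 50%% of iterations degenerate for '%s'.", cn))
    }
    v <- v[ok]
    mz <- mean(v)
    p <- NA_real_
    if (!is.null(null_z)) {
      nv <- null_z[, cn]
      nv <- nv[!is.na(nv)]
      if (length(nv) > 0) p <- permutation_pvalue(mz, nv)
    }
    tibble(
      task_id = cn, mean_z = mz, sd_z = if (length(v) > 1) sd(v) else NA_real_,
      ci_low = as.numeric(quantile(v, 0.025)),
      ci_high = as.numeric(quantile(v, 0.975)),
      mean_r = inv_fisher_z(mz), r_squared = inv_fisher_z(mz)^2,
      p = p, n_used = length(v), n_degenerate = sum(!ok)
    )
  })
  structure(list(
    summary = summary, z_draws = z, null_draws = null_z,
    n_iter = nrow(z), n_perm = n_perm, seed = seed, exhaustive = exhaustive
  ), class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("<split_half_result> %d iterations, %d permutations%s\n",
              x$n_iter, x$n_perm, if (x$exhaustive) " (exhaustive splits)" else ""))
  print(x$summary)
  invisible(x)
}

#' @rdname split_half_reliability
#' @param x,object A `split_half_result`.
#' @param ... Unused.
#' @method tidy split_half_result
#' @export
tidy.split_half_result <- function(x, ...) x$summary

#' @rdname split_half_reliability
#' @method glance split_half_result
#' @export
glance.split_half_result <- function(x, ...) {
  comb <- x$summary[x$summary$task_id == "combined", ]
  tibble(
    mean_z = comb$mean_z, ci_low = comb$ci_low, ci_high = comb$ci_high,
    p = comb$p, n_iter = x$n_iter, n_perm = x$n_perm,
    n_degenerate = sum(x$summary$n_degenerate)
  )
}

#' @rdname split_half_reliability
#' @method autoplot split_half_result
#' @export
autoplot.split_half_result <- function(object, ...) {
  d <- object$summary
  d$task_id <- factor(d$task_id, levels = d$task_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$task_id, y = .data$mean_z)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "split-half reliability (Fisher z)") +
    ggplot2::theme_minimal()
}

#' Between-task correlations with bootstrap confidence intervals
#'
#' Pearson correlations between subjects' task accuracies for every task
#' pair, with Fisher z, \eqn{R^2}, and a 95% percentile interval from
#' resampling subjects with replacement. Undefined accuracy cells are
#' deleted pairwise, so a subject excluded from one task still contributes
#' to the other pairs. Within-task (diagonal) reliabilities are the province
#' of [split_half_reliability()] and are not computed here.
#'
#' @param x A `phys_responses` object or a long accuracy tibble from
#'   [score_accuracy()].
#' @param n_boot Number of bootstrap resamples (reference analyses use
#'   10,000).
#' @param seed Integer seed for the bootstrap stream.
#' @param conf Confidence level.
#' @return A tibble with one row per unordered task pair: `task_a`,
#'   `task_b`, `n`, `r`, `z`, `r_squared`, `ci_low`, `ci_high` (z scale),
#'   `clamped`.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 60, seed = 5))$responses
#' between_task_correlations(rm, n_boot = 200, seed = 1)
#' @export
between_task_correlations <- function(x, n_boot = 1000L, seed = 1L, conf = 0.95) {
  acc <- if (inherits(x, "phys_responses")) score_accuracy(x) else as_tibble(x)
  W <- accuracy_wide(acc)
  tasks <- colnames(W)
  if (length(tasks) < 2L) abort("Need at least 2 tasks.")
  n_boot <- assert_count(n_boot, "n_boot", min = 0L)
  pairs <- combn(tasks, 2L, simplify = FALSE)
  boot_seeds <- iteration_seeds(seed, length(pairs), "boot")
  purrr::map_dfr(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    xi <- W[, pr[1]]
    yi <- W[, pr[2]]
    keep <- is.finite(xi) & is.finite(yi)
    if (sum(keep) < 3L) abort(sprintf("Fewer than 3 complete subjects for pair %s-%s.", pr[1], pr[2]))
    xi <- xi[keep]
    yi <- yi[keep]
    if (var(xi) == 0) abort(sprintf("Task '%s' has zero variance.", pr[1]))
    if (var(yi) == 0) abort(sprintf("Task '%s' has zero variance.", pr[2]))
    st <- correlation_stats(xi, yi, n_boot = n_boot, conf = conf, seed = boot_seeds[k])
    tibble(task_a = pr[1], task_b = pr[2], st)
  })
}

#' Bootstrap test for the difference between two dependent correlations
#'
#' Resamples subjects with replacement; on each replicate both correlations
#' are recomputed and the difference of their Fisher z values recorded. The
#' two-tailed p-value is `2 * min(P(dz <= 0), P(dz >= 0))` with the add-one
#' correction. Replicates where either correlation degenerates (zero
#' variance) are redrawn, with the count reported; more than 10% redraws is
#' an error.
#'
#' @param data A data frame of subject-level scores (one row per subject).
#' @param pair1,pair2 Length-2 character vectors naming the two score
#'   columns of each correlation target.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A one-row tibble: `z1`, `z2`, `delta_z` (z1 - z2), `ci_low`,
#'   `ci_high` (percentile CI of the difference), `p`, `n`, `n_boot`,
#'   `n_redrawn`.
#' @examples
#' d <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50))
#' d$b <- d$a + rnorm(50, sd = 0.5)
#' correlation_difference_test(d, c("a", "b"), c("a", "c"), n_boot = 200, seed = 1)
#' @export
correlation_difference_test <- function(data, pair1, pair2, n_boot = 1000L, seed = 1L) {
  data <- as_tibble(data)
  cols <- unique(c(pair1, pair2))
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) abort(paste0("Columns not found: ", paste(miss, collapse = ", ")))
  keep <- stats::complete.cases(data[, cols])
  data <- data[keep, ]
  n <- nrow(data)
  if (n < 4L) abort("Need at least 4 complete subjects.")
  n_boot <- assert_count(n_boot, "n_boot")
  z_of <- function(d, pr) cor_z_safe(d[[pr[1]]], d[[pr[2]]])
  z1 <- z_of(data, pair1)
  z2 <- z_of(data, pair2)
  if (is.na(z1) || is.na(z2)) abort("Degenerate input: a correlation target has zero variance.")
  res <- with_seed_(seed, {
    dz <- numeric(n_boot)
    redrawn <- 0L
    for (i in seq_len(n_boot)) {
      repeat {
        ix <- sample.int(n, replace = TRUE)
        b1 <- z_of(data[ix, ], pair1)
        b2 <- z_of(data[ix, ], pair2)
        if (!is.na(b1) && !is.na(b2)) break
        redrawn <- redrawn + 1L
        if (redrawn > 0.1 * n_boot) {
          abort("More than 10% of bootstrap replicates degenerate.")
        }
      }
      dz[i] <- b1 - b2
    }
    list(dz = dz, redrawn = redrawn)
  })
  p_low <- (1 + sum(res$dz <= 0)) / (1 + n_boot)
  p_high <- (1 + sum(res$dz >= 0)) / (1 + n_boot)
  tibble(
    z1 = z1, z2 = z2, delta_z = z1 - z2,
    ci_low = as.numeric(quantile(res$dz, 0.025)),
    ci_high = as.numeric(quantile(res$dz, 0.975)),
    p = min(1, 2 * min(p_low, p_high)),
    n = n, n_boot = n_boot, n_redrawn = res$redrawn
  )
}
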