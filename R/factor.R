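#' Extract a single common factor from task accuracies
#'
#' Fits a one-factor model to the Pearson correlation matrix of task
#' accuracies by iterated principal-axis factoring: initial communalities
#' are squared multiple correlations, the reduced correlation matrix is
#' eigendecomposed, the first factor retained, and communalities updated
#' until the largest change falls below `tol` (capped at `max_iter`
#' iterations). Subject factor scores use the regression (Thurstone) method,
#' and the solution's sign is oriented so the loading sum is nonnegative.
#' Heywood cases (communality above 1) are clamped to 0.9999 and flagged.
#'
#' Maximum-likelihood extraction via [stats::factanal()] is available with
#' `method = "ml"`.
#'
#' @param x A long accuracy tibble from [score_accuracy()], a wide
#'   subjects-by-tasks matrix/data frame of accuracies, or a
#'   `phys_responses` object (scored internally). Subjects with an undefined
#'   accuracy in any task are dropped before fitting.
#' @param method `"paf"` (iterated principal axis; default) or `"ml"`.
#' @param tol Convergence tolerance on the largest communality change.
#' @param max_iter Iteration cap (default 50, the convention of mature
#'   factor-analysis implementations; on data with no common variance the
#'   communality update drifts indefinitely because the one-factor model is
#'   unidentified there, so a modest cap is part of the estimator).
#'   Non-convergence returns the current solution with `converged = FALSE`
#'   and a warning.
#' @return An object of class `factor_solution` with elements `loadings`,
#'   `uniquenesses` (named per task), `scores` (tibble `subject_id`,
#'   `score`, standardized), `converged`, `n_iterations`, `heywood`,
#'   `method`. `tidy()` gives per-task loadings/uniquenesses; `glance()`
#'   gives fit metadata.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 80, seed = 11))$responses
#' fit <- extract_single_factor(rm)
#' tidy(fit)
#' @export
extract_single_factor <- function(x, method = c("paf", "ml"),
                                  tol = 1e-6, max_iter = 50L) {
  method <- match.arg(method)
  W <- as_accuracy_matrix(x)
  keep <- stats::complete.cases(W) & apply(is.finite(W), 1, all)
  W <- W[keep, , drop = FALSE]
  tasks <- colnames(W)
  if (length(tasks) < 3L) abort("Need at least 3 tasks.")
  if (nrow(W) < length(tasks) + 2L) abort("Need at least (tasks + 2) subjects.")
  v <- apply(W, 2, var)
  if (any(v == 0)) abort(sprintf("Task '%s' has zero variance.", tasks[which(v == 0)[1]]))
  R <- cor(W)

  if (method == "paf") {
    fit <- paf_one_factor(R, tol = tol, max_iter = max_iter)
  } else {
    fa <- stats::factanal(covmat = R, factors = 1L, n.obs = nrow(W))
    fit <- list(loadings = as.numeric(fa$loadings), converged = fa$converged %||% TRUE,
                n_iterations = NA_integer_, heywood = FALSE)
  }
  lambda <- fit$loadings
  if (sum(lambda) < 0) lambda <- -lambda
  names(lambda) <- tasks
  uniq <- pmax(0, 1 - lambda^2)
  if (!fit$converged) {
    warn(sprintf("Principal-axis factoring did not converge in %d iterations.", max_iter))
  }

  # regression (Thurstone) factor scores on standardized accuracies
  Z <- scale(W)
  wts <- solve(R, lambda)
  raw <- as.numeric(Z %*% wts)
  scores <- tibble(
    subject_id = rownames(W) %||% as.character(seq_len(nrow(W))),
    score = as.numeric(scale(raw))
  )
  structure(list(
    loadings = lambda, uniquenesses = uniq, scores = scores,
    converged = fit$converged, n_iterations = fit$n_iterations,
    heywood = fit$heywood, method = method, n_subjects = nrow(W)
  ), class = "factor_solution")
}

# Iterated principal-axis factoring, one factor, on a correlation matrix.
paf_one_factor <- function(R, tol = 1e-6, max_iter = 50L) {
  p <- ncol(R)
  # squared multiple correlations as starting communalities; no lower floor,
  # so data with no common variance stay at the minimal (near-zero) solution
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h <- if (is.null(Rinv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Rinv), 0), 0.9999)
  heywood <- FALSE
  converged <- FALSE
  it <- 0L
  lambda <- rep(0, p)
  while (it < max_iter) {
    it <- it + 1L
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    ev1 <- max(e$values[1], 0)
    lambda <- sqrt(ev1) * e$vectors[, 1]
    h_new <- lambda^2
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 0.9999)
      lambda <- sign(lambda) * sqrt(h_new)
    }
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  list(loadings = lambda, converged = converged, n_iterations = it, heywood = heywood)
}

as_accuracy_matrix <- function(x) {
  if (inherits(x, "phys_responses")) {
    accuracy_wide(score_accuracy(x))
  } else if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("task", seq_len(ncol(x)))
    x
  } else if (is.data.frame(x) && all(c("subject_id", "task_id", "accuracy") %in% names(x))) {
    accuracy_wide(x)
  } else if (is.data.frame(x)) {
    m <- as.matrix(x)
    if (!is.numeric(m)) abort("Wide accuracy data must be numeric.")
    m
  } else {
    abort("Cannot interpret `x` as accuracies.")
  }
}

#' @rdname extract_single_factor
#' @param x,object A `factor_solution`.
#' @param ... Unused.
#' @method tidy factor_solution
#' @export
tidy.factor_solution <- function(x, ...) {
  tibble(task_id = names(x$loadings), loading = as.numeric(x$loadings),
         uniqueness = as.numeric(x$uniquenesses))
}

#' @rdname extract_single_factor
#' @method glance factor_solution
#' @export
glance.factor_solution <- function(x, ...) {
  tibble(
    converged = x$converged, n_iterations = x$n_iterations,
    heywood = x$heywood, method = x$method, n_subjects = x$n_subjects,
    prop_variance = sum(x$loadings^2) / length(x$loadings)
  )
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> method=%s, converged=%s (%s iterations)\n",
              x$method, x$converged,
              if (is.na(x$n_iterations)) "?" else x$n_iterations))
  print(tidy(x))
  invisible(x)
}

#' Cross-validated single-factor variance per task
#'
#' On each iteration the battery's trials are split into two halves; a
#' single factor is extracted from the half-A task accuracies, its
#' regression scores are correlated with each task's *left-out* half-B
#' accuracy, and the correlations are Fisher-z transformed. The per-task
#' mean z over iterations measures how much of each task's individual
#' variation the common factor captures; the permutation p shuffles the
#' subject alignment between factor scores and left-out accuracies. The
#' `ratio_to_reliability` column divides the factor \eqn{R^2} by the task's
#' own split-half \eqn{R^2} (computed with the identical split-seed stream,
#' so split noise cancels from the comparison): values near 1 mean the
#' factor captures essentially all the explainable variance in that task;
#' values well below 1 expose a task-specific reliable component.
#'
#' @inheritParams split_half_reliability
#' @param method Factor extraction method, see [extract_single_factor()].
#' @return An object of class `factor_validation`; `tidy()` returns per-task
#'   `mean_z`, `sd_z`, `r_squared`, `p`, `split_half_z`,
#'   `split_half_r_squared`, `ratio_to_reliability`, `n_used`,
#'   `n_degenerate`.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 60, seed = 2))$responses
#' fv <- crossvalidated_factor_variance(rm, n_iter = 30, n_perm = 30, seed = 4)
#' tidy(fv)
#' @export
crossvalidated_factor_variance <- function(x, n_iter = 1000L, n_perm = 1000L,
                                           seed = 1L, method = c("paf", "ml")) {
  method <- match.arg(method)
  bm <- battery_matrix(x)
  if (length(bm$tasks) < 3L) abort("Need at least 3 tasks.")
  if (length(bm$subjects) < 10L) abort("Need at least 10 subjects.")
  n_iter <- assert_count(n_iter, "n_iter")
  n_perm <- assert_count(n_perm, "n_perm", min = 0L)
  split_seeds <- iteration_seeds(seed, n_iter, "split")
  tcount <- length(bm$tasks)
  n <- length(bm$subjects)

  factor_z_one <- function(halves, perm = FALSE) {
    ha <- half_accuracies(bm, halves)
    ok <- stats::complete.cases(ha$a) & apply(is.finite(ha$a), 1, all) &
      stats::complete.cases(ha$b) & apply(is.finite(ha$b), 1, all)
    if (sum(ok) < tcount + 2L) return(rep(NA_real_, tcount))
    A <- ha$a[ok, , drop = FALSE]
    B <- ha$b[ok, , drop = FALSE]
    if (any(apply(A, 2, sd) == 0)) return(rep(NA_real_, tcount))
    fit <- tryCatch(
      suppressWarnings(extract_single_factor(A, method = method)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(rep(NA_real_, tcount))
    sc <- fit$scores$score
    # null: break the subject alignment between scores and left-out halves
    if (isTRUE(perm)) sc <- sample(sc)
    vapply(seq_len(tcount), function(t) cor_z_safe(sc, B[, t]), numeric(1))
  }

  z <- matrix(NA_real_, n_iter, tcount, dimnames = list(NULL, bm$tasks))
  for (i in seq_len(n_iter)) {
    halves <- with_seed_(split_seeds[i], make_split(bm))
    z[i, ] <- factor_z_one(halves)
  }

  null_z <- NULL
  if (n_perm > 0) {
    perm_seeds <- iteration_seeds(seed, n_perm, "perm")
    null_z <- matrix(NA_real_, n_perm, tcount, dimnames = list(NULL, bm$tasks))
    for (j in seq_len(n_perm)) {
      null_z[j, ] <- with_seed_(perm_seeds[j], {
        halves <- make_split(bm)
        factor_z_one(halves, perm = TRUE)
      })
    }
  }

  # split-half reliabilities on the identical split stream
  sh <- split_half_reliability(x, n_iter = n_iter, n_perm = 0L, seed = seed)
  sh_sum <- sh$summary[match(bm$tasks, sh$summary$task_id), ]

  summary <- purrr::map_dfr(seq_len(tcount), function(t) {
    v <- z[, t]
    ok <- !is.na(v)
    if (mean(ok) <= 0.5) abort(sprintf("More than 50%% of iterations degenerate for '%s'.", bm$tasks[t]))
    v <- v[ok]
    mz <- mean(v)
    p <- NA_real_
    if (!is.null(null_z)) {
      nv <- null_z[, t]
      nv <- nv[!is.na(nv)]
      if (length(nv) > 0) p <- permutation_pvalue(mz, nv)
    }
    shz <- sh_sum$mean_z[t]
    r2 <- inv_fisher_z(mz)^2
    shr2 <- inv_fisher_z(shz)^2
    tibble(
      task_id = bm$tasks[t], mean_z = mz, sd_z = sd(v), r_squared = r2, p = p,
      split_half_z = shz, split_half_r_squared = shr2,
      ratio_to_reliability = if (shr2 > 0) r2 / shr2 else NA_real_,
      n_used = length(v), n_degenerate = sum(!ok)
    )
  })
  structure(list(
    summary = summary, z_draws = z, null_draws = null_z,
    split_half = sh, n_iter = n_iter, n_perm = n_perm, seed = seed, method = method
  ), class = "factor_validation")
}

#' @rdname crossvalidated_factor_variance
#' @param x,object A `factor_validation`.
#' @param ... Unused.
#' @method tidy factor_validation
#' @export
tidy.factor_validation <- function(x, ...) x$summary

#' @rdname crossvalidated_factor_variance
#' @method glance factor_validation
#' @export
glance.factor_validation <- function(x, ...) {
  tibble(
    n_iter = x$n_iter, n_perm = x$n_perm, method = x$method,
    mean_ratio = mean(x$summary$ratio_to_reliability, na.rm = TRUE),
    n_degenerate = sum(x$summary$n_degenerate)
  )
}

#' @export
print.factor_validation <- function(x, ...) {
  cat(sprintf("<factor_validation> %d iterations, %d permutations (method=%s)\n",
              x$n_iter, x$n_perm, x$method))
  print(x$summary)
  invisible(x)
}

#' @rdname crossvalidated_factor_variance
#' @method autoplot factor_validation
#' @export
autoplot.factor_validation <- function(object, ...) {
  d <- object$summary |>
    dplyr::select("task_id", factor = "r_squared", `split half` = "split_half_r_squared") |>
    tidyr::pivot_longer(-"task_id", names_to = "source", values_to = "r_squared")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$task_id, y = .data$r_squared,
                                  fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = NULL) +
    ggplot2::theme_minimal()
}
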