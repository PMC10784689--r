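#' Correlate a trial subset's score with full-battery performance
#'
#' Scores every subject on the candidate short form (mean accuracy over the
#' selected trials) and on the full battery, and returns the correlation
#' across subjects. By default both scores are means of per-task means (each
#' task weighted equally, matching the combined battery measure); the full
#' score can instead be the grand mean over all trials. Because the selected
#' trials are contained in the full battery, this correlation carries a
#' part-whole overlap; `exclude_selected = TRUE` scores the "full" battery
#' on the unselected trials only, for an overlap-free diagnostic.
#'
#' @param x A `phys_responses` object.
#' @param subset A tibble with columns `task_id`, `trial_id` (or a named
#'   list of trial-id vectors per task) giving the selected trials.
#' @param subjects Optional character vector restricting the subject set.
#' @param comparison `"mean_of_tasks"` (default) or `"grand_mean"` for the
#'   full-battery score.
#' @param exclude_selected Score the full battery on unselected trials only.
#' @return A one-row tibble from [correlation_stats()].
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 40, seed = 6))$responses
#' sub <- compress_battery(rm, k_per_task = 5, n_iter = 20, holdout_fraction = 0, seed = 2)
#' evaluate_subset(rm, sub$selected)
#' @export
evaluate_subset <- function(x, subset, subjects = NULL,
                            comparison = c("mean_of_tasks", "grand_mean"),
                            exclude_selected = FALSE) {
  comparison <- match.arg(comparison)
  bm <- battery_matrix(x)
  sel <- normalise_subset(subset, bm)
  rows <- if (is.null(subjects)) seq_along(bm$subjects) else {
    ix <- match(subjects, bm$subjects)
    if (anyNA(ix)) abort("Unknown subject in `subjects`.")
    ix
  }
  if (length(rows) < 3L) abort("Need at least 3 subjects.")
  sub_score <- subset_scores(bm, sel, rows)
  full_score <- full_scores(bm, rows, comparison,
                            exclude = if (exclude_selected) sel else NULL)
  correlation_stats(sub_score, full_score)
}

# subset as named list of column indices per task
normalise_subset <- function(subset, bm) {
  if (is.data.frame(subset)) {
    subset <- split(subset$trial_id, factor(subset$task_id, levels = bm$tasks))
    subset <- subset[lengths(subset) > 0]
  }
  miss <- setdiff(names(subset), bm$tasks)
  if (length(miss) > 0) abort(paste0("Unknown tasks in subset: ", paste(miss, collapse = ", ")))
  sel <- lapply(names(subset), function(t) {
    ix <- match(subset[[t]], bm$trial_ids[[t]])
    if (anyNA(ix)) abort(sprintf("Unknown trial id in task '%s'.", t))
    if (anyDuplicated(ix)) abort(sprintf("Duplicate trial id in task '%s'.", t))
    bm$task_cols[[t]][ix]
  })
  names(sel) <- names(subset)
  sel
}

# mean of per-task means over selected columns
subset_scores <- function(bm, sel, rows) {
  per_task <- vapply(sel, function(cols) {
    s <- bm$m0[rows, cols, drop = FALSE]
    o <- bm$obs[rows, cols, drop = FALSE]
    rowSums(s) / rowSums(o)
  }, numeric(length(rows)))
  rowMeans(matrix(per_task, nrow = length(rows)))
}

full_scores <- function(bm, rows, comparison, exclude = NULL) {
  cols_of <- bm$task_cols
  if (!is.null(exclude)) {
    cols_of <- lapply(names(cols_of), function(t) setdiff(cols_of[[t]], exclude[[t]]))
    names(cols_of) <- bm$tasks
    cols_of <- cols_of[lengths(cols_of) > 0]
  }
  if (comparison == "grand_mean") {
    cols <- unlist(cols_of, use.names = FALSE)
    s <- bm$m0[rows, cols, drop = FALSE]
    o <- bm$obs[rows, cols, drop = FALSE]
    rowSums(s) / rowSums(o)
  } else {
    subset_scores(bm, cols_of, rows)
  }
}

#' Compress a battery by cross-validated trial subsampling
#'
#' Short-form construction by pure random search: draw `k_per_task` trials
#' from each task, score every subject on the draw, correlate with
#' full-battery performance, and keep the draw with the highest correlation
#' after `n_iter` iterations (ties broken by first-seen order). With
#' `holdout_fraction > 0`, subjects are split once into a training set used
#' for selection and a validation set on which the winning subset is
#' re-scored — the cross-validated estimate of how much full-battery
#' variance the short form captures in new subjects.
#'
#' With `exhaustive = TRUE` all possible k-per-task draws are enumerated
#' instead (small instances only).
#'
#' @inheritParams evaluate_subset
#' @param k_per_task Number of trials to keep per task (default 10).
#' @param n_iter Number of random draws (reference analyses use 10,000).
#' @param holdout_fraction Fraction of subjects held out for validation
#'   (in `[0, 0.9]`; 0 disables validation, reproducing selection and
#'   evaluation on the same subjects).
#' @param seed Integer seed (subject split and draws).
#' @param exhaustive Enumerate all candidate subsets instead of sampling.
#' @param max_exhaustive Cap on the number of enumerated candidates.
#' @return An object of class `battery_subset`: `selected` (tibble
#'   `task_id`, `trial_id`), `train_correlation` and (when validated)
#'   `validation_correlation` (one-row tibbles), `train_subjects`,
#'   `validation_subjects`, `n_candidates_evaluated`, `train_path` (running
#'   argmax of train r per iteration), `seed`. `tidy()` returns the selected
#'   trials; `glance()` the correlations.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 40, seed = 6))$responses
#' cb <- compress_battery(rm, k_per_task = 5, n_iter = 50, seed = 3)
#' glance(cb)
#' @export
compress_battery <- function(x, k_per_task = 10L, n_iter = 10000L,
                             holdout_fraction = 0.5, seed = 1L,
                             comparison = c("mean_of_tasks", "grand_mean"),
                             exhaustive = FALSE, max_exhaustive = 100000L) {
  comparison <- match.arg(comparison)
  bm <- battery_matrix(x)
  k <- assert_count(k_per_task, "k_per_task")
  holdout_fraction <- assert_fraction(holdout_fraction, "holdout_fraction", 0, 0.9)
  sizes <- lengths(bm$task_cols)
  if (any(k > sizes)) {
    abort(sprintf("k_per_task = %d exceeds the %d trials of task '%s'.",
                  k, min(sizes), names(sizes)[which(k > sizes)[1]]))
  }
  n <- length(bm$subjects)

  train_rows <- seq_len(n)
  valid_rows <- integer()
  if (holdout_fraction > 0) {
    n_valid <- round(holdout_fraction * n)
    valid_rows <- with_seed_(seed, sort(sample.int(n, n_valid)))
    train_rows <- setdiff(seq_len(n), valid_rows)
  }
  if (length(train_rows) < 3L) abort("Fewer than 3 training subjects.")
  full_train <- full_scores(bm, train_rows, comparison)

  score_draw <- function(sel) {
    s <- subset_scores(bm, sel, train_rows)
    keep <- is.finite(s) & is.finite(full_train)
    if (sum(keep) < 3L) return(NA_real_)
    if (sd(s[keep]) == 0 || sd(full_train[keep]) == 0) return(NA_real_)
    cor(s[keep], full_train[keep])
  }

  if (exhaustive) {
    combos <- lapply(bm$task_cols, function(cols) combn(cols, k, simplify = FALSE))
    n_cand <- prod(lengths(combos))
    if (n_cand > max_exhaustive) {
      abort(sprintf("Exhaustive search would evaluate %.0f candidates (cap %d).",
                    n_cand, max_exhaustive))
    }
    grid <- expand.grid(lapply(combos, seq_along))
    best_r <- -Inf
    best_sel <- NULL
    path <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      sel <- lapply(seq_along(combos), function(t) combos[[t]][[grid[g, t]]])
      names(sel) <- bm$tasks
      r <- score_draw(sel)
      if (!is.na(r) && r > best_r) {
        best_r <- r
        best_sel <- sel
      }
      path[g] <- best_r
    }
    n_eval <- nrow(grid)
  } else {
    n_iter <- assert_count(n_iter, "n_iter")
    draw_seeds <- iteration_seeds(seed, n_iter, "draw")
    best_r <- -Inf
    best_sel <- NULL
    path <- numeric(n_iter)
    for (g in seq_len(n_iter)) {
      sel <- with_seed_(draw_seeds[g], lapply(bm$task_cols, function(cols) sort(sample(cols, k))))
      names(sel) <- bm$tasks
      r <- score_draw(sel)
      if (!is.na(r) && r > best_r) {
        best_r <- r
        best_sel <- sel
      }
      path[g] <- best_r
    }
    n_eval <- n_iter
  }
  if (is.null(best_sel)) abort("Every candidate subset was degenerate.")
  stopifnot(all(lengths(best_sel) == k))

  selected <- purrr::map_dfr(names(best_sel), function(t) {
    tibble(task_id = t,
           trial_id = bm$trial_ids[[t]][match(best_sel[[t]], bm$task_cols[[t]])])
  })
  train_cor <- correlation_stats(subset_scores(bm, best_sel, train_rows), full_train)
  validation_cor <- NULL
  if (length(valid_rows) >= 3L) {
    sv <- subset_scores(bm, best_sel, valid_rows)
    fv <- full_scores(bm, valid_rows, comparison)
    validation_cor <- tryCatch(correlation_stats(sv, fv), error = function(e) NULL)
  } else if (holdout_fraction > 0) {
    warn("Fewer than 3 validation subjects; validation skipped.")
  }
  structure(list(
    selected = selected, k_per_task = k,
    train_correlation = train_cor, validation_correlation = validation_cor,
    train_subjects = bm$subjects[train_rows],
    validation_subjects = bm$subjects[valid_rows],
    n_candidates_evaluated = n_eval, train_path = path,
    comparison = comparison, seed = seed
  ), class = "battery_subset")
}

#' @rdname compress_battery
#' @param x,object A `battery_subset`.
#' @param ... Unused.
#' @method tidy battery_subset
#' @export
tidy.battery_subset <- function(x, ...) x$selected

#' @rdname compress_battery
#' @method glance battery_subset
#' @export
glance.battery_subset <- function(x, ...) {
  out <- tibble(
    k_per_task = x$k_per_task,
    n_candidates_evaluated = x$n_candidates_evaluated,
    train_r = x$train_correlation$r,
    train_r_squared = x$train_correlation$r_squared,
    validation_r = NA_real_, validation_r_squared = NA_real_
  )
  if (!is.null(x$validation_correlation)) {
    out$validation_r <- x$validation_correlation$r
    out$validation_r_squared <- x$validation_correlation$r_squared
  }
  out
}

#' @export
print.battery_subset <- function(x, ...) {
  cat(sprintf("<battery_subset> %d trials/task, %d candidates evaluated\n",
              x$k_per_task, x$n_candidates_evaluated))
  print(glance(x))
  invisible(x)
}

#' @rdname compress_battery
#' @method autoplot battery_subset
#' @export
autoplot.battery_subset <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$train_path), best_r = object$train_path)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best_r)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::labs(x = "candidate draws", y = "best training correlation") +
    ggplot2::theme_minimal()
}
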