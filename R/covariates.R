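#' Ordinary least squares residuals
#'
#' Plain OLS with an intercept: `y` regressed on the columns of `X`, via the
#' QR decomposition. Used to remove covariate-explained variance from
#' battery scores before re-examining the leftover individual differences.
#'
#' @param y Numeric response vector (one entry per subject).
#' @param X Numeric matrix or data frame of covariate scores (subjects in
#'   rows). An intercept is always added.
#' @return A list with `residuals`, `fitted`, `r_squared`, `coefficients`
#'   (named, intercept first).
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("mrt", "wm")))
#' y <- 0.5 * X[, 1] + rnorm(20)
#' ols_residuals(y, X)$r_squared
#' @export
ols_residuals <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) abort("`y` and `X` must have the same number of rows.")
  if (nrow(X) < ncol(X) + 2L) abort("Need at least (covariates + 2) rows.")
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    abort(paste0("Rank-deficient design; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qx, y)
  fitted <- as.numeric(Xi %*% coefs)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(res^2) / tss
  list(residuals = res, fitted = fitted, r_squared = r2, coefficients = coefs)
}

# Wide standardized covariate matrix for a subject set (error if any subject
# lacks a covariate score).
covariate_matrix <- function(covariates, subjects) {
  cv <- as_tibble(covariates)
  need <- c("subject_id", "covariate_id", "score")
  if (!all(need %in% names(cv))) {
    abort("`covariates` must have columns subject_id, covariate_id, score.")
  }
  wide <- tidyr::pivot_wider(cv, names_from = "covariate_id", values_from = "score")
  ix <- match(subjects, wide$subject_id)
  if (anyNA(ix)) {
    abort(sprintf("Covariates missing for subject '%s'.", subjects[which(is.na(ix))[1]]))
  }
  X <- as.matrix(wide[ix, setdiff(names(wide), "subject_id"), drop = FALSE])
  if (anyNA(X)) abort("Covariate scores contain NA for retained subjects.")
  scale(X)
}

#' Split-half reliability of residualized battery performance
#'
#' Asks whether reliable individual differences in battery performance
#' survive after removing the variance explained by covariate tasks (e.g.
#' mental rotation and working memory). Per iteration: every task is split
#' in half, the combined (across-task mean) accuracy is computed per half,
#' each half is regressed on the covariates, and the *residuals* of the two
#' regressions are correlated (Fisher z). The permutation null shuffles the
#' split-half alignment between subjects.
#'
#' Covariates are standardized internally and regressions always include an
#' intercept, so results are invariant to affine rescaling of covariate
#' scores.
#'
#' @inheritParams split_half_reliability
#' @param covariates Long covariate table (`subject_id`, `covariate_id`,
#'   `score`) defined for every retained subject.
#' @return An object of class `residualization_result`; `tidy()` returns a
#'   one-row summary (`mean_z`, `sd_z`, `ci_low`, `ci_high`, `p`,
#'   `r_squared_half_a`, `r_squared_half_b`, `n_used`, `n_degenerate`);
#'   `$coefficients` holds the mean per-half covariate weights.
#' @examples
#' sim <- simulate_battery(battery_config(n_subjects = 60, seed = 8))
#' cv <- simulate_covariates(sim)
#' rr <- residual_split_half(sim$responses, cv, n_iter = 30, n_perm = 30, seed = 5)
#' tidy(rr)
#' @export
residual_split_half <- function(x, covariates, n_iter = 1000L, n_perm = 1000L,
                                seed = 1L) {
  bm <- battery_matrix(x)
  n <- length(bm$subjects)
  if (n < 4L) abort("Need at least 4 subjects.")
  X <- covariate_matrix(covariates, bm$subjects)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) abort("Rank-deficient covariate design.")
  n_iter <- assert_count(n_iter, "n_iter")
  n_perm <- assert_count(n_perm, "n_perm", min = 0L)
  split_seeds <- iteration_seeds(seed, n_iter, "split")

  one <- function(halves, perm = FALSE) {
    ha <- half_accuracies(bm, halves)
    ca <- rowMeans(ha$a)
    cb <- rowMeans(ha$b)
    ok <- is.finite(ca) & is.finite(cb)
    if (sum(ok) < ncol(X) + 3L) return(c(NA_real_, NA_real_, NA_real_, rep(NA_real_, 2 * ncol(X))))
    if (!all(ok)) {
      # refit on the complete subjects only
      fa <- tryCatch(ols_residuals(ca[ok], X[ok, , drop = FALSE]), error = function(e) NULL)
      fb <- tryCatch(ols_residuals(cb[ok], X[ok, , drop = FALSE]), error = function(e) NULL)
      if (is.null(fa) || is.null(fb)) return(c(NA_real_, NA_real_, NA_real_, rep(NA_real_, 2 * ncol(X))))
      ra <- fa$residuals
      rb <- fb$residuals
      r2a <- fa$r_squared
      r2b <- fb$r_squared
      cfa <- fa$coefficients[-1]
      cfb <- fb$coefficients[-1]
    } else {
      ra <- qr.resid(qx, ca)
      rb <- qr.resid(qx, cb)
      r2a <- 1 - sum(ra^2) / sum((ca - mean(ca))^2)
      r2b <- 1 - sum(rb^2) / sum((cb - mean(cb))^2)
      cfa <- qr.coef(qx, ca)[-1]
      cfb <- qr.coef(qx, cb)[-1]
    }
    if (isTRUE(perm)) rb <- sample(rb)
    c(cor_z_safe(ra, rb), r2a, r2b, cfa, cfb)
  }

  stats_mat <- matrix(NA_real_, n_iter, 3L + 2L * ncol(X))
  for (i in seq_len(n_iter)) {
    halves <- with_seed_(split_seeds[i], make_split(bm))
    stats_mat[i, ] <- one(halves)
  }
  null_z <- NULL
  if (n_perm > 0) {
    perm_seeds <- iteration_seeds(seed, n_perm, "perm")
    null_z <- vapply(seq_len(n_perm), function(j) {
      with_seed_(perm_seeds[j], {
        halves <- make_split(bm)
        one(halves, perm = TRUE)[1]
      })
    }, numeric(1))
    null_z <- null_z[!is.na(null_z)]
  }

  zv <- stats_mat[, 1]
  ok <- !is.na(zv)
  if (mean(ok) <= 0.5) abort("More than 50% of iterations degenerate.")
  zv <- zv[ok]
  mz <- mean(zv)
  coef_means <- colMeans(stats_mat[ok, -(1:3), drop = FALSE])
  coefficients <- tibble(
    covariate_id = rep(colnames(X), 2),
    half = rep(c("a", "b"), each = ncol(X)),
    weight = c(coef_means[seq_len(ncol(X))], coef_means[ncol(X) + seq_len(ncol(X))])
  )
  summary <- tibble(
    mean_z = mz, sd_z = sd(zv),
    ci_low = as.numeric(quantile(zv, 0.025)),
    ci_high = as.numeric(quantile(zv, 0.975)),
    mean_r = inv_fisher_z(mz), r_squared = inv_fisher_z(mz)^2,
    p = if (!is.null(null_z) && length(null_z) > 0) permutation_pvalue(mz, null_z) else NA_real_,
    r_squared_half_a = mean(stats_mat[ok, 2]),
    r_squared_half_b = mean(stats_mat[ok, 3]),
    n_used = sum(ok), n_degenerate = sum(!ok)
  )
  structure(list(
    summary = summary, coefficients = coefficients, z_draws = stats_mat[, 1],
    null_draws = null_z, n_iter = n_iter, n_perm = n_perm, seed = seed
  ), class = "residualization_result")
}

#' @rdname residual_split_half
#' @param x,object A `residualization_result`.
#' @param ... Unused.
#' @method tidy residualization_result
#' @export
tidy.residualization_result <- function(x, ...) x$summary

#' @rdname residual_split_half
#' @method glance residualization_result
#' @export
glance.residualization_result <- function(x, ...) {
  dplyr::bind_cols(x$summary[, c("mean_z", "p")],
                   tibble(n_iter = x$n_iter, n_perm = x$n_perm))
}

#' @export
print.residualization_result <- function(x, ...) {
  cat(sprintf("<residualization_result> %d iterations, %d permutations\n",
              x$n_iter, x$n_perm))
  print(x$summary)
  invisible(x)
}

#' Correlation between two measures after partialing out covariates
#'
#' The cross-measure analogue of [residual_split_half()]: two different
#' subject-level scores (e.g. a short-battery physics score and performance
#' on a novel task) are each regressed on the same covariates, and the
#' residuals are correlated, with a subject-bootstrap confidence interval.
#'
#' @param data A data frame of subject-level scores, one row per subject.
#' @param x,y Column names of the two measures.
#' @param covariates Character vector of covariate column names in `data`.
#' @param n_boot Bootstrap resamples for the CI (0 to skip).
#' @param seed Integer seed.
#' @return A one-row tibble as from [correlation_stats()] plus
#'   `r_squared_x`, `r_squared_y` (covariate-explained variance in each
#'   measure).
#' @examples
#' d <- tibble::tibble(tip = rnorm(50), stay_or_go = rnorm(50), mrt = rnorm(50))
#' residualized_correlation(d, "tip", "stay_or_go", "mrt", n_boot = 100)
#' @export
residualized_correlation <- function(data, x, y, covariates, n_boot = 1000L, seed = 1L) {
  data <- as_tibble(data)
  cols <- c(x, y, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) abort(paste0("Columns not found: ", paste(miss, collapse = ", ")))
  data <- data[stats::complete.cases(data[, cols]), ]
  X <- scale(as.matrix(data[, covariates, drop = FALSE]))
  fx <- ols_residuals(data[[x]], X)
  fy <- ols_residuals(data[[y]], X)
  out <- correlation_stats(fx$residuals, fy$residuals, n_boot = n_boot, seed = seed)
  out$r_squared_x <- fx$r_squared
  out$r_squared_y <- fy$r_squared
  out
}
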