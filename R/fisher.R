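#' Fisher z transform of a correlation
#'
#' `fisher_z()` is `atanh(r)` after clamping `r` to +/- (1 - 1e-12), the
#' variance-stabilizing transform that allows correlations to be averaged and
#' compared on a linear scale. Split halves of small deterministic fixtures
#' legitimately reach `|r| = 1`; clamping keeps the transform finite rather
#' than silently propagating `Inf`.
#'
#' @param r Numeric vector of Pearson correlations in `[-1, 1]`.
#' @param z Numeric vector of Fisher z values.
#' @return `fisher_z()` returns the z values; `inv_fisher_z()` returns
#'   correlations (`tanh(z)`).
#' @examples
#' fisher_z(0.5)
#' inv_fisher_z(fisher_z(0.5))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].")
  }
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

# Was the correlation clamped before the transform?
fisher_clamped <- function(r) abs(r) >= 1 - 1e-12

#' Pearson correlation with Fisher z and R-squared
#'
#' Computes the Pearson correlation between two subject-level score vectors
#' after pairwise deletion of undefined entries, together with its Fisher z
#' and \eqn{R^2}. Optionally attaches a percentile bootstrap confidence
#' interval on the z scale (resampling subjects with replacement).
#'
#' @param x,y Numeric vectors of equal length. `NA`/`NaN` entries are removed
#'   pairwise; at least 3 complete pairs must remain.
#' @param n_boot Number of bootstrap resamples for the confidence interval;
#'   `0` (default) skips the interval.
#' @param conf Confidence level for the bootstrap interval.
#' @param seed Integer seed for the bootstrap stream.
#' @return A one-row tibble with columns `n`, `r`, `z`, `r_squared`,
#'   `clamped`, and (when `n_boot > 0`) `ci_low`/`ci_high` (Fisher z scale).
#' @examples
#' correlation_stats(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
correlation_stats <- function(x, y, n_boot = 0, conf = 0.95, seed = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) abort("Need at least 3 complete pairs.")
  if (var(x) == 0) abort("Degenerate input: `x` has zero variance.")
  if (var(y) == 0) abort("Degenerate input: `y` has zero variance.")
  r <- cor(x, y)
  out <- tibble(
    n = length(x), r = r, z = fisher_z(r), r_squared = r^2,
    clamped = fisher_clamped(r)
  )
  if (n_boot > 0) {
    n_boot <- assert_count(n_boot, "n_boot")
    zs <- with_seed_(seed, vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(length(x), replace = TRUE)
      if (var(x[ix]) == 0 || var(y[ix]) == 0) return(NA_real_)
      fisher_z(cor(x[ix], y[ix]))
    }, numeric(1)))
    zs <- zs[!is.na(zs)]
    alpha <- (1 - conf) / 2
    out$ci_low <- as.numeric(quantile(zs, alpha))
    out$ci_high <- as.numeric(quantile(zs, 1 - alpha))
  }
  out
}

# Fast internal correlation -> Fisher z with pairwise deletion; returns NA on
# degenerate input instead of erroring (degenerate iterations are flagged and
# excluded by the iterated engines).
cor_z_safe <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3L) return(NA_real_)
  x <- x[keep]
  y <- y[keep]
  sx <- sd(x)
  sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  fisher_z(cor(x, y))
}

#' One-sided permutation p-value
#'
#' The add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n)`, one-sided
#' for positive association: the observed statistic is compared against the
#' null distribution generated by breaking the subject correspondence between
#' data halves.
#'
#' @param observed Scalar observed statistic (e.g. a mean Fisher z).
#' @param null_draws Numeric vector of statistics computed under shuffled
#'   subject correspondence. `NA` draws are dropped.
#' @return A single p-value in `(0, 1]`.
#' @examples
#' permutation_pvalue(2, rnorm(999)) # ~1/1000 when observed exceeds all draws
#' @export
permutation_pvalue <- function(observed, null_draws) {
  null_draws <- null_draws[!is.na(null_draws)]
  if (length(null_draws) == 0L) abort("`null_draws` must be nonempty.")
  (1 + sum(null_draws >= observed)) / (1 + length(null_draws))
}
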