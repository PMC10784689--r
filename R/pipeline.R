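#' Factor-vs-reliability ratio table
#'
#' Converts per-task split-half and factor-validation Fisher z values to
#' \eqn{R^2 = \tanh(z)^2} and reports their ratio (factor over split-half):
#' the fraction of each task's explainable variance that the common factor
#' captures. A zero split-half z leaves the ratio undefined (`NA` with a
#' warning).
#'
#' @param split_z Named numeric vector of per-task split-half mean z values.
#' @param factor_z Numeric vector of per-task factor-validation mean z
#'   values, same order (or same names).
#' @param tasks Optional task names; defaults to `names(split_z)`.
#' @return A tibble with columns `task_id`, `split_half_z`, `factor_z`,
#'   `split_half_r_squared`, `factor_r_squared`, `ratio`, plus a
#'   2-decimal presentation column `ratio_2dp`.
#' @examples
#' ratio_table(c(towers = 0.59), c(towers = 0.64))
#' @export
ratio_table <- function(split_z, factor_z, tasks = NULL) {
  if (length(split_z) != length(factor_z)) {
    abort("`split_z` and `factor_z` must have equal length.")
  }
  if (!all(is.finite(split_z)) || !all(is.finite(factor_z))) {
    abort("z values must be finite.")
  }
  tasks <- tasks %||% names(split_z) %||% paste0("task", seq_along(split_z))
  if (!is.null(names(factor_z)) && !is.null(names(split_z))) {
    factor_z <- factor_z[names(split_z)]
  }
  s_r2 <- inv_fisher_z(split_z)^2
  f_r2 <- inv_fisher_z(factor_z)^2
  ratio <- ifelse(s_r2 > 0, f_r2 / s_r2, NA_real_)
  if (any(s_r2 == 0)) warn("Ratio undefined where split-half z is 0.")
  tibble(
    task_id = tasks,
    split_half_z = as.numeric(split_z), factor_z = as.numeric(factor_z),
    split_half_r_squared = as.numeric(s_r2), factor_r_squared = as.numeric(f_r2),
    ratio = as.numeric(ratio), ratio_2dp = round(as.numeric(ratio), 2)
  )
}

#' Assemble and run the full analysis pipeline
#'
#' Orchestrates the stages in order: data (load or simulate) -> exclusions
#' -> split-half reliability -> between-task correlations -> cross-validated
#' factor analysis -> covariate residualization -> battery compression.
#' Every stage records its seed and iteration counts, so an identical
#' config reproduces an identical report.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{responses}{path to a responses CSV, *or*}
#'     \item{synthetic}{a list of [battery_config()] arguments,}
#'     \item{covariates}{optional path to a covariates CSV (defaults to
#'       simulated covariates when `synthetic` is used),}
#'     \item{stages}{character subset of `c("reliability", "correlations",
#'       "factor", "residualize", "compress")` (default: all that have
#'       their inputs),}
#'     \item{n_iter, n_perm, n_boot}{iteration counts (defaults 1000),}
#'     \item{k_per_task, holdout_fraction}{compression settings (10, 0.5),}
#'     \item{seed}{master seed (default 1),}
#'     \item{out_dir}{optional directory; when set, writes `report.json`,
#'       `ratio_table.csv`, and `exclusions.json`.}
#'   }
#' @return A list of class `study_report` with one element per executed
#'   stage plus `ratio_table`, `exclusions`, and `provenance`.
#' @examples
#' rep <- run_pipeline(list(
#'   synthetic = list(n_subjects = 40, seed = 5),
#'   n_iter = 20, n_perm = 20, n_boot = 20, seed = 5
#' ))
#' names(rep)
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  seed <- as.integer(cfg$seed %||% 1L)
  n_iter <- as.integer(cfg$n_iter %||% 1000L)
  n_perm <- as.integer(cfg$n_perm %||% 1000L)
  n_boot <- as.integer(cfg$n_boot %||% 1000L)

  # ---- data stage ----------------------------------------------------------
  covariates <- NULL
  if (!is.null(cfg$responses)) {
    responses <- read_responses(cfg$responses, chance = cfg$chance)
    if (!is.null(cfg$covariates)) covariates <- read_covariates(cfg$covariates)
  } else if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    if (!is.null(args$tasks)) args$tasks <- dplyr::bind_rows(args$tasks)
    if (!is.null(args$covariates)) args$covariates <- dplyr::bind_rows(args$covariates)
    args$seed <- args$seed %||% seed
    bc <- do.call(battery_config, args)
    sim <- simulate_battery(bc)
    responses <- sim$responses
    covariates <- if (!is.null(bc$covariates)) simulate_covariates(sim) else NULL
    if (!is.null(cfg$covariates)) covariates <- read_covariates(cfg$covariates)
  } else {
    abort("Config must provide either `responses` or `synthetic`.")
  }

  all_stages <- c("reliability", "correlations", "factor", "residualize", "compress")
  stages <- cfg$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) abort(paste0("Unknown stages: ", paste(bad, collapse = ", ")))
  if ("residualize" %in% stages && is.null(covariates)) {
    if (!is.null(cfg$stages)) {
      abort("Stage 'residualize' requires a covariates table.")
    }
    stages <- setdiff(stages, "residualize")
  }

  report <- list()
  report$exclusions <- NULL
  responses <- apply_exclusions(responses, covariates = covariates)
  report$exclusions <- exclusions(responses)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
    })
  }
  if ("reliability" %in% stages) {
    report$reliability <- run_stage("reliability", function()
      split_half_reliability(responses, n_iter = n_iter, n_perm = n_perm, seed = seed))
  }
  if ("correlations" %in% stages) {
    report$correlations <- run_stage("correlations", function()
      between_task_correlations(responses, n_boot = n_boot, seed = seed))
  }
  if ("factor" %in% stages) {
    report$factor <- run_stage("factor", function()
      crossvalidated_factor_variance(responses, n_iter = n_iter, n_perm = n_perm, seed = seed))
  }
  if ("residualize" %in% stages) {
    report$residualize <- run_stage("residualize", function()
      residual_split_half(responses, covariates, n_iter = n_iter, n_perm = n_perm, seed = seed))
  }
  if ("compress" %in% stages) {
    report$compress <- run_stage("compress", function()
      compress_battery(responses, k_per_task = as.integer(cfg$k_per_task %||% 10L),
                       n_iter = n_iter,
                       holdout_fraction = cfg$holdout_fraction %||% 0.5,
                       seed = seed))
  }
  if (!is.null(report$reliability) && !is.null(report$factor)) {
    fv <- report$factor$summary
    report$ratio_table <- ratio_table(
      setNames(fv$split_half_z, fv$task_id),
      setNames(fv$mean_z, fv$task_id)
    )
  }
  report$provenance <- list(
    seed = seed, n_iter = n_iter, n_perm = n_perm, n_boot = n_boot,
    stages = stages, package_version = as.character(utils::packageVersion("physbattery"))
  )
  out <- structure(report, class = "study_report")
  if (!is.null(cfg$out_dir)) write_study_report(out, cfg$out_dir)
  out
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a list or a path to a YAML/JSON file.")
  }
}

#' Write a study report to disk
#'
#' Emits `report.json` (the canonical machine-readable report),
#' `ratio_table.csv` (flat spreadsheet form, when present), and
#' `exclusions.json`.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(provenance = report$provenance, exclusions = report$exclusions)
  if (!is.null(report$reliability)) js$reliability <- report$reliability$summary
  if (!is.null(report$correlations)) js$correlations <- report$correlations
  if (!is.null(report$factor)) js$factor <- report$factor$summary
  if (!is.null(report$residualize)) js$residualize <- report$residualize$summary
  if (!is.null(report$compress)) {
    js$compress <- list(selected = report$compress$selected,
                        summary = glance(report$compress))
  }
  if (!is.null(report$ratio_table)) js$ratio_table <- report$ratio_table
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
  if (!is.null(report$ratio_table)) {
    readr::write_csv(report$ratio_table, file.path(dir, "ratio_table.csv"), progress = FALSE)
  }
  jsonlite::write_json(report$exclusions, file.path(dir, "exclusions.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  stages:", paste(x$provenance$stages, collapse = ", "), "\n")
  cat("  seed:", x$provenance$seed, "\n")
  if (!is.null(x$reliability)) {
    comb <- x$reliability$summary[x$reliability$summary$task_id == "combined", ]
    cat(sprintf("  combined split-half z = %.3f (p = %.4g)\n", comb$mean_z, comb$p))
  }
  if (!is.null(x$ratio_table)) {
    cat("  factor/split-half R^2 ratios:\n")
    print(x$ratio_table[, c("task_id", "ratio_2dp")])
  }
  invisible(x)
}
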