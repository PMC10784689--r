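#' Participant and task exclusion rules
#'
#' Rule set mirroring the quality-control filters used with online intuitive
#' physics batteries: whole-subject removal for performing below chance on
#' too many tasks, for failing working-memory catch criteria, or for giving
#' the same response on every trial; and per-task removal for excessive
#' missing trials (a subject who lost too many videos of one task is dropped
#' from that task's analyses only, and retained everywhere else).
#'
#' @param below_chance_task_limit Exclude a subject entirely when accuracy is
#'   below the task's chance level on at least this many tasks (default 2).
#' @param below_chance_strict Logical; `TRUE` (default) compares with strict
#'   `<` (accuracy exactly at chance does not count as below chance).
#' @param max_missing_fraction Drop a subject from a single task when more
#'   than this fraction of that task's trials is missing (default 0.25).
#' @param wm_symmetry_min Exclude subjects whose `wm_symmetry` covariate score
#'   (accuracy on interleaved symmetry judgments of a complex-span task) is
#'   below this fraction (default 0.85).
#' @param wm_zero_span_excludes Exclude subjects whose `wm_span` covariate
#'   score is exactly 0 (no memory-grid trial fully recalled).
#' @param uniform_response_excludes Exclude subjects who gave the same
#'   response on all trials (bot filtering). Evaluated on the raw `response`
#'   column when present; otherwise approximated as accuracy exactly equal to
#'   the task's chance level in every task (the accuracy a constant responder
#'   earns on a balanced two-alternative design).
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(below_chance_task_limit = 2L,
                            below_chance_strict = TRUE,
                            max_missing_fraction = 0.25,
                            wm_symmetry_min = 0.85,
                            wm_zero_span_excludes = TRUE,
                            uniform_response_excludes = TRUE) {
  structure(list(
    below_chance_task_limit = assert_count(below_chance_task_limit, "below_chance_task_limit"),
    below_chance_strict = isTRUE(below_chance_strict),
    max_missing_fraction = assert_fraction(max_missing_fraction, "max_missing_fraction"),
    wm_symmetry_min = assert_fraction(wm_symmetry_min, "wm_symmetry_min"),
    wm_zero_span_excludes = isTRUE(wm_zero_span_excludes),
    uniform_response_excludes = isTRUE(uniform_response_excludes)
  ), class = "exclusion_rules")
}

#' Apply exclusion rules to a response table
#'
#' Whole-subject rules (below-chance on too many tasks, working-memory
#' criteria, uniform responding) remove the subject everywhere; the
#' missing-trials rule removes the subject from the offending task only.
#' The per-task rule is applied first, so the subject-level rules are always
#' evaluated on the retained task data; this makes the operation idempotent
#' (applying it twice equals applying it once).
#'
#' @param x A `phys_responses` object.
#' @param covariates Optional long covariate score table with columns
#'   `subject_id`, `covariate_id`, `score`. Rows with `covariate_id`
#'   `"wm_symmetry"` / `"wm_span"` feed the working-memory rules.
#' @param rules An [exclusion_rules()] object.
#' @return The filtered `phys_responses` (possibly with zero rows), with the
#'   per-subject report attached; retrieve it with [exclusions()].
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 20, seed = 1))$responses
#' kept <- apply_exclusions(rm)
#' exclusions(kept)
#' @export
apply_exclusions <- function(x, covariates = NULL, rules = exclusion_rules()) {
  if (!inherits(rules, "exclusion_rules")) abort("`rules` must come from exclusion_rules().")
  chance <- chance_levels(x)
  report <- tibble(subject_id = character(), rule = character(), detail = character())

  # -- per-task missingness rule (first, so subject rules see retained data) --
  task_sizes <- x |>
    dplyr::distinct(.data$task_id, .data$trial_id) |>
    dplyr::count(.data$task_id, name = "n_trials")
  miss <- x |>
    dplyr::group_by(.data$subject_id, .data$task_id) |>
    dplyr::summarise(n_missing = sum(.data$missing), .groups = "drop") |>
    dplyr::left_join(task_sizes, by = "task_id") |>
    dplyr::filter(.data$n_missing / .data$n_trials > rules$max_missing_fraction)
  if (nrow(miss) > 0) {
    report <- dplyr::bind_rows(report, tibble(
      subject_id = miss$subject_id, rule = "excess_missing",
      detail = sprintf("%d/%d trials missing in task %s",
                       miss$n_missing, miss$n_trials, miss$task_id)
    ))
  }
  keep_row <- !(paste(x$subject_id, x$task_id) %in% paste(miss$subject_id, miss$task_id))
  x2 <- x[keep_row, , drop = FALSE]

  # -- whole-subject rules ---------------------------------------------------
  acc <- score_accuracy(x2)
  acc$chance <- chance[acc$task_id]
  below <- if (rules$below_chance_strict) acc$accuracy < acc$chance else acc$accuracy <= acc$chance
  below[is.na(below)] <- FALSE
  n_below <- tapply(below, acc$subject_id, sum)
  bad_chance <- names(n_below)[n_below >= rules$below_chance_task_limit]
  if (length(bad_chance) > 0) {
    report <- dplyr::bind_rows(report, tibble(
      subject_id = bad_chance, rule = "below_chance",
      detail = sprintf("below chance on %d tasks", as.integer(n_below[bad_chance]))
    ))
  }

  bad_wm <- character()
  if (!is.null(covariates)) {
    cv <- as_tibble(covariates)
    sym <- cv[cv$covariate_id == "wm_symmetry", ]
    low_sym <- sym$subject_id[sym$score < rules$wm_symmetry_min]
    if (length(low_sym) > 0) {
      report <- dplyr::bind_rows(report, tibble(
        subject_id = low_sym, rule = "wm_symmetry",
        detail = sprintf("symmetry accuracy below %.2f", rules$wm_symmetry_min)
      ))
      bad_wm <- c(bad_wm, low_sym)
    }
    if (rules$wm_zero_span_excludes) {
      span <- cv[cv$covariate_id == "wm_span", ]
      zero_span <- span$subject_id[span$score == 0]
      if (length(zero_span) > 0) {
        report <- dplyr::bind_rows(report, tibble(
          subject_id = zero_span, rule = "wm_zero_span",
          detail = "no memory-grid trial fully recalled"
        ))
        bad_wm <- c(bad_wm, zero_span)
      }
    }
  }

  bad_uniform <- character()
  if (rules$uniform_response_excludes) {
    if ("response" %in% names(x2)) {
      resp <- x2[!x2$missing, c("subject_id", "response")]
      n_distinct_resp <- tapply(resp$response, resp$subject_id, function(v) length(unique(v)))
      n_resp <- tapply(resp$response, resp$subject_id, length)
      bad_uniform <- names(n_distinct_resp)[n_distinct_resp == 1 & n_resp > 1]
    } else {
      # constant responders earn exactly the chance level on a balanced design
      at_chance <- abs(acc$accuracy - acc$chance) < 1e-12
      at_chance[is.na(at_chance)] <- TRUE # tasks with no data don't veto
      all_chance <- tapply(at_chance, acc$subject_id, all)
      seen <- tapply(!is.na(acc$accuracy), acc$subject_id, any)
      bad_uniform <- names(all_chance)[all_chance & seen]
    }
    if (length(bad_uniform) > 0) {
      report <- dplyr::bind_rows(report, tibble(
        subject_id = bad_uniform, rule = "uniform_response",
        detail = "same response on all trials"
      ))
    }
  }

  drop_subjects <- unique(c(bad_chance, bad_wm, bad_uniform))
  out <- x2[!(x2$subject_id %in% drop_subjects), , drop = FALSE]
  out <- phys_responses(out, chance = chance[unique(out$task_id)])
  attr(out, "exclusions") <- dplyr::arrange(report, .data$subject_id, .data$rule)
  out
}

#' Exclusion report of a filtered response table
#'
#' @param x The result of [apply_exclusions()].
#' @return A tibble with columns `subject_id`, `rule`, `detail` (zero rows if
#'   nothing was excluded).
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble(subject_id = character(), rule = character(), detail = character())
}

#' Write an exclusion report as JSON
#' @param x The result of [apply_exclusions()].
#' @param path Output path for a JSON array of `{subject_id, rule, detail}`.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(x, path) {
  jsonlite::write_json(exclusions(x), path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
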