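#' Build a validated trial-level response table
#'
#' The raw unit of observation is one subject's correctness on one trial of
#' one task. `phys_responses()` validates a long-format data frame and tags
#' it with the per-task chance level (0.5 for all two-alternative tasks),
#' which downstream exclusion rules use as the below-chance threshold.
#'
#' @param data A data frame with columns `subject_id`, `task_id`, `trial_id`,
#'   `correct` (0/1), `missing` (logical). An optional `response` column
#'   (raw response labels) enables the uniform-responder exclusion rule to be
#'   evaluated exactly. `correct` is ignored wherever `missing` is `TRUE`.
#' @param chance Named numeric vector or list mapping `task_id` to the chance
#'   probability in (0, 1). Defaults to 0.5 for every task present.
#' @return A tibble of class `phys_responses` with a `chance` attribute.
#' @examples
#' df <- tidyr::expand_grid(
#'   subject_id = c("s1", "s2"), task_id = "towers", trial_id = paste0("t", 1:3)
#' )
#' df$correct <- rep(c(1, 0), length.out = nrow(df))
#' df$missing <- FALSE
#' phys_responses(df)
#' @export
phys_responses <- function(data, chance = NULL) {
  need <- c("subject_id", "task_id", "trial_id", "correct", "missing")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing required columns: ", paste(miss, collapse = ", "), "."))
  }
  data <- as_tibble(data)
  data$subject_id <- as.character(data$subject_id)
  data$task_id <- as.character(data$task_id)
  data$trial_id <- as.character(data$trial_id)
  data$missing <- as.logical(data$missing)
  if (anyNA(data$missing)) abort("`missing` must be TRUE/FALSE with no NA.")
  obs <- !data$missing
  bad <- obs & (is.na(data$correct) | !(data$correct %in% c(0, 1)))
  if (any(bad)) {
    abort(sprintf(
      "`correct` must be 0 or 1 on non-missing trials (first bad row: %d).",
      which(bad)[1]
    ))
  }
  data$correct <- as.numeric(data$correct)
  key <- paste(data$subject_id, data$task_id, data$trial_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf(
      "Duplicate (subject_id, task_id, trial_id) key: (%s, %s, %s).",
      d$subject_id, d$task_id, d$trial_id
    ))
  }
  # a trial id must belong to exactly one task
  tt <- unique(data[, c("task_id", "trial_id")])
  if (anyDuplicated(tt$trial_id)) {
    abort("Each trial_id must belong to exactly one task.")
  }
  tasks <- unique(data$task_id)
  if (is.null(chance)) chance <- setNames(rep(0.5, length(tasks)), tasks)
  chance <- unlist(chance)
  if (!all(tasks %in% names(chance))) {
    abort("`chance` must name every task present in the data.")
  }
  chance <- chance[tasks]
  if (any(chance <= 0 | chance >= 1)) abort("Chance levels must lie strictly in (0, 1).")
  structure(data, class = c("phys_responses", class(tibble())), chance = chance)
}

#' Per-task chance levels of a response table
#' @param x A `phys_responses` object.
#' @return Named numeric vector of chance probabilities.
#' @export
chance_levels <- function(x) attr(x, "chance")

#' Read a long-format responses CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `subject_id,task_id,trial_id,correct,missing` (an optional `response`
#' column is carried through). Row order never affects downstream results;
#' duplicate `(subject, task, trial)` keys are rejected.
#'
#' @param path Path to the CSV file.
#' @param chance Optional named chance map passed to [phys_responses()].
#' @return A `phys_responses` tibble.
#' @seealso [write_responses()]
#' @export
read_responses <- function(path, chance = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      task_id = readr::col_character(),
      trial_id = readr::col_character(),
      correct = readr::col_double(),
      missing = readr::col_logical(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(data)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed responses CSV at line %d: %s", prob$row[1], prob$expected[1]))
  }
  phys_responses(data, chance = chance)
}

#' Write a response table to CSV
#'
#' Inverse of [read_responses()]: the written file round-trips to an
#' identical response table.
#'
#' @param x A `phys_responses` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Score proportion correct per subject and task
#'
#' Accuracy is the number of correct responses over the number of
#' *non-missing* trials. A subject with zero observed trials in a task gets
#' an `NaN` accuracy with `n_observed = 0` — undefined, never silently 0 —
#' which propagates as pairwise deletion into downstream correlations.
#'
#' @param x A `phys_responses` object (or data frame with the same columns).
#' @return A tibble with columns `subject_id`, `task_id`, `accuracy`,
#'   `n_observed`, one row per subject-task pair present in the data.
#' @examples
#' rm <- simulate_battery(battery_config(n_subjects = 5, seed = 1))$responses
#' score_accuracy(rm)
#' @export
score_accuracy <- function(x) {
  x |>
    dplyr::group_by(.data$subject_id, .data$task_id) |>
    dplyr::summarise(
      accuracy = if (sum(!.data$missing) == 0) NaN else
        sum(.data$correct[!.data$missing]) / sum(!.data$missing),
      n_observed = sum(!.data$missing),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subject_id, .data$task_id)
}

# Wide subjects x tasks accuracy matrix (NaN for undefined cells).
accuracy_wide <- function(acc) {
  wide <- acc |>
    dplyr::select("subject_id", "task_id", "accuracy") |>
    tidyr::pivot_wider(names_from = "task_id", values_from = "accuracy")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

# Dense internal representation for the iterated engines:
#   m0       subjects x trials correctness with 0 where missing/absent
#   obs      subjects x trials 1 where a non-missing observation exists
#   task_cols named list of column index vectors, one per task
battery_matrix <- function(x) {
  subjects <- sort(unique(x$subject_id))
  tasks <- unique(x$task_id)
  trials <- x |>
    dplyr::distinct(.data$task_id, .data$trial_id) |>
    dplyr::arrange(match(.data$task_id, tasks), .data$trial_id)
  col_of <- setNames(seq_len(nrow(trials)), paste(trials$task_id, trials$trial_id, sep = "\r"))
  i <- match(x$subject_id, subjects)
  j <- col_of[paste(x$task_id, x$trial_id, sep = "\r")]
  m0 <- matrix(0, length(subjects), nrow(trials))
  obs <- matrix(0, length(subjects), nrow(trials))
  keep <- !x$missing
  m0[cbind(i[keep], j[keep])] <- x$correct[keep]
  obs[cbind(i[keep], j[keep])] <- 1
  task_cols <- lapply(tasks, function(t) which(trials$task_id == t))
  names(task_cols) <- tasks
  ch <- chance_levels(x) %||% setNames(rep(0.5, length(tasks)), tasks)
  list(
    m0 = m0, obs = obs, task_cols = task_cols,
    subjects = subjects, tasks = tasks,
    trial_ids = split(trials$trial_id, factor(trials$task_id, levels = tasks)),
    chance = ch[tasks]
  )
}

#' @export
print.phys_responses <- function(x, ...) {
  cat(sprintf(
    "<phys_responses> %d subjects, %d tasks, %d trial records (%0.1f%% missing)\n",
    dplyr::n_distinct(x$subject_id), dplyr::n_distinct(x$task_id),
    nrow(x), 100 * mean(x$missing)
  ))
  NextMethod()
}
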