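#' Configuration for the synthetic battery generator
#'
#' Describes a trial-level battery with the latent structure the
#' individual-differences analyses assume: a shared ability factor with
#' per-task loadings, task-specific abilities, item difficulties, a guessing
#' floor, and covariate tasks that mix the shared ability with a separate
#' spatial latent. The default task roster mirrors a five-task intuitive
#' physics battery with trial counts 48, 64, 240, 40, 58 and two-alternative
#' chance level 0.5.
#'
#' Per trial, the success probability follows the guessing-floor logistic
#' (3PL-style) form
#' \deqn{P = c_t + (1 - c_t)\,\mathrm{logistic}\big(a_t(\lambda_t \theta_i +
#'   \sqrt{1-\lambda_t^2}\, s_{it} - b_j)\big)}
#' with general ability \eqn{\theta_i}, task-specific ability \eqn{s_{it}}
#' (both standard normal), item difficulty \eqn{b_j \sim N(0, \sigma_b^2)},
#' discrimination \eqn{a_t}, and chance floor \eqn{c_t}.
#'
#' @param n_subjects Number of simulated subjects.
#' @param tasks A data frame with columns `task_id`, `n_trials`, `chance`,
#'   `loading`, `discrimination`, `difficulty_sd`. Defaults to
#'   [default_tasks()].
#' @param covariates A data frame with columns `covariate_id`,
#'   `loading_on_general`, `loading_on_spatial`, `noise_sd`. Defaults to
#'   [default_covariates()].
#' @param spatial_physics_correlation Target correlation between the general
#'   physics ability and the spatial latent that covariate tasks load on.
#' @param missing_rate Probability that any single trial response is missing
#'   (completely at random, emulating ignorable video-load failures).
#' @param seed Master integer seed. All draws run through per-component
#'   subseeds derived from it, so adding a task or covariate never perturbs
#'   the draws of earlier components.
#' @return A list of class `battery_config`.
#' @examples
#' cfg <- battery_config(n_subjects = 50, seed = 7)
#' sim <- simulate_battery(cfg)
#' sim$responses
#' @export
battery_config <- function(n_subjects = 100,
                           tasks = default_tasks(),
                           covariates = default_covariates(),
                           spatial_physics_correlation = 0.4,
                           missing_rate = 0.02,
                           seed = 1L) {
  tasks <- as_tibble(tasks)
  need <- c("task_id", "n_trials", "chance", "loading", "discrimination", "difficulty_sd")
  miss <- setdiff(need, names(tasks))
  if (length(miss) > 0) abort(paste0("`tasks` lacks columns: ", paste(miss, collapse = ", ")))
  if (any(tasks$loading < 0 | tasks$loading > 1)) {
    abort("Task loadings must lie in [0, 1] (loading^2 <= 1).")
  }
  if (any(tasks$discrimination < 0)) abort("Discriminations must be >= 0.")
  if (any(tasks$difficulty_sd < 0)) abort("`difficulty_sd` must be >= 0.")
  if (any(tasks$chance <= 0 | tasks$chance >= 1)) abort("Chance levels must lie in (0, 1).")
  if (anyDuplicated(tasks$task_id)) abort("Duplicate task ids in `tasks`.")
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    needc <- c("covariate_id", "loading_on_general", "loading_on_spatial", "noise_sd")
    missc <- setdiff(needc, names(covariates))
    if (length(missc) > 0) abort(paste0("`covariates` lacks columns: ", paste(missc, collapse = ", ")))
    dead <- covariates$loading_on_general == 0 & covariates$loading_on_spatial == 0 &
      covariates$noise_sd == 0
    if (any(dead)) {
      abort(sprintf("Covariate '%s' has all loadings and noise zero (zero variance).",
                    covariates$covariate_id[which(dead)[1]]))
    }
  }
  structure(list(
    n_subjects = assert_count(n_subjects, "n_subjects", min = 1L),
    tasks = tasks,
    covariates = covariates,
    spatial_physics_correlation = assert_fraction(spatial_physics_correlation,
                                                  "spatial_physics_correlation", -1, 1),
    missing_rate = assert_fraction(missing_rate, "missing_rate", 0, 0.999),
    seed = as.integer(seed)
  ), class = "battery_config")
}

#' Default synthetic task roster
#'
#' Five two-alternative tasks with the trial counts of the reference battery
#' (48 tower, 64 disc, 240 collision, 40 lifting, 58 ramp trials), chance
#' 0.5, shared-factor loading 0.6, discrimination 1.5, and unit item
#' difficulty spread.
#'
#' @param loading,discrimination,difficulty_sd Scalars or length-5 vectors
#'   overriding the generative parameters per task.
#' @return A tibble with one row per task.
#' @export
default_tasks <- function(loading = 0.6, discrimination = 1.5, difficulty_sd = 1) {
  tibble(
    task_id = c("towers", "discs", "bowling", "weightlifting", "ramp"),
    n_trials = c(48L, 64L, 240L, 40L, 58L),
    chance = 0.5,
    loading = rep_len(loading, 5),
    discrimination = rep_len(discrimination, 5),
    difficulty_sd = rep_len(difficulty_sd, 5)
  )
}

#' Default synthetic covariate tasks
#'
#' Mental rotation, working memory, and face memory analogues: each score
#' mixes the general physics ability and a separate spatial latent with
#' independent noise. Mental rotation leans most on the spatial latent;
#' face memory is nearly pure noise with respect to the physics battery.
#'
#' @return A tibble with one row per covariate task.
#' @export
default_covariates <- function() {
  tibble(
    covariate_id = c("mental_rotation", "working_memory", "face_memory"),
    loading_on_general = c(0.30, 0.25, 0.15),
    loading_on_spatial = c(0.50, 0.35, 0.10),
    noise_sd = c(0.70, 0.80, 0.95)
  )
}

# Subseed scheme: component k of type `what` draws under seed + offset.
# Primes keep the streams of different component types apart.
component_seed <- function(cfg, what, k = 0L) {
  base <- c(latents = 11L, task = 7919L, covariate = 104729L, missing = 15485863L)[[what]]
  (cfg$seed + base + 31L * k) %% .Machine$integer.max
}

#' Simulate a trial-level battery with known ground truth
#'
#' Draws subject latents, item difficulties, and Bernoulli trial responses
#' under the guessing-floor logistic model of [battery_config()], plus a
#' completely-at-random missingness mask. Fully reproducible from the
#' config's master seed; the same config yields byte-identical output.
#'
#' @param cfg A [battery_config()].
#' @return A list of class `battery_simulation` with elements
#'   \describe{
#'     \item{responses}{a [phys_responses()] tibble (long format),}
#'     \item{truth}{the drawn latents: `theta` (general ability), `spatial`,
#'       `s` (subjects x tasks specific abilities), `difficulties` (named
#'       list of per-trial difficulty vectors), and the config.}
#'   }
#' @examples
#' sim <- simulate_battery(battery_config(n_subjects = 30, seed = 42))
#' head(sim$truth$theta)
#' @export
simulate_battery <- function(cfg) {
  if (!inherits(cfg, "battery_config")) abort("`cfg` must come from battery_config().")
  n <- cfg$n_subjects
  subjects <- sprintf("s%0*d", max(3L, nchar(n)), seq_len(n))
  rho <- cfg$spatial_physics_correlation

  lat <- with_seed_(component_seed(cfg, "latents"), {
    theta <- stats::rnorm(n)
    u <- stats::rnorm(n)
    list(theta = theta, spatial = rho * theta + sqrt(1 - rho^2) * u)
  })

  tasks <- cfg$tasks
  s_mat <- matrix(0, n, nrow(tasks), dimnames = list(subjects, tasks$task_id))
  diffs <- vector("list", nrow(tasks))
  names(diffs) <- tasks$task_id
  parts <- vector("list", nrow(tasks))
  for (t in seq_len(nrow(tasks))) {
    tk <- tasks[t, ]
    part <- with_seed_(component_seed(cfg, "task", t), {
      s_t <- stats::rnorm(n)
      b <- stats::rnorm(tk$n_trials, 0, tk$difficulty_sd)
      ability <- tk$loading * lat$theta + sqrt(1 - tk$loading^2) * s_t
      eta <- tk$discrimination * outer(ability, b, `-`)
      p <- tk$chance + (1 - tk$chance) * stats::plogis(eta)
      correct <- matrix(
        as.numeric(stats::runif(n * tk$n_trials) < p),
        n, tk$n_trials
      )
      list(s_t = s_t, b = b, correct = correct)
    })
    s_mat[, t] <- part$s_t
    diffs[[t]] <- part$b
    trial_ids <- sprintf("%s_t%03d", tk$task_id, seq_len(tk$n_trials))
    parts[[t]] <- tibble(
      subject_id = rep(subjects, times = tk$n_trials),
      task_id = tk$task_id,
      trial_id = rep(trial_ids, each = n),
      correct = as.vector(part$correct)
    )
  }
  long <- dplyr::bind_rows(parts)
  long$missing <- with_seed_(
    component_seed(cfg, "missing"),
    stats::runif(nrow(long)) < cfg$missing_rate
  )
  long <- dplyr::arrange(long, .data$subject_id, .data$task_id, .data$trial_id)
  responses <- phys_responses(long, chance = setNames(tasks$chance, tasks$task_id))
  truth <- list(
    subjects = subjects, theta = setNames(lat$theta, subjects),
    spatial = setNames(lat$spatial, subjects),
    s = s_mat, difficulties = diffs, config = cfg
  )
  structure(list(responses = responses, truth = truth), class = "battery_simulation")
}

#' Simulate covariate task scores from drawn latents
#'
#' Each covariate score is
#' `loading_on_general * theta + loading_on_spatial * spatial + N(0, noise_sd^2)`,
#' standardized across subjects. Reproducible from the config's master seed;
#' independent of the battery's Bernoulli stream.
#'
#' @param sim A `battery_simulation` from [simulate_battery()].
#' @param cfg Optional [battery_config()]; defaults to the config stored in
#'   `sim` (its `covariates` table defines the scores).
#' @return A long tibble with columns `subject_id`, `covariate_id`, `score`.
#' @examples
#' sim <- simulate_battery(battery_config(n_subjects = 30, seed = 42))
#' simulate_covariates(sim)
#' @export
simulate_covariates <- function(sim, cfg = NULL) {
  if (!inherits(sim, "battery_simulation")) abort("`sim` must come from simulate_battery().")
  cfg <- cfg %||% sim$truth$config
  cov <- cfg$covariates
  if (is.null(cov) || nrow(cov) == 0) abort("Config declares no covariates.")
  n <- length(sim$truth$theta)
  purrr::map_dfr(seq_len(nrow(cov)), function(j) {
    cj <- cov[j, ]
    raw <- cj$loading_on_general * sim$truth$theta +
      cj$loading_on_spatial * sim$truth$spatial +
      with_seed_(component_seed(cfg, "covariate", j), stats::rnorm(n, 0, cj$noise_sd))
    tibble(
      subject_id = sim$truth$subjects,
      covariate_id = cj$covariate_id,
      score = as.numeric(scale(raw))
    )
  })
}

#' Read or write a covariate score table
#'
#' Long CSV with header `subject_id,covariate_id,score`.
#' @param path CSV path.
#' @return `read_covariates()` returns the tibble; `write_covariates()`
#'   returns `path` invisibly.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    covariate_id = readr::col_character(),
    score = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_covariates
#' @param x Covariate tibble.
#' @export
write_covariates <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
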