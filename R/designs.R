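# Stimulus-design enumeration helpers. These reproduce the factorial
# structure of each task's trial set and serve as generator defaults and
# design-count checks; no stimulus content is rendered.

#' Enumerate the toppling-towers trial design
#'
#' Towers of 11, 13, 15, 17, 19, or 21 blocks, 8 towers per count, half
#' falling to each side of the platform: 48 trials.
#'
#' @return A tibble with columns `trial`, `n_blocks`, `falls_to`.
#' @export
design_toppling_towers <- function() {
  d <- tidyr::expand_grid(
    n_blocks = c(11L, 13L, 15L, 17L, 19L, 21L),
    rep = 1:8
  )
  d$falls_to <- ifelse(d$rep <= 4, "gray", "white")
  tibble(trial = seq_len(nrow(d)), n_blocks = d$n_blocks, falls_to = d$falls_to)
}

#' Enumerate the bouncing-discs trial design
#'
#' Four arenas crossed with the reappearance type (correct vs. offset),
#' the identity of the disappearing disc, and four repetitions: 64 trials,
#' half with a correct reappearance.
#'
#' @return A tibble with columns `trial`, `arena`, `reappearance`,
#'   `hidden_disc`, `rep`.
#' @export
design_bouncing_discs <- function() {
  d <- tidyr::expand_grid(
    arena = 1:4,
    reappearance = c("correct", "offset"),
    hidden_disc = c("blue_green", "red_yellow"),
    rep = 1:4
  )
  tibble(trial = seq_len(nrow(d)), d)
}

#' Enumerate the bowling-balls trial design
#'
#' Ball weights of 6, 8, 10, 12, 14, and 16 pounds give 30 ordered
#' (incoming, stationary) pairs of distinct weights; each pair was filmed
#' twice (60 stimuli) and every stimulus presented four times: 240 trials.
#'
#' @return A tibble with columns `trial`, `stimulus`, `incoming_lb`,
#'   `stationary_lb`, `filming`, `presentation`.
#' @export
design_bowling_balls <- function() {
  weights <- c(6L, 8L, 10L, 12L, 14L, 16L)
  pairs <- tidyr::expand_grid(incoming_lb = weights, stationary_lb = weights)
  pairs <- pairs[pairs$incoming_lb != pairs$stationary_lb, ]
  stim <- tidyr::expand_grid(pairs, filming = 1:2)
  stim$stimulus <- seq_len(nrow(stim))
  d <- tidyr::expand_grid(stim, presentation = 1:4)
  tibble(trial = seq_len(nrow(d)),
         d[, c("stimulus", "incoming_lb", "stationary_lb", "filming", "presentation")])
}

#' Enumerate the weightlifting trial design
#'
#' Five canister weight pairings (100g/2000g ... 900g/1200g), each shown in
#' both presentation orders by each of four lifters: 40 trials.
#'
#' @return A tibble with columns `trial`, `lifter`, `light_g`, `heavy_g`,
#'   `heavier_first`.
#' @export
design_weightlifting <- function() {
  pairs <- tibble(
    light_g = c(100L, 300L, 500L, 700L, 900L),
    heavy_g = c(2000L, 1800L, 1600L, 1400L, 1200L)
  )
  d <- tidyr::expand_grid(lifter = 1:4, pairs, heavier_first = c(TRUE, FALSE))
  tibble(trial = seq_len(nrow(d)), d)
}

#' Generate a ramp knock-off trial design with balanced outcomes
#'
#' Ramp angle (3 levels), ball weight (light/heavy), and lower-object shape
#' (cube/cylinder/pyramid) vary independently; scenes are assigned so that
#' the object is knocked off on exactly half of the trials (rounded to the
#' nearest split for odd `n_trials`) and the outcome is balanced within each
#' variable as evenly as the trial count allows.
#'
#' @param n_trials Number of trials (default 58).
#' @param seed Integer seed controlling the continuous scene positions.
#' @return A tibble with columns `trial`, `ramp_angle`, `ball_weight`,
#'   `shape`, `ball_position`, `object_position`, `knocked_off`.
#' @export
design_ramp_knock_off <- function(n_trials = 58L, seed = 1L) {
  n_trials <- assert_count(n_trials, "n_trials", min = 2L)
  cells <- tidyr::expand_grid(
    ramp_angle = c("low", "medium", "high"),
    ball_weight = c("light", "heavy"),
    shape = c("cube", "cylinder", "pyramid")
  )
  # cycle through the 18 factorial cells with a one-cell shift per cycle so
  # that the alternating outcome is not confounded with any cell
  k <- seq_len(n_trials) - 1L
  idx <- (k + k %/% nrow(cells)) %% nrow(cells) + 1L
  d <- cells[idx, ]
  d$knocked_off <- rep(c(TRUE, FALSE), length.out = n_trials)
  if (sum(d$knocked_off) != n_trials %/% 2) {
    d$knocked_off[n_trials] <- FALSE
  }
  pos <- with_seed_(seed, list(
    ball = round(stats::runif(n_trials), 3),
    object = round(stats::runif(n_trials), 3)
  ))
  tibble(
    trial = seq_len(n_trials),
    d[, c("ramp_angle", "ball_weight", "shape")],
    ball_position = pos$ball, object_position = pos$object,
    knocked_off = d$knocked_off
  )
}

#' Enumerate the stay-or-go stimulus design
#'
#' Fourteen household objects crossed with four ramp angles (12.02, 14.94,
#' 17.85, 20.77 degrees) and four surface materials (wood, glass, metal,
#' rubber): 224 stimuli.
#'
#' @return A tibble with columns `stimulus`, `object`, `ramp_angle_deg`,
#'   `material`.
#' @export
design_stay_or_go <- function() {
  d <- tidyr::expand_grid(
    object = sprintf("object_%02d", 1:14),
    ramp_angle_deg = c(12.02, 14.94, 17.85, 20.77),
    material = c("wood", "glass", "metal", "rubber")
  )
  tibble(stimulus = seq_len(nrow(d)), d)
}
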