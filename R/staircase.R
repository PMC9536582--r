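#' Double-staircase difficulty controller
#'
#' Two interleaved 1-up/1-down adaptive tracks over a scalar difficulty:
#' the active track moves one step harder after a win and one step easier
#' after a loss, tracks alternate between trials, and difficulty is clamped
#' to `bounds`. Interleaving two tracks makes the adaptation hard to game
#' while holding the win rate near 50%.
#'
#' @param start Numeric length-2 starting difficulties of the two tracks.
#' @param step Step size (difficulty units) per win/loss.
#' @param bounds Length-2 difficulty bounds `[d_min, d_max]`.
#' @return An object of class `asrc_staircase`.
#' @export
staircase_init <- function(start = c(-0.5, 0.5), step = 0.25,
                           bounds = c(-4, 4)) {
  stopifnot(length(start) == 2, step > 0, length(bounds) == 2,
            bounds[1] < bounds[2])
  structure(list(levels = pmin(bounds[2], pmax(bounds[1], start)),
                 step = step, bounds = bounds, active = 1L,
                 last_direction = c(NA_integer_, NA_integer_)),
            class = "asrc_staircase")
}

#' Current difficulty of a staircase
#'
#' @param state An [staircase_init()] state.
#' @return The active track's difficulty level.
#' @export
staircase_difficulty <- function(state) {
  stopifnot(inherits(state, "asrc_staircase"))
  state$levels[state$active]
}

#' One staircase step
#'
#' Moves the active track one step harder after a win (`outcome = 1`) and
#' one step easier after a loss, clamps to the configured bounds, and
#' passes control to the other track.
#'
#' @param state An [staircase_init()] state.
#' @param outcome 0/1 outcome of the trial just played.
#' @return The updated state.
#' @export
staircase_update <- function(state, outcome) {
  stopifnot(inherits(state, "asrc_staircase"), outcome %in% c(0, 1))
  i <- state$active
  dir <- if (outcome == 1) 1 else -1
  state$levels[i] <- min(state$bounds[2],
                         max(state$bounds[1],
                             state$levels[i] + dir * state$step))
  state$last_direction[i] <- dir
  state$active <- 3L - i
  state
}

#' Win probability of a synthetic player
#'
#' The outcome model standing in for real gameplay: a logistic function of
#' the gap between latent ability and current difficulty,
#' `p(win) = sigmoid(kappa * (ability - difficulty))`.
#'
#' @param ability Latent player ability (difficulty units).
#' @param difficulty Current difficulty.
#' @param kappa Logistic slope (default 2); `kappa = 0` gives 50% wins at
#'   any ability.
#' @return Win probability.
#' @export
win_probability <- function(ability, difficulty, kappa = 2) {
  sigmoid(kappa * (ability - difficulty))
}

#' Generate one trial
#'
#' Plays a single trial against the staircase: draws the outcome from
#' [win_probability()], emits task features that grow with difficulty
#' (path length, proportion of non-UP frames, shrinking time limit) and
#' performance features tied to ability (key-press accuracy) or to neither
#' (pauses), then advances the staircase. Uses the current RNG state.
#'
#' @param state An [staircase_init()] state.
#' @param ability Latent player ability.
#' @param kappa Outcome-model slope.
#' @return A list with `outcome` (0/1), `features` (one-row tibble) and
#'   `state` (advanced staircase).
#' @export
generate_trial <- function(state, ability, kappa = 2) {
  d <- staircase_difficulty(state)
  outcome <- rbinom(1, 1, win_probability(ability, d, kappa))
  features <- tibble::tibble(
    path_length = max(3L, as.integer(round(10 + 3 * d + rnorm(1)))),
    prop_nonup = clip01(0.3 + 0.08 * d + rnorm(1, 0, 0.05)),
    prop_correct_keys = sigmoid(ability + rnorm(1, 0, 0.5)),
    prop_pauses = clip01(rbeta(1, 2, 18)),
    time_limit = max(5, 30 - 3 * d),
    difficulty = d)
  list(outcome = outcome, features = features,
       state = staircase_update(state, outcome))
}

#' Simulate a staircase-driven player
#'
#' Convenience wrapper running one synthetic player through the double
#' staircase for `n_trials`, recording outcomes and difficulties.
#'
#' @inheritParams generate_trial
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial`, `difficulty`, `outcome`.
#' @export
simulate_staircase_player <- function(ability, n_trials, kappa = 2,
                                      seed = NULL, state = staircase_init()) {
  if (!is.null(seed)) set.seed(seed)
  out <- integer(n_trials); diff <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    d <- staircase_difficulty(state)
    o <- rbinom(1, 1, win_probability(ability, d, kappa))
    out[t] <- o; diff[t] <- d
    state <- staircase_update(state, o)
  }
  tibble::tibble(trial = seq_len(n_trials), difficulty = diff, outcome = out)
}
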