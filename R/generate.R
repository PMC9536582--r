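ATTRIBUTION_OPTIONS <- c("Internal", "Maze", "Rotations", "Luck")

DATASET_COLUMNS <- c("participant", "probe", "session", "outcome",
                     "attribution", "skill_report", "path_length",
                     "prop_nonup", "prop_correct_keys", "prop_pauses",
                     "time_limit", "difficulty")

# z-score with the n-1 sd convention; constant input maps to zeros
safe_z <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# standardisation of the lagged skill report used at generation time: the
# fitted models z-score the report series, which cannot be done while the
# series is still being produced, so the generator uses fixed constants on
# the same scale (center 0.5, spread 0.2 on the [0,1] slider).
standardize_report <- function(x) (x - 0.5) / 0.2

#' Attribution class of a choice
#'
#' Collapses the four response options into the classes used by the skill
#' models: `Internal` is internal, `Maze`/`Rotations`/`Luck` are external,
#' and an unanswered probe (`NA`) is missing.
#'
#' @param x Character vector of attribution choices (`NA` = missing).
#' @return Character vector over `internal`, `external`, `missing`.
#' @export
attribution_class <- function(x) {
  ifelse(is.na(x), "missing", ifelse(x == "Internal", "internal", "external"))
}

#' A synthetic participant with known generative parameters
#'
#' Composes a latent ability (driving staircase outcomes and key accuracy),
#' a skill-report model ([skill_params()] under a [skill_model_spec()]) and
#' an attribution-choice model ([option_weights()] under an
#' [attribution_model_spec()]) into a generator for one participant's data.
#'
#' @param ability Latent ability (difficulty units).
#' @param skill_spec,skill_params Skill-model family member and parameters
#'   generating the latent skill trajectory and noisy reports.
#' @param attr_spec,attr_weights Attribution-model feature set and option
#'   weights generating the probe choices.
#' @param missing_prob Probability that an attribution probe is unanswered.
#' @param id Participant identifier.
#' @return An object of class `asrc_participant`.
#' @export
generative_participant <- function(ability, skill_spec, skill_params,
                                   attr_spec, attr_weights,
                                   missing_prob = 0.05, id = "p1") {
  stopifnot(missing_prob >= 0, missing_prob <= 1)
  structure(list(ability = ability, skill_spec = skill_spec,
                 skill_params = skill_params, attr_spec = attr_spec,
                 attr_weights = attr_weights, missing_prob = missing_prob,
                 id = id),
            class = "asrc_participant")
}

#' Reference generative participant
#'
#' The package's default study conditions for recovery experiments: a
#' 12-rate (session x outcome x attribution) skill model whose internal
#' learning rates exceed the external ones by 0.1, a session offset of
#' 0.05, report noise s.d. 0.1, and a bias+skill attribution model whose
#' skill weight on the Internal option is +1 after wins and -1 after
#' losses (the self-serving coupling).
#'
#' @inheritParams generative_participant
#' @return An `asrc_participant`.
#' @export
default_participant <- function(ability = 0, id = "p1", missing_prob = 0.05) {
  spec <- skill_model_spec("SAO")
  ext <- c(0.08, 0.12, 0.10, 0.14) # session x outcome cells
  alphas <- numeric(spec$n_rates)
  k <- 0
  for (s in 1:2) for (o in c(1, 0)) {
    k <- k + 1
    alphas[learning_rate_index(spec, s, o, "internal")] <- ext[k] + 0.1
    alphas[learning_rate_index(spec, s, o, "external")] <- ext[k]
    alphas[learning_rate_index(spec, s, o, "missing")] <- ext[k]
  }
  sp <- skill_params(spec, alphas, s0 = 0.5, session_offset = 0.05,
                     report_noise_sd = 0.1)
  aspec <- attribution_model_spec("skill")
  # internal-for-wins bias well above the other options (self-serving
  # pattern); the bias dominates the average skill-feature contribution
  w_win <- rbind(Internal = c(0.8, 1), Maze = c(0, -0.3),
                 Rotations = c(-0.1, -0.3))
  w_loss <- rbind(Internal = c(-0.8, -1), Maze = c(0.1, 0.3),
                  Rotations = c(0.1, 0.3))
  colnames(w_win) <- colnames(w_loss) <- c("bias", "skill")
  aw <- option_weights(aspec, w_win, w_loss)
  generative_participant(ability, spec, sp, aspec, aw,
                         missing_prob = missing_prob, id = id)
}

#' Generate one participant's synthetic dataset
#'
#' Emulates the probed maze task: `2 * n_probes` trials are played against
#' the double staircase; every second trial ends with a probe collecting an
#' attribution (sampled from the participant's attribution model given the
#' probe's features and the previous skill report, replaced by missing with
#' probability `missing_prob`) followed by a skill report (the latent
#' Rescorla-Wagner trajectory value plus Gaussian noise, clipped to the
#' `[0,1]` slider). The first half of the probes form session 1.
#'
#' @param participant A [generative_participant()].
#' @param n_probes Number of probes (>= 2); the task has twice as many trials.
#' @param seed Optional integer seed.
#' @param kappa Outcome-model slope passed to [generate_trial()].
#' @return A tibble with one row per probe (columns
#'   `participant, probe, session, outcome, attribution, skill_report` and
#'   the probed trial's task/performance features).
#' @export
generate_dataset <- function(participant, n_probes = 120, seed = NULL,
                             kappa = 2) {
  stopifnot(inherits(participant, "asrc_participant"))
  if (n_probes < 2) stop("`n_probes` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n_trials <- 2L * n_probes
  state <- staircase_init()
  trials <- vector("list", n_trials)
  outcomes <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    g <- generate_trial(state, participant$ability, kappa)
    trials[[t]] <- g$features
    outcomes[t] <- g$outcome
    state <- g$state
  }
  probe_trials <- seq(2L, n_trials, by = 2L)
  feats <- do.call(rbind, trials[probe_trials])
  o <- outcomes[probe_trials]
  session <- rep(1:2, each = ceiling(n_probes / 2))[seq_len(n_probes)]
  t0_ii <- match(2L, session)

  # generation-time feature matrix for the attribution model
  zfeat <- feats
  for (nm in c("path_length", "prop_nonup", "prop_correct_keys",
               "prop_pauses")) {
    zfeat[[nm]] <- safe_z(feats[[nm]])
  }
  active <- participant$attr_spec$features
  sp <- participant$skill_params
  spec <- participant$skill_spec

  attribution <- character(n_probes)
  report <- numeric(n_probes)
  s <- sp$s0
  prev_report <- NA_real_
  for (i in seq_len(n_probes)) {
    fvec <- c(bias = 1)
    for (nm in active) {
      fvec[nm] <- if (nm == "skill") {
        if (is.na(prev_report)) 0 else standardize_report(prev_report)
      } else zfeat[[nm]][i]
    }
    sc <- option_scores(participant$attr_weights, fvec[-1],
                        valence = if (o[i] == 1) "win" else "loss")
    pr <- choice_probabilities(sc)
    choice <- sample(ATTRIBUTION_OPTIONS, 1, prob = pr)
    if (runif(1) < participant$missing_prob) choice <- NA_character_
    attribution[i] <- choice
    cls <- attribution_class(choice)
    idx <- learning_rate_index(spec, session[i], o[i], cls)
    delta <- o[i] - s
    s <- s + sp$alphas[idx] * delta
    if (i == t0_ii) s <- s + sp$session_offset
    s <- clip01(s)
    report[i] <- clip01(s + rnorm(1, 0, sp$report_noise_sd))
    prev_report <- report[i]
  }
  base <- data.frame(participant = participant$id, probe = seq_len(n_probes),
                     session = session, outcome = o,
                     attribution = attribution, skill_report = report,
                     stringsAsFactors = FALSE)
  tibble::as_tibble(cbind(base, as.data.frame(feats)))
}

#' Generate a synthetic cohort
#'
#' @param participants List of [generative_participant()] objects (or an
#'   integer: that many [default_participant()]s with abilities drawn from a
#'   standard normal).
#' @inheritParams generate_dataset
#' @return A single tibble stacking all participants' datasets.
#' @export
generate_cohort <- function(participants = 40, n_probes = 120, seed = NULL,
                            kappa = 2) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(participants) && length(participants) == 1) {
    abilities <- rnorm(participants)
    participants <- lapply(seq_len(participants), function(i) {
      default_participant(abilities[i], id = sprintf("p%02d", i))
    })
  }
  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(participants)) else
    as.list(seed + seq_along(participants))
  do.call(rbind, Map(function(p, s) generate_dataset(p, n_probes, s, kappa),
                     participants, sub_seeds))
}

#' Write / read probe-aligned datasets
#'
#' Tidy CSV persistence with schema validation; `read_dataset()` reports
#' malformed rows with their file line numbers.
#'
#' @param data A dataset tibble (possibly several participants).
#' @param path File path.
#' @return `read_dataset()` returns the validated tibble.
#' @export
write_dataset <- function(data, path) {
  miss <- setdiff(DATASET_COLUMNS, names(data))
  if (length(miss)) stop("dataset is missing columns: ",
                         paste(miss, collapse = ", "))
  write.csv(data[DATASET_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(miss)) stop("file is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) return(tibble::as_tibble(raw))
  bad_line <- function(ok, what) {
    if (any(!ok)) stop("malformed ", what, " at line(s) ",
                       paste(which(!ok) + 1L, collapse = ", "),
                       " of ", path)
  }
  bad_line(raw$outcome %in% c(0, 1), "outcome (must be 0/1)")
  bad_line(raw$session %in% c(1, 2), "session (must be 1/2)")
  bad_line(is.na(raw$attribution) | raw$attribution %in% ATTRIBUTION_OPTIONS,
           "attribution")
  for (nm in c("skill_report", "prop_nonup", "prop_correct_keys",
               "prop_pauses")) {
    bad_line(is.finite(raw[[nm]]) & raw[[nm]] >= 0 & raw[[nm]] <= 1, nm)
  }
  bad_line(is.finite(raw$path_length) & raw$path_length >= 1, "path_length")
  raw$probe <- as.integer(raw$probe)
  raw$session <- as.integer(raw$session)
  raw$outcome <- as.integer(raw$outcome)
  raw$path_length <- as.integer(raw$path_length)
  ord <- order(raw$participant, raw$probe)
  tibble::as_tibble(raw[ord, ])
}

#' First probe of the second session
#'
#' @param data One participant's dataset rows, ordered by probe.
#' @return 1-based probe index of the session boundary (0 if none).
#' @export
session_boundary <- function(data) {
  i <- match(2L, data$session)
  if (is.na(i)) 0L else i
}
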