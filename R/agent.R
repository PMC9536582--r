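#' Parameters of the attribution-skill-cycle agent
#'
#' Bundles the parameters of the simulated agent: the sigmoidal attribution
#' rule (indifference points `x0_win`, `x0_loss` and non-negative slopes
#' `beta_win`, `beta_loss`) and the attribution-gated Rescorla-Wagner update
#' with one learning rate per attribution x outcome cell.
#'
#' @param x0_win,x0_loss Sigmoid indifference points (skill units) for wins
#'   and losses: the skill belief at which an internal attribution is as
#'   likely as an external one.
#' @param beta_win,beta_loss Non-negative sigmoid slopes controlling how
#'   sensitive attribution is to the current skill belief.
#' @param alpha Named numeric vector of four learning rates in `[0, 1]`:
#'   `internal_win`, `external_win`, `internal_loss`, `external_loss`.
#' @param s0 Initial skill belief (unbounded real; the agent's belief scale).
#'
#' @return An object of class `asrc_agent_params`.
#' @examples
#' agent_params() # the benign reference regime
#' @export
agent_params <- function(x0_win = 0, x0_loss = 0, beta_win = 2, beta_loss = 2,
                         alpha = c(internal_win = 0.1, external_win = 0.05,
                                   internal_loss = 0.1, external_loss = 0.05),
                         s0 = 0) {
  need <- c("internal_win", "external_win", "internal_loss", "external_loss")
  if (!all(need %in% names(alpha))) {
    stop("`alpha` must be named with: ", paste(need, collapse = ", "))
  }
  alpha <- alpha[need]
  stopifnot(is.finite(x0_win), is.finite(x0_loss), is.finite(s0))
  if (!is.finite(beta_win) || !is.finite(beta_loss) ||
      beta_win < 0 || beta_loss < 0) {
    stop("`beta_win` and `beta_loss` must be finite and >= 0")
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("all learning rates in `alpha` must lie in [0, 1]")
  }
  structure(list(x0_win = x0_win, x0_loss = x0_loss, beta_win = beta_win,
                 beta_loss = beta_loss, alpha = alpha, s0 = s0),
            class = "asrc_agent_params")
}

#' Probability of an internal attribution
#'
#' The probability that the agent attributes the current outcome internally,
#' a sigmoid of the current skill belief for wins and an inverse sigmoid for
#' losses.
#'
#' @param skill Current skill belief(s); finite numeric.
#' @param outcome 0/1 outcome(s) (1 = win), recycled against `skill`.
#' @param params An [agent_params()] object.
#' @return Probability of internal attribution, in `[0, 1]`.
#' @examples
#' attribution_probability(1, 1, agent_params()) # ~0.88
#' @export
attribution_probability <- function(skill, outcome, params) {
  stopifnot(inherits(params, "asrc_agent_params"))
  if (any(!is.finite(skill))) stop("`skill` must be finite")
  if (!all(outcome %in% c(0, 1))) stop("`outcome` must be 0 or 1")
  ifelse(outcome == 1,
         sigmoid(params$beta_win * (skill - params$x0_win)),
         1 - sigmoid(params$beta_loss * (skill - params$x0_loss)))
}

#' Attribution-gated skill belief update
#'
#' One Rescorla-Wagner step: the prediction error is the outcome minus the
#' win expectation `sigmoid(skill)`, scaled by the learning rate of the
#' attribution x outcome cell.
#'
#' @inheritParams attribution_probability
#' @param attribution 0/1 (1 = internal).
#' @return Updated skill belief.
#' @examples
#' update_skill(0, 1, 1, agent_params()) # 0.05
#' @export
update_skill <- function(skill, outcome, attribution, params) {
  stopifnot(inherits(params, "asrc_agent_params"))
  if (any(!is.finite(skill))) stop("`skill` must be finite")
  if (!all(outcome %in% c(0, 1)) || !all(attribution %in% c(0, 1))) {
    stop("`outcome` and `attribution` must be 0 or 1")
  }
  cell <- ifelse(attribution == 1,
                 ifelse(outcome == 1, "internal_win", "internal_loss"),
                 ifelse(outcome == 1, "external_win", "external_loss"))
  skill + params$alpha[cell] * (outcome - sigmoid(skill))
}

#' Fixed outcome schedule
#'
#' Draws a fair-coin win/loss sequence, optionally followed by an unbroken
#' loss streak; the same schedule is shared by every run of an ensemble so
#' that run-to-run variability comes only from attribution sampling.
#'
#' @param n_trials Number of coin-flip trials.
#' @param seed Optional integer seed.
#' @param streak Number of losses appended after the coin flips.
#' @return Integer vector of 0/1 outcomes.
#' @export
outcome_schedule <- function(n_trials, seed = NULL, streak = 0) {
  stopifnot(n_trials >= 0, streak >= 0)
  if (!is.null(seed)) set.seed(seed)
  c(rbinom(n_trials, 1, 0.5), rep(0L, streak))
}

new_ensemble <- function(skill, attribution, outcomes, params, seed,
                         decoupled = FALSE, match_rates = NULL) {
  structure(list(skill = skill, attribution = attribution,
                 outcomes = outcomes, params = params, seed = seed,
                 decoupled = decoupled, match_rates = match_rates),
            class = "asrc_ensemble")
}

#' Simulate an ensemble of coupled agents
#'
#' Runs `n_runs` agents with identical parameters over one shared outcome
#' schedule. Each run starts at `s0`, samples its attribution from
#' [attribution_probability()] and updates skill via [update_skill()], so
#' randomness enters only through attribution sampling.
#'
#' @param params An [agent_params()] object.
#' @param outcomes 0/1 outcome schedule shared by all runs.
#' @param n_runs Number of runs (>= 1).
#' @param seed Optional integer seed; equal seeds give identical ensembles.
#' @return An `asrc_ensemble` with a `skill` matrix (`n_runs` x `T + 1`,
#'   first column `s0`) and an `attribution` matrix (`n_runs` x `T`).
#' @export
simulate_ensemble <- function(params, outcomes, n_runs = 100, seed = NULL) {
  stopifnot(inherits(params, "asrc_agent_params"), n_runs >= 1)
  if (!all(outcomes %in% c(0, 1))) stop("`outcomes` must be 0/1")
  if (!is.null(seed)) set.seed(seed)
  n_t <- length(outcomes)
  skill <- matrix(params$s0, n_runs, n_t + 1)
  attribution <- matrix(NA_integer_, n_runs, max(n_t, 1))[, seq_len(n_t), drop = FALSE]
  for (r in seq_len(n_runs)) {
    s <- params$s0
    for (t in seq_len(n_t)) {
      p_int <- attribution_probability(s, outcomes[t], params)
      a <- rbinom(1, 1, p_int)
      s <- unname(update_skill(s, outcomes[t], a, params))
      attribution[r, t] <- a
      skill[r, t + 1] <- s
    }
  }
  new_ensemble(skill, attribution, outcomes, params, seed)
}

#' Simulate the decoupling ablation
#'
#' Removes the influence of skill beliefs on attributions while preserving
#' the average attribution propensity: attributions are drawn i.i.d. per
#' outcome valence with probability equal to the coupled reference
#' ensemble's empirical internal-attribution rate for that valence. Skill
#' is still updated by the usual Rescorla-Wagner rule.
#'
#' @inheritParams simulate_ensemble
#' @param reference Optional coupled `asrc_ensemble` to match; simulated
#'   with the same arguments when omitted.
#' @return An `asrc_ensemble` with `decoupled = TRUE` and the matched
#'   per-valence internal rates in `match_rates`.
#' @export
decouple_attributions <- function(params, outcomes, n_runs = 100, seed = NULL,
                                  reference = NULL) {
  if (is.null(reference)) {
    reference <- simulate_ensemble(params, outcomes, n_runs, seed)
  }
  stopifnot(inherits(reference, "asrc_ensemble"))
  win_cols <- which(reference$outcomes == 1)
  loss_cols <- which(reference$outcomes == 0)
  rates <- c(win = mean(reference$attribution[, win_cols]),
             loss = mean(reference$attribution[, loss_cols]))
  if (!is.null(seed)) set.seed(seed + 1L)
  n_t <- length(outcomes)
  skill <- matrix(params$s0, n_runs, n_t + 1)
  attribution <- matrix(NA_integer_, n_runs, max(n_t, 1))[, seq_len(n_t), drop = FALSE]
  for (r in seq_len(n_runs)) {
    s <- params$s0
    for (t in seq_len(n_t)) {
      p_int <- if (outcomes[t] == 1) rates[["win"]] else rates[["loss"]]
      a <- rbinom(1, 1, p_int)
      s <- unname(update_skill(s, outcomes[t], a, params))
      attribution[r, t] <- a
      skill[r, t + 1] <- s
    }
  }
  new_ensemble(skill, attribution, outcomes, params, seed,
               decoupled = TRUE, match_rates = rates)
}

#' Ensemble summary tables
#'
#' Computes the trial-level summaries used to characterise ensembles of
#' simulated agents: (i) internal-attribution proportion by pre-update
#' skill quintile and outcome, pooled over runs and trials; (ii) mean skill
#' update per outcome x attribution cell; (iii) mean and s.e.m. skill
#' trajectories after a median split on the internal-attribution proportion
#' over each run's first five wins; (iv) internal-attribution proportions
#' in the first and second batches of ten losses after trial 50, for runs
#' in the top and bottom quartile of skill at trial 50.
#'
#' @param ensemble An `asrc_ensemble`.
#' @return A list of tibbles `quintile_attribution`, `update_by_cell`,
#'   `first_wins_split`, `loss_batches`, plus `n_excluded_first_wins`, the
#'   number of runs without five wins (excluded from (iii)).
#' @export
ensemble_summaries <- function(ensemble) {
  stopifnot(inherits(ensemble, "asrc_ensemble"))
  o <- ensemble$outcomes
  n_t <- length(o)
  if (n_t == 0 || nrow(ensemble$skill) == 0) stop("ensemble is empty")
  skill_pre <- ensemble$skill[, seq_len(n_t), drop = FALSE] # belief before trial t
  skill_post <- ensemble$skill[, seq_len(n_t) + 1, drop = FALSE]
  att <- ensemble$attribution
  out_mat <- matrix(o, nrow(att), n_t, byrow = TRUE)

  # (i) quintiles of the pooled pre-update skill distribution, ties by rank
  v <- as.vector(skill_pre)
  bin <- ceiling(5 * rank(v, ties.method = "first") / length(v))
  quintile_attribution <- stats::aggregate(
    list(prop_internal = as.vector(att)),
    by = list(quintile = bin, outcome = as.vector(out_mat)),
    FUN = mean)
  quintile_attribution <- tibble::as_tibble(quintile_attribution)

  # (ii) mean update per outcome x attribution cell
  upd <- as.vector(skill_post - skill_pre)
  update_by_cell <- tibble::as_tibble(stats::aggregate(
    list(mean_update = upd),
    by = list(outcome = as.vector(out_mat), attribution = as.vector(att)),
    FUN = mean))

  # (iii) median split on internal proportion over first 5 wins
  win_idx <- which(o == 1)
  first_wins_split <- NULL
  n_excluded <- nrow(att)
  if (length(win_idx) >= 5) {
    w5 <- win_idx[1:5]
    prop5 <- rowMeans(att[, w5, drop = FALSE])
    n_excluded <- 0L
    grp <- ifelse(prop5 >= median(prop5), "high", "low")
    sem <- function(x) sd(x) / sqrt(length(x))
    rows <- lapply(c("high", "low"), function(g) {
      m <- ensemble$skill[grp == g, , drop = FALSE]
      tibble::tibble(group = g, trial = 0:n_t,
                     mean_skill = colMeans(m),
                     sem_skill = apply(m, 2, sem))
    })
    first_wins_split <- do.call(rbind, rows)
  }

  # (iv) loss batches after trial 50 by skill quartile at trial 50
  loss_batches <- NULL
  loss_after <- which(o == 0 & seq_len(n_t) > 50)
  if (n_t >= 50 && length(loss_after) >= 20) {
    b1 <- loss_after[1:10]; b2 <- loss_after[11:20]
    s50 <- ensemble$skill[, 51]
    qs <- quantile(s50, c(0.25, 0.75))
    grp_rows <- list(top = which(s50 >= qs[2]), bottom = which(s50 <= qs[1]))
    loss_batches <- do.call(rbind, lapply(names(grp_rows), function(g) {
      r <- grp_rows[[g]]
      tibble::tibble(group = g, batch = c(1L, 2L),
                     prop_internal = c(mean(att[r, b1]), mean(att[r, b2])))
    }))
  }

  list(quintile_attribution = quintile_attribution,
       update_by_cell = update_by_cell,
       first_wins_split = first_wins_split,
       loss_batches = loss_batches,
       n_excluded_first_wins = n_excluded)
}
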