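SKILL_MODEL_NAMES <- c("b", "S", "O", "A", "SA", "SO", "AO", "SAO")

#' Skill-model family member
#'
#' One of the eight Rescorla-Wagner variants for skill reports, defined by
#' which factors the learning rate varies over: session (`S`), outcome
#' (`O`) and attribution class (`A`, which adds a third rate for probes
#' with missing attributions). The baseline `b` has a single rate; the
#' full `SAO` model has 2 x 2 x 3 = 12.
#'
#' @param name One of `b, S, O, A, SA, SO, AO, SAO`.
#' @return An `asrc_skill_spec` with flags `S`, `O`, `A` and `n_rates`.
#' @export
skill_model_spec <- function(name = SKILL_MODEL_NAMES) {
  name <- match.arg(name)
  S <- grepl("S", name); O <- grepl("O", name); A <- grepl("A", name)
  structure(list(name = name, S = S, O = O, A = A,
                 n_rates = (if (S) 2L else 1L) * (if (O) 2L else 1L) *
                   (if (A) 3L else 1L)),
            class = "asrc_skill_spec")
}

ATTRIBUTION_CLASSES <- c("internal", "external", "missing")

#' Learning-rate index
#'
#' Deterministic bijection from (session, outcome, attribution class) onto
#' `1..n_rates` for a given model. Factors the model does not vary over are
#' ignored; the index is session-major, then outcome (win before loss),
#' then attribution class (internal, external, missing).
#'
#' @param spec A [skill_model_spec()].
#' @param session Session number, 1 or 2 (vectorised).
#' @param outcome 0/1 outcome (vectorised).
#' @param attribution_class One of `internal`, `external`, `missing`
#'   (vectorised); ignored unless the spec has the `A` flag.
#' @return Integer index/indices in `1..spec$n_rates`.
#' @export
learning_rate_index <- function(spec, session, outcome, attribution_class) {
  stopifnot(inherits(spec, "asrc_skill_spec"))
  if (!all(session %in% c(1, 2))) stop("`session` must be 1 or 2")
  if (!all(outcome %in% c(0, 1))) stop("`outcome` must be 0 or 1")
  if (!all(attribution_class %in% ATTRIBUTION_CLASSES)) {
    stop("`attribution_class` must be one of: ",
         paste(ATTRIBUTION_CLASSES, collapse = ", "))
  }
  n <- max(length(session), length(outcome), length(attribution_class))
  session <- rep_len(session, n)
  outcome <- rep_len(outcome, n)
  attribution_class <- rep_len(attribution_class, n)
  n_o <- if (spec$O) 2L else 1L
  n_a <- if (spec$A) 3L else 1L
  s_i <- if (spec$S) as.integer(session) - 1L else integer(n)
  o_i <- if (spec$O) ifelse(outcome == 1, 0L, 1L) else integer(n)
  a_i <- if (spec$A) match(attribution_class, ATTRIBUTION_CLASSES) - 1L
         else integer(n)
  as.integer(s_i * n_o * n_a + o_i * n_a + a_i + 1L)
}

#' Parameters of a skill-report model
#'
#' @param spec A [skill_model_spec()].
#' @param alphas Learning rates in `[0, 1]`, length `spec$n_rates`, ordered
#'   as by [learning_rate_index()].
#' @param s0 Initial latent skill in `[0, 1]`.
#' @param session_offset Additive jump of the latent skill at the first
#'   probe of session 2 (effect of the between-session break).
#' @param report_noise_sd Standard deviation of the Gaussian report noise
#'   (fixed at 0.1 in the reference analyses).
#' @return An `asrc_skill_params`.
#' @export
skill_params <- function(spec, alphas, s0 = 0.5, session_offset = 0,
                         report_noise_sd = 0.1) {
  stopifnot(inherits(spec, "asrc_skill_spec"))
  if (length(alphas) != spec$n_rates) {
    stop("`alphas` must have length ", spec$n_rates, " for model ",
         spec$name)
  }
  if (any(alphas < 0 | alphas > 1)) stop("`alphas` must lie in [0, 1]")
  if (s0 < 0 || s0 > 1) stop("`s0` must lie in [0, 1]")
  if (!is.finite(session_offset)) stop("`session_offset` must be finite")
  if (report_noise_sd <= 0) stop("`report_noise_sd` must be > 0")
  structure(list(spec = spec, alphas = as.numeric(alphas), s0 = s0,
                 session_offset = session_offset,
                 report_noise_sd = report_noise_sd),
            class = "asrc_skill_params")
}

# per-probe learning-rate indices for one participant's ordered rows
dataset_rate_idx <- function(spec, data) {
  learning_rate_index(spec, data$session, data$outcome,
                      attribution_class(data$attribution))
}

#' Latent skill trajectory
#'
#' Runs the probe-grain Rescorla-Wagner recursion
#' `s_t = s_{t-1} + alpha * (o_t - s_{t-1})` (plus the session offset at the
#' first probe of session 2) over one participant's ordered dataset,
#' clipping the latent state to the `[0, 1]` slider after each update.
#'
#' @param params An [skill_params()].
#' @param data One participant's dataset rows, ordered by probe.
#' @return A tibble with `probe`, `latent` (s_t) and `delta`
#'   (prediction error o_t - s_{t-1}).
#' @export
predict_trajectory <- function(params, data) {
  stopifnot(inherits(params, "asrc_skill_params"))
  spec <- params$spec
  idx <- dataset_rate_idx(spec, data)
  s <- skill_trajectory_cpp(as.integer(data$outcome), idx, params$alphas,
                            params$s0, params$session_offset,
                            session_boundary(data))
  prev <- c(params$s0, s[-length(s)])
  tibble::tibble(probe = data$probe, latent = s,
                 delta = data$outcome - prev)
}

#' Skill-report log-likelihood
#'
#' Sum over probes of the log Normal density of the reported skill around
#' the latent trajectory, with s.d. `report_noise_sd`. Probes with missing
#' reports are dropped from the likelihood, but still advance the latent
#' recursion.
#'
#' @inheritParams predict_trajectory
#' @return Log-likelihood (scalar).
#' @export
skill_loglik <- function(params, data) {
  stopifnot(inherits(params, "asrc_skill_params"))
  obs <- !is.na(data$skill_report)
  rep_ <- data$skill_report
  rep_[!obs] <- 0
  if (any(rep_[obs] < 0 | rep_[obs] > 1)) {
    stop("skill reports must lie in [0, 1]")
  }
  ll <- skill_loglik_cpp(rep_, obs, as.integer(data$outcome),
                         dataset_rate_idx(params$spec, data),
                         params$alphas, params$s0, params$session_offset,
                         session_boundary(data), params$report_noise_sd)
  if (!is.finite(ll)) stop("non-finite skill log-likelihood")
  ll
}
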