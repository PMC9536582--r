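ATTR_FEATURE_SETS <- list(
  bias = character(0),
  skill = "skill",
  perf = c("prop_correct_keys", "prop_pauses"),
  perf_task = c("prop_correct_keys", "prop_pauses", "path_length",
                "prop_nonup"),
  skill_task = c("skill", "path_length", "prop_nonup"),
  full = c("skill", "prop_correct_keys", "prop_pauses", "path_length",
           "prop_nonup"))

#' Attribution-model feature set
#'
#' One of the six softmax linear choice models for the four attribution
#' options, defined by the features entering the option scores alongside a
#' constant bias. Each model has separate weights for wins and losses and
#' independent weights for three options (Internal, Maze, Rotations); the
#' Luck weights are the negative sum of the other three, so the four
#' option scores sum to zero for every feature vector.
#'
#' @param feature_set One of `bias`, `skill`, `perf`, `perf_task`,
#'   `skill_task`, `full` (`full` = skill + performance + task features,
#'   36 parameters per participant).
#' @return An `asrc_attr_spec` with `features` and `n_params`.
#' @export
attribution_model_spec <- function(feature_set = names(ATTR_FEATURE_SETS)) {
  feature_set <- match.arg(feature_set)
  features <- ATTR_FEATURE_SETS[[feature_set]]
  structure(list(feature_set = feature_set, features = features,
                 n_params = 2L * 3L * (1L + length(features))),
            class = "asrc_attr_spec")
}

#' Valence-specific option weights
#'
#' @param spec An [attribution_model_spec()].
#' @param win,loss 3 x (1 + n_features) numeric matrices of weights for the
#'   Internal, Maze and Rotations options (rows) over `bias` plus the
#'   spec's features (columns).
#' @return An `asrc_option_weights`.
#' @export
option_weights <- function(spec, win, loss) {
  stopifnot(inherits(spec, "asrc_attr_spec"))
  k <- 1L + length(spec$features)
  for (m in list(win, loss)) {
    if (!is.matrix(m) || nrow(m) != 3 || ncol(m) != k) {
      stop("weight matrices must be 3 x ", k, " for feature set '",
           spec$feature_set, "'")
    }
  }
  dn <- list(c("Internal", "Maze", "Rotations"), c("bias", spec$features))
  dimnames(win) <- dimnames(loss) <- dn
  structure(list(spec = spec, win = win, loss = loss),
            class = "asrc_option_weights")
}

# 4 x k weight matrix including the derived Luck row
full_weight_matrix <- function(weights, valence) {
  W <- weights[[valence]]
  rbind(W, Luck = -colSums(W))
}

#' Option scores
#'
#' Dot products of the valence-appropriate weights with the feature vector
#' for Internal, Maze and Rotations; the Luck score is their negative sum,
#' so the four scores sum to zero exactly.
#'
#' @param weights An [option_weights()].
#' @param features Named numeric vector of the spec's active features
#'   (without the bias, which is always 1).
#' @param valence `"win"` or `"loss"`.
#' @return Named numeric vector of four scores.
#' @export
option_scores <- function(weights, features, valence = c("win", "loss")) {
  stopifnot(inherits(weights, "asrc_option_weights"))
  valence <- match.arg(valence)
  active <- weights$spec$features
  if (length(active)) {
    if (is.null(names(features)) || !setequal(names(features), active)) {
      stop("`features` must be named with exactly: ",
           paste(active, collapse = ", "))
    }
    f <- c(bias = 1, features[active])
  } else {
    f <- c(bias = 1)
  }
  W <- weights[[valence]]
  s <- drop(W %*% f)
  c(s, Luck = -sum(s))
}

#' Softmax choice probabilities
#'
#' @param scores Finite numeric vector of option scores.
#' @return Probabilities summing to 1; invariant to adding a constant to
#'   all scores (the maximum is subtracted before exponentiation).
#' @export
choice_probabilities <- function(scores) {
  if (any(!is.finite(scores))) stop("`scores` must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Attribution-model feature matrix
#'
#' Builds the per-probe feature matrix for one participant: a bias column
#' of ones; the skill feature (the previous probe's skill report, z-scored
#' within participant, 0 for the first probe); and the active task and
#' performance features z-scored within participant.
#'
#' @param data One participant's dataset rows, ordered by probe.
#' @param spec An [attribution_model_spec()].
#' @param skill_scale `"zscore"` (fitting default) or `"fixed"`, the
#'   generation-time standardisation of the lagged report (see the package
#'   vignette).
#' @return Numeric matrix `n_probes x (1 + n_features)`.
#' @export
attribution_features <- function(data, spec,
                                 skill_scale = c("zscore", "fixed")) {
  stopifnot(inherits(spec, "asrc_attr_spec"))
  skill_scale <- match.arg(skill_scale)
  n <- nrow(data)
  X <- matrix(1, n, 1 + length(spec$features),
              dimnames = list(NULL, c("bias", spec$features)))
  for (nm in spec$features) {
    if (nm == "skill") {
      z <- if (skill_scale == "zscore") safe_z(data$skill_report)
           else standardize_report(data$skill_report)
      X[, nm] <- c(0, z[-n])
    } else {
      X[, nm] <- safe_z(data[[nm]])
    }
  }
  X
}

choice_index <- function(attribution) {
  match(attribution, ATTRIBUTION_OPTIONS)
}

#' Attribution-choice log-likelihood
#'
#' Sum of log softmax probabilities of the observed choices under the
#' valence-appropriate weights (valence = the probed trial's outcome).
#' Missing attributions carry no choice information and are excluded.
#'
#' @inheritParams attribution_features
#' @param weights An [option_weights()].
#' @return Log-likelihood (scalar).
#' @export
attr_loglik <- function(weights, data, skill_scale = c("zscore", "fixed")) {
  stopifnot(inherits(weights, "asrc_option_weights"))
  ch <- choice_index(data$attribution)
  if (all(is.na(ch))) stop("dataset has no non-missing attributions")
  X <- attribution_features(data, weights$spec, match.arg(skill_scale))
  attr_loglik_cpp(as.integer(ch), as.integer(data$outcome), X,
                  weights$win, weights$loss)
}

#' Baseline option preferences
#'
#' The softmax of the bias parameters alone (all feature weights clamped
#' to 0): the model-implied baseline probability of each option per
#' valence, comparable across options unlike the raw biases.
#'
#' @param weights An [option_weights()].
#' @return A tibble with `valence`, `option`, `prob` (summing to 1 within
#'   valence).
#' @export
bias_preferences <- function(weights) {
  stopifnot(inherits(weights, "asrc_option_weights"))
  rows <- lapply(c("win", "loss"), function(v) {
    W <- full_weight_matrix(weights, v)
    p <- choice_probabilities(W[, "bias"])
    tibble::tibble(valence = v, option = rownames(W), prob = unname(p))
  })
  do.call(rbind, rows)
}

#' Average marginal feature effect
#'
#' The contribution of feature `x` to choosing option `A` after outcome
#' `o`: the derivative of the softmax choice probability with respect to
#' `x`, evaluated at `x = 0` with all other features at their trial
#' values, averaged over the dataset's probes of the given valence. Uses
#' the analytic softmax gradient
#' `dp(A)/dx = p(A) * (w_Ax - sum_B p(B) * w_Bx)`.
#'
#' @inheritParams attr_loglik
#' @param feature An active feature of the spec.
#' @param option One of `Internal`, `Maze`, `Rotations`, `Luck`.
#' @param valence `"win"` or `"loss"`.
#' @return The average marginal effect (scalar).
#' @export
feature_effect <- function(weights, data, feature, option,
                           valence = c("win", "loss"),
                           skill_scale = c("zscore", "fixed")) {
  stopifnot(inherits(weights, "asrc_option_weights"))
  valence <- match.arg(valence)
  spec <- weights$spec
  if (!feature %in% spec$features) {
    stop("`feature` must be one of the spec's features: ",
         paste(spec$features, collapse = ", "))
  }
  if (!option %in% ATTRIBUTION_OPTIONS) stop("unknown `option`")
  X <- attribution_features(data, spec, match.arg(skill_scale))
  keep <- data$outcome == (if (valence == "win") 1 else 0)
  if (!any(keep)) return(0)
  X <- X[keep, , drop = FALSE]
  X[, feature] <- 0
  W <- full_weight_matrix(weights, valence)
  S <- X %*% t(W)                       # n x 4 scores at x = 0
  E <- exp(S - apply(S, 1, max))
  P <- E / rowSums(E)
  wx <- W[, feature]
  eff <- P[, option] * (wx[option] - drop(P %*% wx))
  mean(eff)
}
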