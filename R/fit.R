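# ---- parameter naming -------------------------------------------------

skill_param_names <- function(spec) {
  nm <- character(spec$n_rates)
  for (s in 1:2) for (o in c(1, 0)) for (cl in ATTRIBUTION_CLASSES) {
    idx <- learning_rate_index(spec, s, o, cl)
    parts <- c(if (spec$S) paste0("s", s),
               if (spec$O) ifelse(o == 1, "win", "loss"),
               if (spec$A) cl)
    nm[idx] <- if (length(parts)) {
      paste0("alpha[", paste(parts, collapse = ","), "]")
    } else "alpha"
  }
  c(nm, "s0", "session_offset")
}

attr_param_names <- function(spec) {
  feats <- c("bias", spec$features)
  opts <- c("Internal", "Maze", "Rotations")
  nm <- character(0)
  for (v in c("win", "loss")) for (j in feats) for (o in opts) {
    nm <- c(nm, paste(v, o, j, sep = "."))
  }
  nm
}

# order matches the column-major matrix(w, 3, k) reconstruction below,
# except names above iterate feature-major; rebuild accordingly
attr_unpack <- function(w, k) {
  half <- 3L * k
  list(win = matrix(w[seq_len(half)], 3L, k),
       loss = matrix(w[half + seq_len(half)], 3L, k))
}

split_participants <- function(data) {
  if (nrow(data) == 0) stop("data is empty")
  ids <- unique(data$participant)
  lapply(stats::setNames(ids, ids), function(id) {
    d <- data[data$participant == id, ]
    d[order(d$probe), ]
  })
}

dataset_fingerprint <- function(data) {
  list(ids = sort(unique(data$participant)), n = nrow(data),
       outcome_sum = sum(data$outcome),
       report_sum = round(sum(data$skill_report), 9))
}

# ---- skill-model fitting ----------------------------------------------

# per-participant MAP-style initialisation on the unit-interval scale:
# short chains started from random points spend most of their budget
# burning in, so chains are seeded at (jittered) penalised optima instead
map_init_unit <- function(loglik1, P, D, start) {
  eps <- 1e-4
  t(vapply(seq_len(P), function(p) {
    obj <- function(th) -loglik1(p, th)
    opt <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = eps,
                   upper = 1 - eps, control = list(maxit = 100)),
      error = function(e) list(par = start))
    pmin(pmax(opt$par, eps), 1 - eps)
  }, numeric(D)))
}

# moment-matched Beta hyperparameters from initial individual values
beta_moment_init <- function(theta) {
  m <- pmin(pmax(colMeans(theta), 0.02), 0.98)
  v <- pmax(apply(theta, 2, var), 1e-4)
  v <- pmin(v, m * (1 - m) * 0.9)
  nu <- m * (1 - m) / v - 1
  list(a = pmin(pmax(m * nu, 0.5), 50), b = pmin(pmax((1 - m) * nu, 0.5), 50))
}

run_skill_chain <- function(pd, spec, hier, n_iter, warmup, seed, noise_sd,
                            theta0) {
  set.seed(seed)
  P <- length(pd); K <- spec$n_rates; D <- K + 2L
  theta <- plogis(qlogis(theta0) + matrix(rnorm(P * D, 0, 0.15), P, D))
  theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
  loglik1 <- function(p, th) {
    x <- pd[[p]]
    skill_loglik_cpp(x$report, x$observed, x$outcome, x$rate_idx,
                     th[seq_len(K)], th[K + 1L], 2 * th[K + 2L] - 1,
                     x$t0, noise_sd)
  }
  lp <- vapply(seq_len(P), function(p) loglik1(p, theta[p, ]), numeric(1))
  scale <- matrix(0.5, P, D); accw <- matrix(0L, P, D)
  hy0 <- beta_moment_init(theta)
  a <- hy0$a; b <- hy0$b
  keep <- n_iter - warmup
  th_draws <- array(NA_real_, c(keep, P, D))
  hy_draws <- if (hier) matrix(NA_real_, keep, 2L * D) else NULL
  for (it in seq_len(n_iter)) {
    for (p in seq_len(P)) {
      thp <- theta[p, ]
      for (d in seq_len(D)) {
        cur <- thp[d]
        z2 <- log(cur / (1 - cur)) + rnorm(1, 0, scale[p, d])
        new <- 1 / (1 + exp(-z2))
        new <- min(max(new, 1e-12), 1 - 1e-12)
        prop <- thp; prop[d] <- new
        ll2 <- loglik1(p, prop)
        logr <- ll2 - lp[p] + log(new * (1 - new)) - log(cur * (1 - cur))
        if (hier) {
          logr <- logr + dbeta(new, a[d], b[d], log = TRUE) -
            dbeta(cur, a[d], b[d], log = TRUE)
        }
        if (is.finite(logr) && log(runif(1)) < logr) {
          thp[d] <- new; lp[p] <- ll2; accw[p, d] <- accw[p, d] + 1L
        }
      }
      theta[p, ] <- thp
    }
    if (hier) {
      for (d in seq_len(D)) {
        td <- theta[, d]
        cur_lp <- sum(dbeta(td, a[d], b[d], log = TRUE))
        a2 <- a[d] * exp(rnorm(1, 0, 0.35))
        logr <- sum(dbeta(td, a2, b[d], log = TRUE)) - cur_lp +
          dgamma(a2, 2, rate = 0.2, log = TRUE) -
          dgamma(a[d], 2, rate = 0.2, log = TRUE) + log(a2) - log(a[d])
        if (is.finite(logr) && log(runif(1)) < logr) {
          a[d] <- a2
          cur_lp <- sum(dbeta(td, a[d], b[d], log = TRUE))
        }
        b2 <- b[d] * exp(rnorm(1, 0, 0.35))
        logr <- sum(dbeta(td, a[d], b2, log = TRUE)) - cur_lp +
          dgamma(b2, 2, rate = 0.2, log = TRUE) -
          dgamma(b[d], 2, rate = 0.2, log = TRUE) + log(b2) - log(b[d])
        if (is.finite(logr) && log(runif(1)) < logr) b[d] <- b2
      }
    }
    if (it <= warmup && it %% 25L == 0L) {
      rate <- accw / 25
      scale <- scale * ifelse(rate < 0.25, 0.7, ifelse(rate > 0.6, 1.4, 1))
      accw[] <- 0L
    }
    if (it > warmup) {
      th_draws[it - warmup, , ] <- theta
      if (hier) hy_draws[it - warmup, ] <- c(a, b)
    }
  }
  list(theta = th_draws, hyper = hy_draws)
}

#' Fit a skill-report model
#'
#' Posterior sampling for one member of the Rescorla-Wagner skill-model
#' family, either independently per participant (flat priors on the unit
#' interval) or hierarchically with independent Beta population priors
#' over every individual parameter. Learning rates and `s0` live on
#' `[0, 1]`; the session offset is reparameterised as `2*theta - 1` so the
#' same Beta prior applies. Sampling is adaptive per-coordinate
#' Metropolis-within-Gibbs.
#'
#' @param data A probe-aligned dataset tibble (one or more participants).
#' @param spec A [skill_model_spec()] or its name.
#' @param mode `"hierarchical"` or `"independent"`.
#' @param chains,iter Number of chains and iterations per chain (the first
#'   `warmup` iterations are discarded; the reference analyses used 4
#'   chains of 1000, the package's desk default is 2 x 300).
#' @param warmup Warmup iterations per chain.
#' @param seed Optional integer seed.
#' @param report_noise_sd Fixed report noise s.d. (default 0.1).
#' @return An `asrc_fit` with per-participant posterior draws (natural
#'   scale), split-R-hat diagnostics, and the participant x sample
#'   log-likelihood matrix used by [waic()].
#' @export
fit_skill_model <- function(data, spec, mode = c("hierarchical", "independent"),
                            chains = 2, iter = 300,
                            warmup = floor(iter / 2), seed = NULL,
                            report_noise_sd = 0.1) {
  if (is.character(spec)) spec <- skill_model_spec(spec)
  stopifnot(inherits(spec, "asrc_skill_spec"))
  mode <- match.arg(mode)
  parts <- split_participants(data)
  pd <- lapply(parts, function(d) {
    obs <- !is.na(d$skill_report)
    rp <- d$skill_report; rp[!obs] <- 0
    list(report = rp, observed = obs, outcome = as.integer(d$outcome),
         rate_idx = dataset_rate_idx(spec, d), t0 = session_boundary(d))
  })
  K <- spec$n_rates; D <- K + 2L
  pnames <- skill_param_names(spec)
  loglik_unit <- function(p, th) {
    x <- pd[[p]]
    skill_loglik_cpp(x$report, x$observed, x$outcome, x$rate_idx,
                     th[seq_len(K)], th[K + 1L], 2 * th[K + 2L] - 1,
                     x$t0, report_noise_sd)
  }
  theta0 <- map_init_unit(loglik_unit, length(pd), D,
                          start = c(rep(0.15, K), 0.5, 0.5))
  seeds <- (seed %||% sample.int(1e6, 1)) + seq_len(chains)
  res <- lapply(seeds, function(s) {
    run_skill_chain(pd, spec, mode == "hierarchical", iter, warmup, s,
                    report_noise_sd, theta0)
  })
  finish_fit(res, pd, pnames, mode, spec, family = "skill",
             natural = function(draws) {
               draws[, D] <- 2 * draws[, D] - 1 # session offset
               draws
             },
             loglik1 = loglik_unit,
             data_id = dataset_fingerprint(data), seed = seed,
             config = list(chains = chains, iter = iter, warmup = warmup,
                           report_noise_sd = report_noise_sd))
}

# ---- attribution-model fitting ----------------------------------------

map_init_real <- function(loglik1, P, D) {
  t(vapply(seq_len(P), function(p) {
    obj <- function(w) -loglik1(p, w) + sum(w^2) / (2 * 2.5^2)
    opt <- tryCatch(
      stats::optim(rep(0, D), obj, method = "L-BFGS-B",
                   control = list(maxit = 100)),
      error = function(e) list(par = rep(0, D)))
    opt$par
  }, numeric(D)))
}

run_attr_chain <- function(pd, D, hier, n_iter, warmup, seed, w0) {
  set.seed(seed)
  P <- length(pd); k <- D / 6L
  w <- w0 + matrix(rnorm(P * D, 0, 0.1), P, D)
  loglik1 <- function(p, wv) {
    x <- pd[[p]]
    W <- attr_unpack(wv, k)
    attr_loglik_cpp(x$choice, x$outcome, x$X, W$win, W$loss)
  }
  lp <- vapply(seq_len(P), function(p) loglik1(p, w[p, ]), numeric(1))
  scale <- matrix(0.3, P, D); accw <- matrix(0L, P, D)
  mu <- colMeans(w); sig2 <- pmax(apply(w, 2, var), 0.01)
  prior_sd_ind <- 2.5
  keep <- n_iter - warmup
  w_draws <- array(NA_real_, c(keep, P, D))
  hy_draws <- if (hier) matrix(NA_real_, keep, 2L * D) else NULL
  for (it in seq_len(n_iter)) {
    for (p in seq_len(P)) {
      wp <- w[p, ]
      for (d in seq_len(D)) {
        cur <- wp[d]
        new <- cur + rnorm(1, 0, scale[p, d])
        prop <- wp; prop[d] <- new
        ll2 <- loglik1(p, prop)
        pr <- if (hier) {
          dnorm(new, mu[d], sqrt(sig2[d]), log = TRUE) -
            dnorm(cur, mu[d], sqrt(sig2[d]), log = TRUE)
        } else {
          dnorm(new, 0, prior_sd_ind, log = TRUE) -
            dnorm(cur, 0, prior_sd_ind, log = TRUE)
        }
        logr <- ll2 - lp[p] + pr
        if (is.finite(logr) && log(runif(1)) < logr) {
          wp[d] <- new; lp[p] <- ll2; accw[p, d] <- accw[p, d] + 1L
        }
      }
      w[p, ] <- wp
    }
    if (hier) {
      # conjugate Normal / inverse-gamma population updates
      for (d in seq_len(D)) {
        wd <- w[, d]
        v <- 1 / (P / sig2[d] + 1 / 25)
        mu[d] <- rnorm(1, v * sum(wd) / sig2[d], sqrt(v))
        sig2[d] <- 1 / rgamma(1, 2 + P / 2,
                              rate = 0.5 + sum((wd - mu[d])^2) / 2)
      }
    }
    if (it <= warmup && it %% 25L == 0L) {
      rate <- accw / 25
      scale <- scale * ifelse(rate < 0.25, 0.7, ifelse(rate > 0.6, 1.4, 1))
      accw[] <- 0L
    }
    if (it > warmup) {
      w_draws[it - warmup, , ] <- w
      if (hier) hy_draws[it - warmup, ] <- c(mu, sqrt(sig2))
    }
  }
  list(theta = w_draws, hyper = hy_draws)
}

#' Fit an attribution-choice model
#'
#' Posterior sampling for one member of the softmax linear attribution
#' family, independently per participant (Normal(0, 2.5) priors) or
#' hierarchically with Normal population priors over each weight
#' (conjugate population updates). Valence = the probed trial's outcome;
#' missing attributions are excluded from the likelihood.
#'
#' @inheritParams fit_skill_model
#' @param spec An [attribution_model_spec()] or its feature-set name.
#' @param skill_scale Standardisation of the lagged skill-report feature
#'   (see [attribution_features()]).
#' @return An `asrc_fit`.
#' @export
fit_attribution_model <- function(data, spec,
                                  mode = c("hierarchical", "independent"),
                                  chains = 2, iter = 300,
                                  warmup = floor(iter / 2), seed = NULL,
                                  skill_scale = c("zscore", "fixed")) {
  if (is.character(spec)) spec <- attribution_model_spec(spec)
  stopifnot(inherits(spec, "asrc_attr_spec"))
  mode <- match.arg(mode)
  skill_scale <- match.arg(skill_scale)
  parts <- split_participants(data)
  pd <- lapply(parts, function(d) {
    ch <- choice_index(d$attribution)
    if (all(is.na(ch))) stop("a participant has no non-missing attributions")
    list(choice = as.integer(ch), outcome = as.integer(d$outcome),
         X = attribution_features(d, spec, skill_scale))
  })
  k <- 1L + length(spec$features); D <- 6L * k
  pnames <- attr_param_names(spec)
  loglik_w <- function(p, wv) {
    x <- pd[[p]]
    W <- attr_unpack(wv, k)
    attr_loglik_cpp(x$choice, x$outcome, x$X, W$win, W$loss)
  }
  w0 <- map_init_real(loglik_w, length(pd), D)
  seeds <- (seed %||% sample.int(1e6, 1)) + seq_len(chains)
  res <- lapply(seeds, function(s) {
    run_attr_chain(pd, D, mode == "hierarchical", iter, warmup, s, w0)
  })
  finish_fit(res, pd, pnames, mode, spec, family = "attribution",
             natural = identity,
             loglik1 = function(p, th) {
               x <- pd[[p]]
               W <- attr_unpack(th, k)
               attr_loglik_cpp(x$choice, x$outcome, x$X, W$win, W$loss)
             },
             data_id = dataset_fingerprint(data), seed = seed,
             config = list(chains = chains, iter = iter, warmup = warmup,
                           skill_scale = skill_scale))
}

# combine chains, compute diagnostics and the WAIC log-likelihood matrix
finish_fit <- function(res, pd, pnames, mode, spec, family, natural,
                       loglik1, data_id, seed, config) {
  P <- length(pd); D <- length(pnames)
  ids <- names(pd)
  samples <- lapply(seq_len(P), function(p) {
    m <- do.call(rbind, lapply(res, function(r) r$theta[, p, , drop = TRUE]))
    m <- matrix(m, ncol = D, dimnames = list(NULL, pnames))
    natural(m)
  })
  names(samples) <- ids
  rhat <- do.call(rbind, lapply(seq_len(P), function(p) {
    ch <- lapply(res, function(r) matrix(r$theta[, p, ], ncol = D))
    tibble::tibble(participant = ids[p], parameter = pnames,
                   rhat = split_rhat(ch))
  }))
  if (any(rhat$rhat > 1.05, na.rm = TRUE)) {
    warning(sum(rhat$rhat > 1.05, na.rm = TRUE),
            " parameter(s) with split-Rhat > 1.05; consider more iterations")
  }
  S <- nrow(samples[[1]])
  ll <- matrix(NA_real_, P, S, dimnames = list(ids, NULL))
  for (p in seq_len(P)) {
    # likelihood evaluated on the sampler's (unit-interval) scale
    raw <- do.call(rbind, lapply(res, function(r) {
      matrix(r$theta[, p, ], ncol = D)
    }))
    for (s in seq_len(S)) ll[p, s] <- loglik1(p, raw[s, ])
  }
  hyper <- if (!is.null(res[[1]]$hyper)) {
    do.call(rbind, lapply(res, `[[`, "hyper"))
  }
  structure(list(family = family, spec = spec, mode = mode,
                 samples = samples, hyper = hyper, diagnostics = rhat,
                 loglik_matrix = ll, data_id = data_id, seed = seed,
                 config = config),
            class = "asrc_fit")
}

#' @export
print.asrc_fit <- function(x, ...) {
  nm <- if (x$family == "skill") x$spec$name else x$spec$feature_set
  cat("asrcycle ", x$family, " model fit (", nm, ", ", x$mode, ")\n",
      "participants: ", length(x$samples),
      ", posterior samples: ", nrow(x$samples[[1]]),
      ", max split-Rhat: ", round(max(x$diagnostics$rhat), 3), "\n",
      sep = "")
  invisible(x)
}

#' Posterior-mean point estimates
#'
#' Arithmetic mean of the posterior draws per participant and parameter;
#' these point estimates feed the downstream model-agnostic analyses.
#'
#' @param fit An `asrc_fit`.
#' @return A tibble with `participant`, `parameter`, `mean`.
#' @export
posterior_mean_params <- function(fit) {
  stopifnot(inherits(fit, "asrc_fit"))
  do.call(rbind, lapply(names(fit$samples), function(id) {
    m <- colMeans(fit$samples[[id]])
    tibble::tibble(participant = id, parameter = names(m),
                   mean = unname(m))
  }))
}

#' Widely applicable information criterion
#'
#' Participant-grain WAIC: minus the mean (over participants) log of the
#' posterior-mean likelihood of each participant's full data, plus the
#' mean posterior variance (n-1 convention) of the participant
#' log-likelihood. Smaller is better. The log of the mean likelihood is
#' computed by log-sum-exp.
#'
#' @param x An `asrc_fit`, or a participants x samples matrix of
#'   log-likelihoods `log p(X_p | theta_ps)`.
#' @return An `asrc_waic` list with `waic`, `lppd`, `penalty`, the
#'   per-participant `pointwise` tibble, and the counts `P`, `S`.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "asrc_fit")) x$loglik_matrix else as.matrix(x)
  if (ncol(ll) < 2) stop("WAIC requires at least 2 posterior samples")
  if (any(!is.finite(ll))) stop("non-finite log-likelihoods")
  P <- nrow(ll); S <- ncol(ll)
  lme <- apply(ll, 1, function(r) {
    m <- max(r)
    m + log(mean(exp(r - m)))
  })
  pen <- apply(ll, 1, var)
  structure(list(waic = (-sum(lme) + sum(pen)) / P,
                 lppd = sum(lme), penalty = sum(pen),
                 pointwise = tibble::tibble(
                   participant = rownames(ll) %||% as.character(seq_len(P)),
                   lppd = lme, penalty = pen),
                 P = P, S = S),
            class = "asrc_waic")
}

#' @export
print.asrc_waic <- function(x, ...) {
  cat("WAIC = ", format(x$waic), " (lppd ", format(x$lppd),
      ", penalty ", format(x$penalty), "; P = ", x$P, ", S = ", x$S, ")\n",
      sep = "")
  invisible(x)
}

#' Rank fitted models by WAIC
#'
#' @param fits A named list of `asrc_fit` objects on identical data.
#' @return A tibble with `model`, `waic`, `delta` (difference to the best,
#'   i.e. smallest, WAIC), in ascending WAIC order.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "asrc_fit")))
  ids <- lapply(fits, `[[`, "data_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("all fits must be on identical data")
  }
  nm <- names(fits) %||% vapply(fits, function(f) {
    if (f$family == "skill") f$spec$name else f$spec$feature_set
  }, character(1))
  w <- vapply(fits, function(f) waic(f)$waic, numeric(1))
  ord <- order(w)
  tibble::tibble(model = nm[ord], waic = unname(w[ord]),
                 delta = unname(w[ord] - min(w)))
}

#' Internal-minus-external learning-rate differences
#'
#' For a fitted skill model with attribution-varying rates, the
#' per-participant posterior-mean difference between the internal and
#' external learning rate of every session x outcome cell.
#'
#' @param fit An `asrc_fit` of a skill model with the `A` flag.
#' @return A tibble with `participant`, `session`, `outcome`, `diff`.
#' @export
internal_external_diff <- function(fit) {
  stopifnot(inherits(fit, "asrc_fit"), fit$family == "skill",
            fit$spec$A)
  spec <- fit$spec
  sessions <- if (spec$S) 1:2 else 1
  outcomes <- if (spec$O) c(1, 0) else 1
  pm <- posterior_mean_params(fit)
  do.call(rbind, lapply(unique(pm$participant), function(id) {
    mu <- pm$mean[pm$participant == id]
    names(mu) <- pm$parameter[pm$participant == id]
    do.call(rbind, lapply(sessions, function(s) {
      do.call(rbind, lapply(outcomes, function(o) {
        i_int <- learning_rate_index(spec, s, o, "internal")
        i_ext <- learning_rate_index(spec, s, o, "external")
        nm <- skill_param_names(spec)
        tibble::tibble(participant = id, session = s, outcome = o,
                       diff = unname(mu[nm[i_int]] - mu[nm[i_ext]]))
      }))
    }))
  }))
}
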