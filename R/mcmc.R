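#' Adaptive random-walk Metropolis sampler
#'
#' Per-coordinate Gaussian random-walk Metropolis with acceptance-rate
#' adaptation during warmup. This is the generic engine behind the model
#' fits; it is also exercised directly on conjugate toys in the test suite
#' to validate the sampler against closed-form posteriors.
#'
#' @param log_target Function of the full parameter vector returning the
#'   unnormalised log posterior density.
#' @param init Numeric initial parameter vector.
#' @param n_iter Total iterations per chain (warmup included).
#' @param warmup Iterations discarded (and used for adaptation).
#' @param prop_sd Initial proposal s.d. per coordinate.
#' @param seed Optional integer seed; equal seeds give identical draws.
#' @param adapt Adapt proposal scales during warmup toward ~40% acceptance.
#' @return A list with `draws` (kept iterations x parameters),
#'   `accept_rate` and the final `prop_sd`.
#' @export
mh_sample <- function(log_target, init, n_iter = 1000,
                      warmup = floor(n_iter / 2),
                      prop_sd = rep(0.5, length(init)), seed = NULL,
                      adapt = TRUE) {
  stopifnot(n_iter > warmup, warmup >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- length(init)
  prop_sd <- rep_len(prop_sd, k)
  theta <- as.numeric(init)
  lp <- log_target(theta)
  if (!is.finite(lp)) stop("log_target is not finite at `init`")
  keep <- n_iter - warmup
  draws <- matrix(NA_real_, keep, k)
  acc <- integer(k); acc_win <- integer(k); n_prop <- 0L
  for (it in seq_len(n_iter)) {
    for (d in seq_len(k)) {
      prop <- theta
      prop[d] <- theta[d] + rnorm(1, 0, prop_sd[d])
      lp2 <- log_target(prop)
      if (is.finite(lp2) && log(runif(1)) < lp2 - lp) {
        theta <- prop; lp <- lp2
        acc[d] <- acc[d] + 1L; acc_win[d] <- acc_win[d] + 1L
      }
    }
    n_prop <- n_prop + 1L
    if (adapt && it <= warmup && it %% 25L == 0L) {
      rate <- acc_win / 25
      prop_sd <- prop_sd * ifelse(rate < 0.25, 0.7,
                                  ifelse(rate > 0.6, 1.4, 1))
      acc_win[] <- 0L
    }
    if (it > warmup) draws[it - warmup, ] <- theta
  }
  colnames(draws) <- names(init)
  list(draws = draws, accept_rate = acc / n_iter, prop_sd = prop_sd)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half; values near 1 indicate convergence.
#'
#' @param chains A list of equal-length numeric vectors (one per chain) or
#'   matrices (iterations x parameters).
#' @return A numeric R-hat per parameter.
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains[[1]]) && is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(x) matrix(x, ncol = 1))
  }
  n <- nrow(chains[[1]])
  half <- floor(n / 2)
  split_list <- unlist(lapply(chains, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    xs <- vapply(split_list, function(m) mean(m[, j]), numeric(1))
    vs <- vapply(split_list, function(m) var(m[, j]), numeric(1))
    W <- mean(vs)
    B <- half * var(xs)
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

#' Effective sample size (crude autocorrelation estimate)
#'
#' @param x Numeric vector of (pooled) draws.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, plot = FALSE, lag.max = min(n - 1, 100))$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}
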