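# paired t statistic across participants for the permutation engines
paired_t_stat <- function(d) {
  n <- length(d)
  s <- sd(d)
  if (s == 0) return(0)
  mean(d) / (s / sqrt(n))
}

permutation_p <- function(null_abs_geq, n_perm) (1 + null_abs_geq) / (1 + n_perm)

new_permtest <- function(statistic, p, n_perm, seed, effect_size = NA_real_,
                         n_excluded = 0L, note = NULL) {
  structure(list(statistic = statistic, p_value = p,
                 at_floor = p <= 1 / (n_perm + 1) + 1e-12,
                 n_perm = n_perm, effect_size = effect_size,
                 n_excluded = n_excluded, seed = seed, note = note),
            class = "asrc_permtest")
}

#' @export
print.asrc_permtest <- function(x, ...) {
  p_str <- if (x$at_floor) paste0("p < 1/", x$n_perm + 1, " (reported ",
                                  format(x$p_value), ")")
           else paste0("p = ", format(x$p_value))
  cat("permutation test: statistic = ", format(x$statistic), ", ", p_str,
      ", n_perm = ", x$n_perm,
      if (!is.na(x$effect_size)) paste0(", d = ", format(x$effect_size)),
      "\n", sep = "")
  invisible(x)
}

#' Skill-estimate updates
#'
#' Z-scores one participant's skill reports (n-1 s.d. convention) and
#' returns the first differences of the z-scored series; these are the
#' trial-level updates the model-agnostic analyses operate on. A constant
#' series has an undefined z-score and yields all-zero updates with a
#' warning.
#'
#' @param reports Numeric vector of at least 2 skill reports.
#' @return Numeric vector of `length(reports) - 1` updates.
#' @export
skill_updates <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  s <- sd(reports)
  if (!is.finite(s) || s == 0) {
    warning("constant report series: z-score undefined, returning zeros")
    return(rep(0, length(reports) - 1))
  }
  diff((reports - mean(reports)) / s)
}

#' Within-participant paired permutation test
#'
#' Tests whether the mean of a trial-level quantity differs between two
#' conditions: condition labels are shuffled within participant, the two
#' per-participant cell means are recomputed, and the paired t statistic
#' across participants is recorded for every permutation. The two-sided p
#' uses the add-one convention `(1 + k) / (1 + n_perm)`. Hedges' corrected
#' d of the observed cell means is attached.
#'
#' @param values Numeric vector of trial-level values.
#' @param condition Two-level vector of condition labels, parallel to
#'   `values`; the observed statistic is the paired t of (first level
#'   minus second level), with levels taken from `levels()` for factors
#'   and first appearance otherwise.
#' @param participant Participant identifier, parallel to `values`.
#' @param n_perm Number of permutations (reference setting 5000).
#' @param seed Optional integer seed.
#' @return An `asrc_permtest` with the observed paired t, p-value, effect
#'   size, and the count of participants excluded for lacking a condition.
#' @export
paired_permutation_test <- function(values, condition, participant,
                                    n_perm = 5000, seed = NULL) {
  stopifnot(length(values) == length(condition),
            length(values) == length(participant))
  if (!is.null(seed)) set.seed(seed)
  lev <- if (is.factor(condition)) levels(droplevels(condition))
         else unique(condition[!is.na(condition)])
  if (length(lev) != 2) stop("`condition` must have exactly 2 levels")
  condition <- as.character(condition)
  lev <- as.character(lev)
  keep <- !is.na(values) & !is.na(condition)
  values <- values[keep]; condition <- condition[keep]
  participant <- participant[keep]
  by_p <- split(seq_along(values), participant)
  has_both <- vapply(by_p, function(i) {
    all(lev %in% condition[i])
  }, logical(1))
  n_excluded <- sum(!has_both)
  by_p <- by_p[has_both]
  if (length(by_p) < 2) stop("need >= 2 participants with both conditions")
  vlist <- lapply(by_p, function(i) values[i])
  clist <- lapply(by_p, function(i) condition[i] == lev[1])
  cell_diffs <- function(cl) {
    vapply(seq_along(vlist), function(p) {
      v <- vlist[[p]]; c1 <- cl[[p]]
      mean(v[c1]) - mean(v[!c1])
    }, numeric(1))
  }
  d_obs <- cell_diffs(clist)
  t_obs <- paired_t_stat(d_obs)
  k <- 0L
  for (b in seq_len(n_perm)) {
    perm <- lapply(clist, sample)
    # degenerate shuffles (a cell emptied) cannot occur: counts preserved
    t_b <- paired_t_stat(cell_diffs(perm))
    if (abs(t_b) >= abs(t_obs)) k <- k + 1L
  }
  m1 <- vapply(seq_along(vlist), function(p) {
    mean(vlist[[p]][clist[[p]]])
  }, numeric(1))
  m2 <- vapply(seq_along(vlist), function(p) {
    mean(vlist[[p]][!clist[[p]]])
  }, numeric(1))
  es <- tryCatch(hedges_d(mean(m1), mean(m2), sd(m1), sd(m2),
                          length(m1), length(m2)),
                 error = function(e) NA_real_)
  new_permtest(t_obs, permutation_p(k, n_perm), n_perm, seed,
               effect_size = es, n_excluded = n_excluded)
}

#' Hedges' corrected d
#'
#' Bias-corrected standardised mean difference,
#' `d = (1 - 3 / (4(l1 + l2) - 9)) * (mu1 - mu2) / s_pooled`, with the
#' pooled s.d. using `l - 1` weights.
#'
#' @param mu1,mu2 Sample means.
#' @param sd1,sd2 Sample standard deviations.
#' @param l1,l2 Sample sizes (`l1 + l2 >= 4`).
#' @return The effect size (scalar).
#' @export
hedges_d <- function(mu1, mu2, sd1, sd2, l1, l2) {
  stopifnot(sd1 >= 0, sd2 >= 0, l1 >= 2, l2 >= 2)
  if (l1 + l2 < 4) stop("need l1 + l2 >= 4")
  pooled <- sqrt(((l1 - 1) * sd1^2 + (l2 - 1) * sd2^2) / (l1 + l2 - 2))
  if (pooled == 0) stop("zero pooled standard deviation: d undefined")
  (1 - 3 / (4 * (l1 + l2) - 9)) * (mu1 - mu2) / pooled
}

# rank-based quartile bins; the within-participant z-scoring applied to the
# factor before discretisation is monotone, so rank-based bins are identical
# on the raw and z-scored values
quartile_bins <- function(x, n_bins = 4) {
  ceiling(n_bins * rank(x, ties.method = "first") / length(x))
}

#' Attribution proportions by factor quartile
#'
#' For each participant, outcome and quartile of a continuous factor
#' (z-scored within participant before discretisation), the proportion of
#' probes attributed to the given option out of all answered probes in
#' that cell. Missing attributions are excluded; empty cells are recorded
#' as `NA`.
#'
#' @param data A probe-aligned dataset tibble.
#' @param option One of `Internal`, `Maze`, `Rotations`, `Luck`.
#' @param factor Name of a continuous dataset column (e.g. `path_length`).
#' @return A tibble with `participant`, `quartile`, `outcome`, `prop`,
#'   `n` (answered probes in the cell).
#' @export
quartile_proportions <- function(data, option, factor) {
  stopifnot(option %in% ATTRIBUTION_OPTIONS, factor %in% names(data))
  ids <- unique(data$participant)
  rows <- lapply(ids, function(id) {
    d <- data[data$participant == id, ]
    bin <- quartile_bins(d[[factor]])
    grid <- expand.grid(quartile = 1:4, outcome = c(0L, 1L))
    grid$prop <- NA_real_; grid$n <- 0L
    for (r in seq_len(nrow(grid))) {
      sel <- bin == grid$quartile[r] & d$outcome == grid$outcome[r] &
        !is.na(d$attribution)
      grid$n[r] <- sum(sel)
      if (grid$n[r] > 0) {
        grid$prop[r] <- mean(d$attribution[sel] == option)
      }
    }
    cbind(participant = id, grid)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# two-way repeated-measures interaction F from the full SS decomposition;
# y is a participants x binsA x binsB array (flattened to P x J*K internally)
rm_interaction_F <- function(y) {
  P <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  M <- matrix(y, P, J * K) # column (j, k), j fastest
  g <- mean(M)
  m_jk <- colMeans(M)
  jj <- rep(seq_len(J), K); kk <- rep(seq_len(K), each = J)
  m_j <- vapply(seq_len(J), function(j) mean(m_jk[jj == j]), numeric(1))
  m_k <- vapply(seq_len(K), function(k) mean(m_jk[kk == k]), numeric(1))
  ss_ab <- P * sum((m_jk - m_j[jj] - m_k[kk] + g)^2)
  if (ss_ab == 0) return(0)
  m_pj <- vapply(seq_len(J), function(j) {
    rowMeans(M[, jj == j, drop = FALSE])
  }, numeric(P))
  m_pk <- vapply(seq_len(K), function(k) {
    rowMeans(M[, kk == k, drop = FALSE])
  }, numeric(P))
  m_p <- rowMeans(M)
  resid <- M - matrix(m_jk, P, J * K, byrow = TRUE) -
    m_pj[, jj, drop = FALSE] - m_pk[, kk, drop = FALSE] +
    matrix(m_j[jj] + m_k[kk], P, J * K, byrow = TRUE) + m_p - g
  ss_err <- sum(resid^2)
  df_ab <- (J - 1) * (K - 1)
  df_err <- (J - 1) * (K - 1) * (P - 1)
  (ss_ab / df_ab) / (ss_err / df_err)
}

#' Quartile-by-outcome interaction permutation test
#'
#' Tests whether the effect of a continuous factor on attributions to an
#' option differs between wins and losses: the repeated-measures
#' two-way interaction F (factor quartile x outcome) is computed on the
#' per-participant cell proportions, and its permutation null is built by
#' shuffling the factor's raw values within participant before
#' re-discretising. Participants with any empty cell are excluded.
#'
#' @inheritParams quartile_proportions
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return An `asrc_permtest` holding the observed F and one-sided
#'   permutation p-value.
#' @export
interaction_F <- function(data, option, factor, n_perm = 5000,
                          seed = NULL) {
  stopifnot(option %in% ATTRIBUTION_OPTIONS, factor %in% names(data))
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data$participant)
  parts <- lapply(ids, function(id) {
    d <- data[data$participant == id & !is.na(data$attribution), ]
    list(x = d[[factor]], outcome = d$outcome,
         hit = d$attribution == option)
  })
  cell_table <- function(xs) {
    y <- array(NA_real_, c(length(parts), 4, 2))
    for (p in seq_along(parts)) {
      pp <- parts[[p]]
      idx <- quartile_bins(xs[[p]]) + 4L * pp$outcome # losses 1:4, wins 5:8
      n_cell <- tabulate(idx, 8L)
      h_cell <- tabulate(idx[pp$hit], 8L)
      y[p, , ] <- ifelse(n_cell > 0, h_cell / n_cell, NA_real_)
    }
    y
  }
  y_obs <- cell_table(lapply(parts, `[[`, "x"))
  complete <- apply(y_obs, 1, function(m) all(is.finite(m)))
  n_excluded <- sum(!complete)
  if (sum(complete) < 3) stop("need >= 3 participants with complete cells")
  parts <- parts[complete]
  f_obs <- rm_interaction_F(cell_table(lapply(parts, `[[`, "x")))
  k <- 0L
  for (b in seq_len(n_perm)) {
    y_b <- cell_table(lapply(parts, function(pp) sample(pp$x)))
    ok <- apply(y_b, 1, function(m) all(is.finite(m)))
    if (sum(ok) < 3) next
    f_b <- rm_interaction_F(y_b[ok, , , drop = FALSE])
    if (f_b >= f_obs) k <- k + 1L
  }
  new_permtest(f_obs, permutation_p(k, n_perm), n_perm, seed,
               n_excluded = n_excluded)
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate control: rejects the largest `k` p-values
#' with `p_(k) <= k * alpha / m` and all smaller ones.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A list with `rejected` (logical, in input order), `threshold`
#'   (largest rejected raw p, 0 if none) and `adjusted` (BH-adjusted
#'   p-values).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  rejected <- adj <= alpha
  list(rejected = rejected,
       threshold = if (any(rejected)) max(p[rejected]) else 0,
       adjusted = adj)
}

#' Correlation permutation test
#'
#' Pearson correlation with a permutation null obtained by shuffling `y`;
#' two-sided p with the add-one convention.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return An `asrc_permtest` with the observed r.
#' @export
correlation_permutation <- function(x, y, n_perm = 5000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- cor(x, y)
  k <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= abs(r_obs)) k <- k + 1L
  }
  new_permtest(r_obs, permutation_p(k, n_perm), n_perm, seed)
}
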