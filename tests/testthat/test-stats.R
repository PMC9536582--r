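test_that("skill updates are first differences of z-scored reports", {
  u <- skill_updates(c(0.2, 0.4, 0.6))
  # z-scores are (-1, 0, 1) under the n-1 convention
  expect_equal(u, c(1, 1))
  expect_equal(skill_updates(c(0.6, 0.4, 0.2)), -u)
  expect_warning(u0 <- skill_updates(rep(0.5, 4)), "constant")
  expect_equal(u0, rep(0, 3))
  expect_error(skill_updates(0.5), "at least 2")
})

test_that("the paired permutation test matches t.test and hits its floor", {
  set.seed(1)
  P <- 10; n <- 20
  part <- rep(seq_len(P), each = n)
  cond <- rep(rep(c("int", "ext"), n / 2), P)
  # identical condition data: t = 0, p ~ 1
  vals_same <- rep(rnorm(P), each = n)
  r0 <- paired_permutation_test(vals_same, cond, part, n_perm = 200,
                                seed = 2)
  expect_equal(r0$statistic, 0)
  expect_gt(r0$p_value, 0.9)
  # observed statistic equals the classical paired t on the cell means
  vals <- rnorm(P * n) + (cond == "int") * 0.5
  r1 <- paired_permutation_test(vals, cond, part, n_perm = 100, seed = 3)
  m_int <- tapply(vals[cond == "int"], part[cond == "int"], mean)
  m_ext <- tapply(vals[cond == "ext"], part[cond == "ext"], mean)
  expect_equal(r1$statistic,
               unname(t.test(m_int, m_ext, paired = TRUE)$statistic),
               tolerance = 1e-10)
  # an overwhelming effect bottoms out at 1 / (n_perm + 1)
  vals_big <- rnorm(P * n, sd = 0.01) + (cond == "int") * 10
  r2 <- paired_permutation_test(vals_big, cond, part, n_perm = 200,
                                seed = 4)
  expect_equal(r2$p_value, 1 / 201)
  expect_true(r2$at_floor)
  # participants missing a condition are excluded with a count
  part2 <- c(part, rep(99, 4)); cond2 <- c(cond, rep("int", 4))
  r3 <- paired_permutation_test(c(vals, rnorm(4)), cond2, part2,
                                n_perm = 50, seed = 5)
  expect_identical(r3$n_excluded, 1L)
})

test_that("Hedges' corrected d applies the small-sample correction exactly", {
  expect_equal(hedges_d(1, 0, 1, 1, 20, 20), (1 - 3 / 151),
               tolerance = 1e-12)
  expect_equal(hedges_d(0.3, 0.3, 1, 2, 10, 12), 0)
  expect_equal(hedges_d(2, 1, 0.5, 0.8, 9, 14),
               -hedges_d(1, 2, 0.8, 0.5, 14, 9), tolerance = 1e-12)
  # literal transcription oracle on random inputs
  set.seed(6)
  for (i in 1:10) {
    mu <- rnorm(2); s <- runif(2, 0.5, 2); l <- sample(5:30, 2)
    pooled <- sqrt(((l[1] - 1) * s[1]^2 + (l[2] - 1) * s[2]^2) /
                     (l[1] + l[2] - 2))
    want <- (1 - 3 / (4 * (l[1] + l[2]) - 9)) * (mu[1] - mu[2]) / pooled
    expect_equal(hedges_d(mu[1], mu[2], s[1], s[2], l[1], l[2]), want,
                 tolerance = 1e-12)
  }
  expect_error(hedges_d(1, 0, 0, 0, 5, 5), "pooled")
})

test_that("quartile proportions match hand counts on a small fixture", {
  d <- tibble::tibble(
    participant = "p1",
    probe = 1:8,
    outcome = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    attribution = c("Internal", "Internal", "Maze", "Luck",
                    "Internal", "Maze", "Maze", NA),
    path_length = c(1, 2, 3, 4, 5, 6, 7, 8))
  qp <- quartile_proportions(d, "Internal", "path_length")
  # bins: probes (1,2), (3,4), (5,6), (7,8)
  expect_equal(qp$prop[qp$quartile == 1 & qp$outcome == 1], 1)
  expect_equal(qp$prop[qp$quartile == 2 & qp$outcome == 1], 0)
  expect_equal(qp$prop[qp$quartile == 3 & qp$outcome == 0], 0.5)
  expect_equal(qp$prop[qp$quartile == 4 & qp$outcome == 0], 0) # NA excluded
  expect_equal(qp$n[qp$quartile == 4 & qp$outcome == 0], 1L)
  expect_true(all(is.na(qp$prop[qp$outcome == 0 & qp$quartile %in% 1:2])))
  # proportions across the four options sum to one in occupied cells
  tot <- rep(0, 8)
  for (opt in c("Internal", "Maze", "Rotations", "Luck")) {
    tot <- tot + ifelse(is.na(quartile_proportions(d, opt,
                                                   "path_length")$prop), 0,
                        quartile_proportions(d, opt, "path_length")$prop)
  }
  expect_true(all(tot %in% c(0, 1)))
})

test_that("the interaction F equals the repeated-measures aov oracle", {
  set.seed(9)
  P <- 5
  y <- array(runif(P * 4 * 2), c(P, 4, 2))
  df <- expand.grid(p = factor(1:P), bin = factor(1:4),
                    outcome = factor(1:2))
  df$y <- as.vector(y)
  a <- summary(stats::aov(y ~ bin * outcome + Error(p / (bin * outcome)),
                          data = df))
  want <- a[["Error: p:bin:outcome"]][[1]]["bin:outcome", "F value"]
  expect_equal(asrcycle:::rm_interaction_F(y), want, tolerance = 1e-10)
  # identical cell means everywhere: F defined as 0
  expect_equal(asrcycle:::rm_interaction_F(array(0.3, c(P, 4, 2))), 0)
})

test_that("interaction_F detects a planted quartile-by-outcome interaction", {
  set.seed(10)
  P <- 10; n <- 48
  rows <- lapply(seq_len(P), function(p) {
    x <- rnorm(n)
    o <- rbinom(n, 1, 0.5)
    # losses blamed on the maze more as path length grows
    p_maze <- plogis(ifelse(o == 0, 1.5, -1.5) * x)
    att <- ifelse(rbinom(n, 1, p_maze) == 1, "Maze", "Luck")
    tibble::tibble(participant = sprintf("p%02d", p), probe = seq_len(n),
                   outcome = o, attribution = att, path_length = x)
  })
  d <- do.call(rbind, rows)
  r <- interaction_F(d, "Maze", "path_length", n_perm = 99, seed = 11)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$statistic, 1)
  expect_error(interaction_F(d[d$participant %in% c("p01", "p02"), ],
                             "Maze", "path_length", n_perm = 9),
               ">= 3 participants")
})

test_that("Benjamini-Hochberg step-up matches the hand procedure", {
  expect_true(bh_adjust(0.04, 0.05)$rejected)
  expect_false(any(bh_adjust(rep(1, 6))$rejected))
  r <- bh_adjust(c(0.001, 0.01, 0.03, 0.2), alpha = 0.05)
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.03)
  # independent hand step-up on random p-values
  set.seed(12)
  p <- runif(15)^2
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[ord][k] <= k * 0.05 / m) k_max <- k
  }
  want <- rep(FALSE, m)
  if (k_max > 0) want[ord[seq_len(k_max)]] <- TRUE
  expect_equal(bh_adjust(p, 0.05)$rejected, want)
})

test_that("the correlation permutation test is exact on its edge cases", {
  x <- rnorm(20)
  r1 <- correlation_permutation(x, x, n_perm = 100, seed = 1)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p_value, 1 / 101)
  r2 <- correlation_permutation(x, -x, n_perm = 100, seed = 2)
  expect_equal(r2$statistic, -1)
  expect_error(correlation_permutation(x, rep(1, 20), n_perm = 10),
               "zero-variance")
  expect_error(correlation_permutation(x[1:5], x[1:4]), "length")
})
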