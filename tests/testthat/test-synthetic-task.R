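test_that("staircase tracks move one step, clamp, and alternate", {
  st <- staircase_init(start = c(0, 1), step = 0.25, bounds = c(-1, 1))
  expect_equal(staircase_difficulty(st), 0)
  st1 <- staircase_update(st, 1)
  expect_equal(st1$levels, c(0.25, 1))     # win: active track harder
  expect_equal(st1$active, 2L)             # control passes to track 2
  st2 <- staircase_update(st1, 1)
  expect_equal(st2$levels, c(0.25, 1))     # clamped at the upper bound
  st3 <- staircase_update(staircase_init(start = c(-1, 0), step = 0.5,
                                         bounds = c(-1, 1)), 0)
  expect_equal(st3$levels, c(-1, 0))       # loss at d_min stays at d_min
})

test_that("the double staircase holds the win rate near one half", {
  pl <- simulate_staircase_player(ability = 0.7, n_trials = 500, seed = 21)
  expect_gt(mean(pl$outcome[101:500]), 0.45)
  expect_lt(mean(pl$outcome[101:500]), 0.55)
  # shift-invariance of the equilibrium: a much stronger player, same rate
  pl2 <- simulate_staircase_player(ability = 2.5, n_trials = 500, seed = 22)
  expect_gt(mean(pl2$outcome[101:500]), 0.45)
  expect_lt(mean(pl2$outcome[101:500]), 0.55)
})

test_that("the outcome model matches its closed form", {
  expect_equal(win_probability(1, 1, kappa = 2), 0.5)
  expect_equal(win_probability(3, 0, kappa = 0), 0.5)
  set.seed(31)
  ab <- 0.8; d <- 0.3; n <- 1e4
  st <- staircase_init(start = c(d, d), step = 1e-9)
  wins <- vapply(seq_len(n), function(i) generate_trial(st, ab)$outcome,
                 numeric(1))
  p_hat <- mean(wins)
  p_true <- win_probability(ab, d)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("generated datasets satisfy the probe-aligned contract", {
  d <- generate_dataset(default_participant(0.3, id = "x"), n_probes = 40,
                        seed = 7)
  expect_equal(nrow(d), 40)
  expect_identical(d$probe, 1:40)
  expect_equal(d$session, rep(1:2, each = 20))
  expect_equal(session_boundary(d), 21)
  expect_true(all(d$skill_report >= 0 & d$skill_report <= 1))
  expect_true(all(is.na(d$attribution) |
                    d$attribution %in% c("Internal", "Maze", "Rotations",
                                         "Luck")))
  # determinism
  d2 <- generate_dataset(default_participant(0.3, id = "x"), n_probes = 40,
                         seed = 7)
  expect_identical(d, d2)
  expect_error(generate_dataset(default_participant(), n_probes = 1), ">= 2")
})

test_that("degenerate generator settings behave as specified", {
  p <- default_participant(0, id = "z")
  # all rates zero, no offset, no noise: reports pinned at s0
  flat <- skill_params(p$skill_spec, rep(0, p$skill_spec$n_rates), s0 = 0.5,
                       session_offset = 0, report_noise_sd = 1e-12)
  pz <- generative_participant(0, p$skill_spec, flat, p$attr_spec,
                               p$attr_weights, missing_prob = 0, id = "z")
  dz <- generate_dataset(pz, n_probes = 20, seed = 3)
  expect_equal(dz$skill_report, rep(0.5, 20), tolerance = 1e-9)
  # missing_prob = 1: every probe unanswered
  pm <- generative_participant(0, p$skill_spec, p$skill_params, p$attr_spec,
                               p$attr_weights, missing_prob = 1, id = "m")
  dm <- generate_dataset(pm, n_probes = 20, seed = 4)
  expect_true(all(is.na(dm$attribution)))
})

test_that("a self-serving generator yields more internal wins than losses", {
  coh <- generate_cohort(20, n_probes = 60, seed = 15)
  win_int <- mean(coh$attribution[coh$outcome == 1] == "Internal",
                  na.rm = TRUE)
  loss_int <- mean(coh$attribution[coh$outcome == 0] == "Internal",
                   na.rm = TRUE)
  expect_gt(win_int, loss_int)
})

test_that("datasets round-trip through CSV and malformed rows are located", {
  coh <- generate_cohort(3, n_probes = 20, seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_dataset(coh, path)
  back <- read_dataset(path)
  expect_equal(back, coh, tolerance = 1e-9)
  # empty collection: header-only file
  write_dataset(coh[0, ], path)
  expect_equal(nrow(read_dataset(path)), 0)
  # malformed outcome reported with its line number
  bad <- coh
  bad$outcome[2] <- 7L
  write_dataset(bad, path)
  expect_error(read_dataset(path), "line\\(s\\) 3")
})

test_that("a handcrafted fixture file parses to known values", {
  path <- system.file("extdata", "example_probes.csv", package = "asrcycle")
  d <- read_dataset(path)
  expect_equal(nrow(d), 3)
  expect_equal(d$attribution, c("Internal", NA, "Luck"))
  expect_equal(d$skill_report, c(0.52, 0.61, 0.55))
  expect_equal(d$outcome, c(1L, 1L, 0L))
  expect_equal(session_boundary(d), 3)
})

test_that("generating parameters outscore perturbed ones on generated data", {
  set.seed(77)
  n_rep <- 6
  better_skill <- 0; better_attr <- 0
  for (i in seq_len(n_rep)) {
    p <- default_participant(rnorm(1), id = "c")
    d <- generate_dataset(p, n_probes = 120, seed = 700 + i)
    ll0 <- skill_loglik(p$skill_params, d)
    for (shift in c(-0.2, 0.2)) {
      pert <- skill_params(p$skill_spec,
                           pmin(pmax(p$skill_params$alphas + shift, 0), 1),
                           s0 = p$skill_params$s0,
                           session_offset = p$skill_params$session_offset)
      if (ll0 > skill_loglik(pert, d)) better_skill <- better_skill + 1
    }
    la0 <- attr_loglik(p$attr_weights, d, skill_scale = "fixed")
    for (shift in c(-0.2, 0.2)) {
      pw <- option_weights(p$attr_spec, p$attr_weights$win + shift,
                           p$attr_weights$loss + shift)
      if (la0 > attr_loglik(pw, d, skill_scale = "fixed")) {
        better_attr <- better_attr + 1
      }
    }
  }
  expect_gt(better_skill / (2 * n_rep), 0.75)
  expect_gt(better_attr / (2 * n_rep), 0.75)
})
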