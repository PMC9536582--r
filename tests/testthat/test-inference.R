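test_that("WAIC reproduces hand-computed and identity cases", {
  # constant likelihood across samples: no penalty
  ll <- matrix(log(c(0.2, 0.4)), 2, 5)
  w <- waic(ll)
  expect_equal(w$penalty, 0)
  expect_equal(w$waic, -(log(0.2) + log(0.4)) / 2, tolerance = 1e-12)
  # hand-computed P = 1, S = 2 case: lppd = log 1.5, penalty = (log 2)^2 / 2
  w2 <- waic(matrix(c(0, log(2)), 1, 2))
  expect_equal(w2$lppd, log(1.5), tolerance = 1e-12)
  expect_equal(w2$penalty, log(2)^2 / 2, tolerance = 1e-12)
  expect_equal(w2$waic, -log(1.5) + log(2)^2 / 2, tolerance = 1e-12)
  # translation: adding c to every log-likelihood shifts WAIC by -c
  ll3 <- matrix(rnorm(40), 4, 10)
  expect_equal(waic(ll3 + 1.7)$waic, waic(ll3)$waic - 1.7,
               tolerance = 1e-10)
  expect_error(waic(matrix(0, 3, 1)), "at least 2")
})

test_that("the sampler recovers a conjugate Normal-mean posterior", {
  set.seed(42)
  y <- rnorm(30, mean = 1.2, sd = 1)
  tau2 <- 4 # prior N(0, tau2) on the mean, known unit sd
  post_var <- 1 / (length(y) + 1 / tau2)
  post_mean <- post_var * sum(y)
  lt <- function(th) sum(dnorm(y, th, 1, log = TRUE)) +
    dnorm(th, 0, sqrt(tau2), log = TRUE)
  fit <- mh_sample(lt, init = 0, n_iter = 4000, warmup = 1000, seed = 7)
  draws <- fit$draws[, 1]
  mcse <- sd(draws) / sqrt(ess_basic(draws))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 1e-3)
  expect_lt(abs(sd(draws) - sqrt(post_var)), 0.05)
  # determinism contract
  fit2 <- mh_sample(lt, init = 0, n_iter = 4000, warmup = 1000, seed = 7)
  expect_identical(fit$draws, fit2$draws)
})

test_that("model fits reject empty data and are seed-reproducible", {
  expect_error(fit_skill_model(make_probe_data(5)[0, ], "b"), "empty")
  coh <- generate_cohort(3, n_probes = 30, seed = 2)
  f1 <- suppressWarnings(fit_skill_model(coh, "b", mode = "independent",
                                         chains = 2, iter = 120, seed = 5))
  f2 <- suppressWarnings(fit_skill_model(coh, "b", mode = "independent",
                                         chains = 2, iter = 120, seed = 5))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$loglik_matrix, f2$loglik_matrix)
})

test_that("posterior means average draws and model ranking handles ties", {
  coh <- generate_cohort(2, n_probes = 20, seed = 3)
  f <- suppressWarnings(fit_skill_model(coh, "b", mode = "independent",
                                        chains = 2, iter = 100, seed = 5))
  pm <- posterior_mean_params(f)
  id <- names(f$samples)[1]
  # loop oracle over the stored draws
  for (par in colnames(f$samples[[id]])) {
    tot <- 0
    for (s in seq_len(nrow(f$samples[[id]]))) {
      tot <- tot + f$samples[[id]][s, par]
    }
    expect_equal(pm$mean[pm$participant == id & pm$parameter == par],
                 unname(tot) / nrow(f$samples[[id]]), tolerance = 1e-12)
  }
  cmp1 <- compare_models(list(only = f))
  expect_equal(cmp1$delta, 0)
  cmp2 <- compare_models(list(a = f, b = f))
  expect_equal(cmp2$delta, c(0, 0))
  other <- suppressWarnings(fit_skill_model(
    generate_cohort(2, n_probes = 20, seed = 4), "b",
    mode = "independent", chains = 2, iter = 100, seed = 5))
  expect_error(compare_models(list(a = f, b = other)), "identical data")
})

test_that("hierarchical fits shrink estimates relative to independent fits", {
  coh <- generate_cohort(8, n_probes = 60, seed = 8)
  fi <- suppressWarnings(fit_skill_model(coh, "O", mode = "independent",
                                         chains = 2, iter = 250, seed = 6))
  fh <- suppressWarnings(fit_skill_model(coh, "O", mode = "hierarchical",
                                         chains = 2, iter = 250, seed = 6))
  pm_i <- posterior_mean_params(fi)
  pm_h <- posterior_mean_params(fh)
  spread <- function(pm) {
    mean(tapply(pm$mean, pm$parameter, var))
  }
  expect_lt(spread(pm_h), spread(pm_i))
})

test_that("the attribution-shuffle refit is calibrated on decoupled data", {
  coh0 <- generate_cohort(6, n_probes = 40, seed = 12)
  # attribution-independent generation: tie internal and external rates
  tmpl <- default_participant()
  spec <- tmpl$skill_spec
  al <- tmpl$skill_params$alphas
  for (s in 1:2) for (o in c(1, 0)) {
    i_int <- learning_rate_index(spec, s, o, "internal")
    i_ext <- learning_rate_index(spec, s, o, "external")
    i_mis <- learning_rate_index(spec, s, o, "missing")
    al[c(i_int, i_mis)] <- al[i_ext]
  }
  flat <- skill_params(spec, al, s0 = 0.5, session_offset = 0.05)
  parts <- lapply(1:6, function(i) {
    generative_participant(0, spec, flat, tmpl$attr_spec,
                           tmpl$attr_weights, missing_prob = 0.05,
                           id = sprintf("p%02d", i))
  })
  coh <- generate_cohort(parts, n_probes = 40, seed = 12)
  sr <- suppressWarnings(shuffle_refit(coh, "SAO", n_perm = 19,
                                       mode = "independent", chains = 1,
                                       iter = 150, seed = 13))
  expect_equal(dim(sr$null), c(19, 4))
  # observed mean difference inside the central mass of the null
  obs <- mean(sr$observed$diff)
  null_means <- rowMeans(sr$null)
  expect_gte(obs, quantile(null_means, 0.025) - 0.05)
  expect_lte(obs, quantile(null_means, 0.975) + 0.05)
  # a single-permutation run returns a single null draw
  sr1 <- suppressWarnings(shuffle_refit(coh0[coh0$participant %in%
                                               c("p01", "p02"), ],
                                        "SAO", n_perm = 1,
                                        mode = "independent", chains = 1,
                                        iter = 80, seed = 14))
  expect_equal(nrow(sr1$null), 1)
})
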