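# deterministic hand-sized probe dataset used across likelihood oracles
make_probe_data <- function(n = 8, participant = "p1", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    participant = participant,
    probe = seq_len(n),
    session = rep(1:2, each = ceiling(n / 2))[seq_len(n)],
    outcome = rep(c(1L, 0L), length.out = n),
    attribution = rep(c("Internal", "Maze", "Luck", "Rotations"),
                      length.out = n),
    skill_report = round(runif(n, 0.2, 0.8), 3),
    path_length = sample(5:15, n, replace = TRUE),
    prop_nonup = round(runif(n, 0.1, 0.6), 3),
    prop_correct_keys = round(runif(n, 0.4, 0.95), 3),
    prop_pauses = round(runif(n, 0, 0.3), 3),
    time_limit = rep(25, n),
    difficulty = round(rnorm(n), 3))
}

# random attribution weight object for a spec
random_weights <- function(spec, seed = 1, scale = 0.5) {
  set.seed(seed)
  k <- 1 + length(spec$features)
  option_weights(spec,
                 win = matrix(rnorm(3 * k, 0, scale), 3, k),
                 loss = matrix(rnorm(3 * k, 0, scale), 3, k))
}

reference_params <- function() agent_params()

vulnerable_params <- function() {
  agent_params(beta_win = 0.5, beta_loss = 5,
               alpha = c(internal_win = 0.12, external_win = 0.05,
                         internal_loss = 0.15, external_loss = 0.05))
}
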