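# asrcycle

Trial-level modelling of the **attribution–self-representation cycle
(ASRC)**: the idea that the causal attributions people make for individual
successes and failures, and their beliefs about their own skill, influence
each other event by event. `asrcycle` is aimed at computational-psychiatry
and cognitive-modelling researchers who want to simulate this cycle, fit
its two halves to probe-aligned behavioural data, and run the matching
permutation statistics — all of it testable on synthetic data with known
generative parameters.

## What is in the package

**Agent simulator.** An agent holds a skill belief *s* and attributes each
binary outcome *o* ∈ {0, 1} internally (*a* = 1) or externally (*a* = 0)
with probability

> p(a = 1 | o, s) = σ(β_w (s − x_0w)) for wins, 1 − σ(β_l (s − x_0l)) for
> losses,

then updates its belief by a Rescorla–Wagner step gated by the attribution,

> s ← s + α_{a,o} (o − σ(s)),

with one learning rate per attribution × outcome cell. Ensembles of agents
sharing one fixed outcome schedule isolate the variability injected purely
by attribution sampling; a *decoupling ablation* replaces the skill-dependent
attribution rule by an i.i.d. rule matched for average propensity per
valence, and summary tables reproduce the trial-level diagnostics
(attribution by skill quintile, update size by cell, median splits,
loss-batch comparisons) used to characterise these dynamics.

**Synthetic task generator.** A double-staircase difficulty controller (two
interleaved 1-up/1-down tracks) holds the win rate of synthetic players
near 50%; every second trial yields a probe with an attribution choice over
{Internal, Maze, Rotations, Luck} (optionally missing) followed by a noisy
skill-report on a [0, 1] slider. All generative parameters are explicit, so
every downstream fit can be audited by parameter recovery.

**Model families with exact likelihoods.**
*Skill reports*: eight Rescorla–Wagner variants (`b, S, O, A, SA, SO, AO,
SAO`) in which the learning rate may vary by session, outcome and
attribution class (internal / external / missing), with a session-break
offset β and fixed Gaussian report noise (s.d. 0.1).
*Attribution choices*: six softmax linear models whose option scores are
weight–feature dot products with a sum-to-zero constraint across the four
options (Luck is derived), separate weights for wins and losses, and
feature sets ranging from bias-only to the full skill + performance + task
model (36 parameters per participant). Bias-to-preference and
average-marginal-effect (analytic softmax gradient) transforms make the
weights interpretable.

**Inference.** Hierarchical (Beta population priors for skill parameters,
Normal for attribution weights) or independent fits by adaptive
Metropolis-within-Gibbs with MAP-seeded chains, split-R̂ diagnostics,
participant-grain WAIC

> WAIC = −(1/P) Σ_p log( (1/S) Σ_s p(X_p | θ_ps) ) + (1/P) Σ_p Var_s( log p(X_p | θ_ps) ),

model ranking by ΔWAIC, a parameter-recovery harness and an
attribution-shuffle refit control.

**Model-agnostic statistics.** Within-participant permutation tests with
the paired-t statistic (5000 samples, add-one p-values), Hedges' corrected
d, quartile discretisation of z-scored factors with per-cell attribution
proportions, a repeated-measures interaction-F permutation test,
Benjamini–Hochberg correction, and correlation permutation tests.

## Worked example

```r
library(asrcycle)

# 1. simulate the reference agent regime and its decoupling ablation
params <- agent_params()                      # benign reference parameters
schedule <- outcome_schedule(150, seed = 101) # one shared outcome sequence
coupled <- simulate_ensemble(params, schedule, n_runs = 100, seed = 1)
decoupled <- decouple_attributions(params, schedule, n_runs = 100, seed = 1,
                                   reference = coupled)
sd(coupled$skill[, 151])   # 0.107
sd(decoupled$skill[, 151]) # 0.061

# 2. generate a synthetic cohort and compare two skill models by WAIC
cohort <- generate_cohort(12, n_probes = 120, seed = 42)
fit_sao <- fit_skill_model(cohort, "SAO", mode = "hierarchical",
                           chains = 2, iter = 300, seed = 7)
fit_so  <- fit_skill_model(cohort, "SO",  mode = "hierarchical",
                           chains = 2, iter = 300, seed = 7)
compare_models(list(SAO = fit_sao, SO = fit_so))
#>   model   waic delta
#> 1 SAO   -103.   0
#> 2 SO     -93.7  8.92

# 3. are internal learning rates larger than external ones?
ie <- internal_external_diff(fit_sao)
diffs <- tapply(ie$diff, ie$participant, mean)
mean(diffs)     # 0.094  (generated with a true difference of 0.1)
sum(diffs > 0)  # 12 of 12 participants

# 4. model-agnostic check: more internal attributions for wins than losses?
answered <- cohort[!is.na(cohort$attribution), ]
paired_permutation_test(
  values = as.numeric(answered$attribution == "Internal"),
  condition = factor(ifelse(answered$outcome == 1, "win", "loss"),
                     c("win", "loss")),
  participant = answered$participant, n_perm = 5000, seed = 9)
#> permutation test: statistic = 8.02, p < 1/5001, n_perm = 5000, d = 3.55
```

The cohort was generated under the 12-rate `SAO` model with every internal
learning rate 0.1 above its external counterpart, so step 2 should prefer
`SAO` (it does, ΔWAIC ≈ 9), step 3 should recover a positive difference of
about 0.1 in every participant (it does), and step 4 recovers the
self-serving attribution asymmetry built into the generator.

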