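---
title: "Modelling reciprocal attribution-skill-belief dynamics with asrcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reciprocal attribution-skill-belief dynamics with asrcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrcycle)
```

## The scientific problem

When people succeed or fail at a task they assign a cause to the outcome —
their own ability, features of the task, or luck — and they maintain a
belief about how skilled they are. The attribution-self-representation
cycle (ASRC) holds that these two quantities influence each other at the
level of individual events: a person who believes they are skilled is more
inclined to credit a win to ability and to blame a loss on the
circumstances, and an outcome attributed internally moves the skill belief
more than one attributed externally. Closing this loop can stabilise
beliefs, amplify random early differences, or create latent vulnerability
to losing streaks, which is why the cycle is of interest to computational
psychiatry.

`asrcycle` implements the computational core needed to study this cycle
end to end on synthetic data: a generative agent, a simulated probe task,
likelihood-based model families for the two halves of the cycle,
hierarchical Bayesian inference with WAIC comparison, and permutation
statistics. Everything is exercised through parameter recovery, so the
package makes no empirical claims beyond what its own tests and
`scripts/acceptance.R` compute.

## The agent

The agent's skill belief $s^t$ is an unbounded real; its win expectation
is $\sigma(s^t)$ with $\sigma$ the logistic function. Attribution of the
outcome $o^t \in \{0, 1\}$ is sampled from a sigmoid in $s^t$ for wins and
an inverse sigmoid for losses, with indifference points $x_{0w}, x_{0l}$
and non-negative slopes $\beta_w, \beta_l$ (`attribution_probability()`).
The belief then moves against the prediction error
$\delta = o^t - \sigma(s^t)$, scaled by a learning rate
$\alpha_{a,o} \in [0, 1]$ indexed by the attribution and the outcome
(`update_skill()`).

Ensembles (`simulate_ensemble()`) share a single fair-coin outcome
schedule so that all run-to-run variability originates in attribution
sampling. The reference ("benign") parameter set —
$x_{0w} = x_{0l} = 0$, $\beta_w = \beta_l = 2$, internal rates 0.1,
external rates 0.05, $s^0 = 0$ — produces slowly growing divergence
between runs; `decouple_attributions()` removes the skill-to-attribution
arrow while matching the average internal-attribution propensity per
outcome valence (wins and losses matched separately, because the
attribution rule conditions on the outcome), which visibly reduces
late-trial dispersion. A "vulnerable" variant ($\beta_w = 0.5$,
$\beta_l = 5$, internal rates 0.12 for wins and 0.15 for losses)
matches the benign agent under balanced outcomes but collapses relative to
it during an appended 25-loss streak. These regimes are asserted, with
seeds fixed, in the test suite.

`ensemble_summaries()` pools pre-update skill values across runs and
trials and bins them into quintiles by rank (ties broken by rank order),
rather than binning per run: the trial-level question is about the pooled
relationship between momentary belief and attribution, and pooled bins
keep cell counts stable for 100-run ensembles.

## The synthetic task

The simulated experiment mirrors a staircase-controlled maze game probed
every second trial. Difficulty is a scalar driven by a **double
staircase**: two interleaved tracks, each 1-up/1-down with step 0.25 on a
[-4, 4] scale, alternating between trials. A 1-up/1-down rule converges on
the 50% point of the player's psychometric function regardless of ability,
and interleaving two tracks is the classic protection against participants
steering the adaptation. Outcomes follow
$p(\text{win}) = \sigma(\kappa(\text{ability} - \text{difficulty}))$ with
$\kappa = 2$ by default; task features (path length, proportion of frames
in a non-UP orientation, time limit) are affine in difficulty plus noise,
key-press accuracy is a logistic function of ability, and pauses are
bounded noise. These outcome and feature maps are this package's own
plumbing — they stand in for real gameplay and make no claims about any
particular game engine.

Each probe collects an attribution (sampled from the participant's
attribution model; unanswered with probability `missing_prob`) followed by
a skill report: the latent Rescorla-Wagner trajectory value plus Gaussian
noise, both clipped to the [0, 1] slider. Only probed trials enter the
latent recursion, because attribution-dependent learning rates need an
attribution label per update. The default cohort is 40 participants x 120
probes x 2 sessions; recovery experiments use 20 x 120 to keep a full fit
under a minute.

One standardisation detail matters for generator/fitter consistency: the
fitted attribution models use the previous probe's skill report z-scored
within participant as the skill feature, but a sequential generator cannot
z-score a series it has not finished producing. The generator therefore
standardises the lagged report with fixed constants (centre 0.5, scale
0.2, the typical within-participant spread). The transform is monotone
affine, so generated weight signs survive fitting; magnitudes shrink by
the ratio of the two scales, which the recovery tests account for by
checking signs, not magnitudes, for this feature.

The default generative participant couples a 12-rate skill model (internal
learning rates 0.1 above external in every session x outcome cell, session
offset 0.05, report noise 0.1) with a bias+skill attribution model whose
Internal option carries a +1 skill weight after wins and -1 after losses,
and an internal-for-wins bias (+0.8 / -0.8) well above the other options.
The strong bias is deliberate: because loss learning rates exceed win
rates, the average latent skill sits below the slider midpoint, and a weak
bias would be overwhelmed by the skill feature's negative mean, producing
a generator that fails to display the self-serving asymmetry it is meant
to emulate.

What the generator does **not** emulate: real maze solvability, key-press
event streams, attention lapses, slider anchoring effects, or any
systematic difference between a "self" and an "other" condition. Passing
recovery tests therefore show that the estimators work when their
assumptions hold — they are not evidence about human data.

## Skill-report models

All eight family members share the probe-grain recursion
$\delta_t = o_t - s_{t-1}$, $s_t = s_{t-1} + \alpha \delta_t$, with an
additive offset $\beta$ at the first probe of the second session, and a
Gaussian report likelihood with fixed s.d. 0.1. The learning rate may vary
by session (S), outcome (O) and attribution class (A: internal, external,
or missing response), giving 1, 2, 2, 3, 6, 4, 6 or 12 rates
(`skill_model_spec()`, `learning_rate_index()`).

Numerical choices:

* "N(0, 0.1)" is read as standard deviation 0.1, the plausible scale for
  slider noise; reading it as a variance would make the noise s.d. 0.32,
  a third of the whole scale.
* The latent state is clipped to [0, 1] after every update so it lives on
  the slider scale; the recursion itself would otherwise drift outside the
  response range whenever rates are large.
* For models without the A flag the attribution label is ignored entirely
  (a missing response still updates with the cell's rate); for A models a
  dedicated third rate handles missing responses.
* Probes with missing skill reports contribute no likelihood term but
  still advance the recursion.
* The session offset is reparameterised as $2u - 1$ with $u \in [0, 1]$
  in both fitting modes, so the same Beta population prior machinery
  applies to every parameter; an offset beyond $\pm 1$ is meaningless
  after clipping, so the restriction costs nothing.

## Attribution-choice models

Option scores are dot products $s_{t,o} = w_o \cdot f_t$ for Internal,
Maze and Rotations, with the Luck score defined as minus their sum so the
four scores sum to zero — the softmax is otherwise over-parameterised.
Weights are valence-specific (separate for wins and losses) and the six
feature sets range from bias-only (6 parameters) to the full model
(bias + skill + 2 performance + 2 task features, 36 parameters).
Continuous features are z-scored within participant before fitting,
mirroring the model-agnostic pipeline; the skill feature for probe $t$ is
the report from probe $t-1$ (0 for the first probe, the z-scored mean).
Missing attributions carry no choice information and are excluded from the
likelihood.

Two transforms make weights interpretable. `bias_preferences()` applies
the softmax to the bias terms alone (all feature weights clamped to zero),
giving baseline option probabilities. `feature_effect()` computes the
average marginal effect of a feature on an option's choice probability:
the analytic softmax gradient
$\partial p(A) / \partial x = p(A)\,(w_{A,x} - \sum_B p(B) w_{B,x})$
evaluated at $x = 0$ with the other features at their trial values,
averaged over probes whose outcome matches the valence of the weights
being differentiated (weights are valence-specific, so the probability is
only defined per valence). The gradient is verified against central finite
differences to 1e-6 in the tests.

## Inference

There is no general-purpose probabilistic-programming backend in the
package's dependency set, so sampling is an adaptive per-coordinate
random-walk Metropolis-within-Gibbs written for these two likelihood
families, with the likelihood kernels in C++:

* Chains are seeded at jittered per-participant penalised optima
  (L-BFGS-B); short desk-scale chains started from random points spend
  their whole budget burning in, which inflates the WAIC variance penalty
  and destabilises model ranking.
* Skill parameters are sampled on the logit scale with the Jacobian
  correction; attribution weights on the natural scale.
* Proposal scales adapt toward roughly 40% acceptance during warmup only.
* Hierarchical skill fits place independent Beta$(a_i, b_i)$ population
  priors on every unit-interval parameter, with Gamma(2, rate 0.2)
  hyperpriors and log-scale Metropolis updates for $a_i, b_i$;
  hierarchical attribution fits use Normal population priors with
  conjugate mean and inverse-gamma variance updates. Independent fits use
  flat priors on [0, 1] (skill) and Normal(0, 2.5) (weights).
* Split-R-hat is reported per parameter; values above 1.05 trigger a
  warning, not a failure — weakly identified cells (for example the
  missing-attribution rate of a 12-rate model, informed by a handful of
  probes) routinely mix slowly at desk scale without affecting the
  identified parameters. The reference full-scale setting is 4 chains of
  1000 iterations; the package's desk default is 2 chains of 300 with the
  first half as warmup.

WAIC is computed at the participant grain, exactly as the formula above:
the log of the mean likelihood over posterior samples via log-sum-exp, and
the n-1 sample variance of the participant log-likelihood as the penalty
(the variance convention is not dictated by the formula; n-1 is the
unbiased choice and the one the tests freeze). The penalty is reported
unnormalised alongside `lppd`, and `compare_models()` refuses to rank fits
whose data fingerprints differ.

`recovery_experiment()` is the audit loop: generate a cohort with known
parameters, fit, and report per-parameter bias and RMSE, the rank
correlation between generating and recovered profiles, the WAIC ranking,
and the share of participants whose internal-external learning-rate
difference has the generating sign. `shuffle_refit()` is the permutation
control for attribution-dependent rates: shuffling each participant's
attribution labels (counts preserved) and refitting must, and does, pull
the internal-external difference to its null distribution; the desk
default is 50 permutations with independent short-chain refits, with the
full 1000-permutation setting available through the arguments.

## Model-agnostic statistics

Skill updates are first differences of within-participant z-scored reports
(n-1 s.d.; a constant series yields zero updates with a warning rather
than failing a cohort). Permutation tests shuffle condition labels within
participant, recompute per-participant cell means, and use the paired t
across participants; p-values use the add-one convention
$(1 + k)/(1 + n_{perm})$, so the floor is $1/(n_{perm} + 1)$ and results
at the floor are flagged as "p < 1/(n+1)". Hedges' corrected d uses the
small-sample factor $1 - 3/(4(l_1 + l_2) - 9)$ with the pooled,
$l - 1$-weighted s.d.

Quartile discretisation uses rank-based bins of the within-participant
z-scored factor (rank bins are invariant to the monotone z-transform; ties
are broken by order, keeping bins balanced). The interaction test computes
the two-way repeated-measures interaction F (quartile x outcome) on cell
proportions and permutes the factor's raw values within participant before
re-binning — raw-value shuffling rather than bin-label shuffling, because
re-binning after the shuffle preserves the marginal bin occupancy exactly.
Both permutation engines are type-I calibrated in the acceptance tests
(rejection rate within [0.03, 0.07] at the 0.05 level over 500 null
simulations). Benjamini-Hochberg correction wraps `stats::p.adjust`.

## Problem sizes and limitations

The test and acceptance workloads use sizes chosen to make the full suite
a few minutes on one core while leaving every check well powered: 100-run
agent ensembles over 150 trials (300 runs for the amplification regime),
recovery cohorts of 20 participants x 120 probes at 2 chains x 300
iterations, 500-replication calibration suites at 200 (paired) and 99
(interaction-F) permutations, and a 120-player staircase population for
the steady-state win rate.

Known limitations: the sampler is a random-walk scheme — adequate for
these posteriors at these sizes but no substitute for gradient-based
samplers on larger models; the generator's feature maps are stylised; the
"other" experimental condition is not modelled as distinct from "self";
and WAIC is the only model-comparison criterion provided (no LOO or
bridge sampling). Questionnaire scoring is out of scope — the correlation
permutation test is the generic operation such analyses reduce to.
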