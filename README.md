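# utilicit

Measuring a cardinal utility function from risky choice, and reading
marginal utility out of simulated dopamine prediction-error responses.

## What this package is for

Expected-utility theory describes a risky chooser as maximising
E[u(x)] for a utility function u identified, up to a positive affine
transformation, from choices between gambles and safe rewards.
Reinforcement-learning theory describes phasic dopamine activity as a
reward prediction error — delivered minus predicted value. `utilicit`
implements the full computational chain that connects the two for binary
equiprobable juice gambles on 0.1–1.2 ml:

1. **Certainty equivalents (CEs)** by the PEST adaptive staircase
   (`run_pest`) — the safe offer moves by a step ε that doubles after two
   identical choices and halves after a switch, terminating when
   ε < 20 µl — and by an incentive-compatible logistic psychometric fit
   (`fit_psychometric`, CE = −α/β at the 50% point).
2. **A von Neumann–Morgenstern utility function** by the fractile method
   (`build_fractile_schedule`, `run_fractile`): measured CEs become
   outcomes of new gambles that bisect the utility axis
   (levels 0.5, 0.25, 0.75, …, 0.063, 0.938), and the points are fitted
   with a weakly increasing cubic spline with three free knots
   (`fit_utility`).
3. **Marginal utility** as the analytic first derivative dU/dx
   (`marginal_utility`), plus chord slopes over finite reward intervals
   (`interval_marginal_utility`).
4. **Out-of-sample validation** of the fitted function on held-out gambles
   by Deming (errors-in-both-variables) regression, with an EV-residualised
   fit isolating the curvature's contribution (`validate_out_of_sample`).
5. **Stochastic dominance**: exact first-order dominance on finite-lottery
   CDFs (`fosd`), mean-preserving spreads
   (`is_mean_preserving_spread`), and second-order dominance predictions
   under a utility function (`sosd_preference`).
6. **Synthetic dopamine responses**: an inhomogeneous-Poisson generator
   whose phasic rate encodes the utility prediction error with a ~5-fold
   smaller dynamic range for negative errors (`generate_response`,
   `simulate_session`), and the analysis toolkit — 10 ms PSTHs, windowed
   rates, liquid-flow prediction-error alignment times, Pearson
   correlations with marginal utility, Hedges' g with bootstrap CIs
   (`bin_psth`, `window_response`, `prediction_error_time`, `hedges_g`).
7. **TD(λ) learning** (λ = 0.9, complete serial compound) driven by
   response magnitudes, whose stable cue value converges to the mean
   delivered magnitude and therefore orders equal-EV gambles by expected
   utility (`td_config`, `train_on_outcomes`, `compare_learned_values`).

No behavioural or neuronal recordings are deposited anywhere, so all
inputs are generated by a synthetic expected-utility-maximising agent with
a known convex-then-concave ground truth (`ground_truth_utility`,
`agent_params`); every stage is testable against that truth. The methods
vignette (`vignettes/utility-elicitation.Rmd`) documents the model, the
defaults, the numerical choices and the limitations.

## Worked example

```r
library(utilicit)
gt <- ground_truth_utility()          # beta-CDF truth, CE(0.1,1.2 ml) = 0.76 ml

## one PEST staircase against a deterministic maximiser
run_pest(gamble(c(0.1, 1.2)), agent_oracle(agent_params(sensitivity = Inf)),
         seed = 1)
#> PEST: converged after 9 trials; CE = 0.742 ml

## a full fractile session with a noisy agent, 3 CE repeats per node
set.seed(2)
pts <- run_fractile(pest_ce_oracle(agent_params()), repeats = 3)
u <- fit_utility(pts)
u
#> Monotone cubic-spline utility on [0.1, 1.2] ml; interior knots: 0.601, 0.654, 0.918

round(marginal_utility(u, c(0.25, 0.65, 1.10)), 2)
#> [1] 0.11 1.63 0.26            # inverted U: steepest in midrange

certainty_equivalent(gamble(c(0.1, 0.4)), u)   # 0.338 ml > EV 0.25: risk seeking
certainty_equivalent(gamble(c(0.9, 1.2)), u)   # 0.968 ml < EV 1.05: risk averse

## dominance
fosd(gamble(0.4), gamble(c(0.1, 0.4)))                        # "a-dominates"
is_mean_preserving_spread(gamble(c(0.1, 1.2)), gamble(c(0.5, 0.8)))  # TRUE
sosd_preference(gamble(c(0.1, 1.2)), gamble(c(0.5, 0.8)), u)$preferred  # "a"

## simulated dopamine responses to 12 unpredicted reward sizes
cur <- unpredicted_reward_curve(seq(0.1, 1.2, length.out = 12),
                                n_trials = 300, seed = 3)
max(abs(cur$normalized_response - cur$normalized_utility))
#> [1] 0.035                     # responses trace the utility function

## TD(lambda) trained on the responses of two equal-EV gambles
cfg <- td_config(n_reps = 100)
risky <- train_on_outcomes(cur$normalized_response[c(1, 12)], cfg, seed = 4)
safer <- train_on_outcomes(cur$normalized_response[c(5, 8)], cfg, seed = 5)
c(mean(risky), mean(safer))
#> [1] 0.505 0.314               # riskier gamble acquires the higher value
compare_learned_values(risky, safer)$p
#> [1] 3.6e-92
```

The CE of the low-value gamble sits above its expected value and that of
the high-value gamble below it (risk seeking then risk aversion); the
marginal-utility profile across the reward range is an inverted U; the
riskier of two equal-EV gambles is a mean-preserving spread, is predicted
preferred under the convex lower range, and — trained through its simulated
outcome responses — acquires the larger TD cue value.

`run_full(experiment_config())` chains every stage (utility measurement
across sessions, validation, dominance verdicts, neural simulation and
analysis, TD training) under a single master seed and can write all stage
outputs as CSV/JSON; `make_fixtures()` writes small deterministic example
datasets.

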