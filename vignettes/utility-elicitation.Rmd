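---
title: "Measuring utility from risky choice and reading it out of simulated dopamine responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring utility from risky choice and reading it out of simulated dopamine responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(utilicit)
```

## The problem

Expected-utility theory says a decision maker valuing risky options acts as
if maximising the probability-weighted mean of a *utility function* u(x) of
physical outcomes, a function that is identified from choices only up to a
positive affine transformation. Reinforcement-learning theory says phasic
dopamine activity encodes a reward prediction error — delivered minus
predicted value. `utilicit` implements the computational chain that links
the two: it measures a cardinal utility function from binary risky choices,
differentiates it to obtain *marginal utility*, and asks whether simulated
phasic responses whose magnitudes encode utility prediction errors
reproduce the marginal-utility read-out, support stochastic-dominance
predictions, and suffice to train a temporal-difference learner whose cue
values order gambles by expected utility.

Because no behavioural or neuronal recordings are deposited anywhere, every
input is synthetic: a ground-truth utility maximiser stands in for the
subject and an inhomogeneous-Poisson generator for the neurons. That makes
each stage testable against a known truth — the package's central design
idea — at the price that passing tests certify the *procedures*, not any
biological claim.

## The synthetic agent

The ground truth is a beta CDF on the normalised reward range
`[0.1, 1.2]` ml:

$$u(x) = F_{\mathrm{beta}}\!\left(\frac{x - 0.1}{1.1};\, a, b\right),$$

which for $a, b > 1$ is convex then concave with inflection at
$(a-1)/(a+b-2)$. The defaults $a = 4$, $b = 2.77$ were fixed once, against
three qualitative constraints on the behaviour being emulated: the
certainty equivalent (CE) of the full-range equiprobable gamble falls at
0.76 ml; the inflection lies right of midrange (an overall risk-seeking
subject: risk seeking for small rewards, risk averse for large ones); and
the utility slope in midrange is roughly twice the slope near either end,
so the marginal-utility profile across the three task gambles is a
pronounced inverted U.

```{r truth}
gt <- ground_truth_utility()
certainty_equivalent(gamble(c(0.1, 1.2)), gt)   # 0.76 ml
```

Choices follow a logistic rule on the expected-utility difference,

$$P(\text{safe}) = \frac{\lambda}{2} + (1 - \lambda)\,
  \mathrm{logistic}\!\big(\beta\,[u(\text{safe}) - EU(\text{gamble})] + \alpha\big),$$

with sensitivity $\beta$ (default 50 per util, `Inf` for a deterministic
maximiser), bias $\alpha$ (default 0) and lapse rate $\lambda$ (default 0).
A single EU-difference kernel yields monotone psychometric curves in the
safe volume, so the same agent serves the staircase, the
incentive-compatible procedure and the trialwise choice regression.

## Certainty equivalents: PEST and the psychometric check

`run_pest()` implements the adaptive staircase: one constant gamble, a safe
offer moving up after each gamble choice and down after each safe choice by
a step $\varepsilon$ (initial 0.2 ml); from the fourth trial on,
$\varepsilon$ doubles after two identical consecutive choices and halves
after a switch; when $\varepsilon$ drops below the 0.020 ml exit rule the
CE is the mean of the final two offers. The initial offer is uniform on the
representable range, offers are clamped to it, and a 50-trial cap flags
non-terminating sequences as exhausted.

Two numerical facts about this staircase are worth knowing. First, for a
deterministic agent convergence implies the final two offers straddle the
indifference point, giving the error bound exit-rule + final $\varepsilon$
(< 0.04 ml); median sequence length is 11–13 trials. Second, the literal
doubling rule combined with clamping admits a deterministic limit cycle
when the indifference point lies near the range edge: the offer rides the
boundary, $\varepsilon$ inflates, and the staircase jumps back and forth
across the CE indefinitely. `pest_ce_oracle()` therefore applies the
natural session-control policy: an exhausted sequence is re-run from a
fresh random start (up to 5 attempts). Without retries roughly 8–10% of
staircases on narrow top-range gambles exhaust.

`fit_psychometric()` is the incentive-compatible cross-check: safe volumes
drawn from a flat distribution independent of history, a maximum-likelihood
logistic fit $P(\text{safe}) = \mathrm{logistic}(\alpha + \beta\,x)$, and
CE $= -\alpha/\beta$ at the 50% point. A slope that is not significantly
positive leaves the 50% point unidentified and is flagged `"flat"`;
complete separation falls back to the response midpoint with a
`"separation"` flag. For a low-noise agent the two estimators agree within
0.05 ml.

## The fractile construction and the monotone spline

`build_fractile_schedule()` bisects the utility axis: the full-range gamble
first (its CE gets level 0.5 under the anchors u(0.1) = 0, u(1.2) = 1),
then gambles built from previously measured CEs bisect the lowest and
highest remaining subintervals, yielding levels 0.25, 0.75, 0.125, 0.875
and the edge refinements 1/16 and 15/16 — with anchors, the levels
{0, 0.063, 0.125, 0.25, 0.5, 0.75, 0.875, 0.938, 1} (half-up rounding at 3
decimals). Each node's CE is the mean over repeated measurements (default
3) and seeds its descendants.

`fit_utility()` fits the points with a cubic spline with three free
interior knots under an exact monotonicity constraint: the B-spline
coefficients are restricted to be nondecreasing (a sufficient condition for
a nondecreasing spline), encoding nonsatiation. Knot positions are chosen
by Nelder–Mead from five starts (one equispaced, four randomised under a
fixed local seed); for each candidate the coefficients solve a
bound-constrained least-squares problem (L-BFGS-B on increments). Because
7–11 points against 7 coefficients make near-interpolation common, many
knot placements tie at zero residual; a tiny curvature penalty (weight
1e-6) breaks those ties toward the smoothest monotone solution — without
it the fit can wiggle a few 1e-3 util between points. The fitted ends are
renormalised to exactly 0 and 1. On noiseless fractile points from the
ground truth the fit tracks it within 0.003 util; straight-line points
return a linear function to 1e-7.

Marginal utility is the analytic first derivative of the piecewise cubic
(`marginal_utility()`); the chord slope over a finite interval
(`interval_marginal_utility()`) is its discrete counterpart used where a
prediction error spans a reward interval. `certainty_equivalent()` inverts
the monotone fit by root finding (tolerance 1e-9 util in function value).

```{r fractile}
pts <- run_fractile(exact_ce_oracle(gt))
u <- fit_utility(pts)
u
round(marginal_utility(u, c(0.25, 0.65, 1.1)), 2)   # inverted U
```

Session averaging (`average_sessions()`) is pointwise over curves on a
common grid — the declared resolution of an ambiguity between averaging
curves and pooling points. The ±1 SD across-day band covers the ground
truth at most grid points (~85–90% at realistic noise); the residual
misses are the spline's systematic approximation bias, shared across
sessions and bounded by about 0.01 util, which no across-session spread
can capture.

## Out-of-sample validation and a self-validation caveat

`validate_out_of_sample()` compares predicted expected utilities of
held-out gambles (the package generates its own set of 12 spanning the
range) with the utilities of behaviourally measured CEs, by Deming
regression at variance ratio 1 (errors in both variables; jackknife 95%
slope band; swapping axes gives the reciprocal slope). Because both
quantities co-vary with expected value, a second regression is run after
removing the linear EV component from both axes by ordinary regression on
EV; the residual association isolates the curvature's contribution.

One caveat the implementation makes explicit: the same fitted function maps
both axes, so any fitting wiggle produces *shared* deviations from the EV
line. Even when the generating truth is exactly linear, the residual
association is significant far more often than the nominal 5%. Residual
association is therefore summarised by a Pearson correlation (well defined
under the null, unlike the errors-in-variables slope), and competing truths
are compared by the *strength* of that association: in paired replicates
the curved truth shows a significant positive residual relation that is
stronger than the linear truth's in essentially every replicate, while raw
significance alone would not separate them.

## Stochastic dominance

`fosd()` decides first-order dominance exactly on finite lotteries by
comparing right-continuous CDFs on the union of supports (strictness
tolerance 1e-12): safe rewards equal to a gamble's better outcome dominate
it, and the gamble dominates its worse outcome — the four behavioural
choice sets. `is_mean_preserving_spread()` tests equal means plus
majorisation of integrated CDFs; the full-range gamble is a mean-preserving
spread of (0.5, 0.8) ml at the common mean 0.65 ml.
`sosd_preference()` predicts the choice between equal-mean lotteries from
the utility function: concave prefers the safer, convex the riskier, linear
ties — the risk-seeking synthetic subject prefers the riskier gamble.

## Simulated dopamine responses

`generate_response()` emits a piecewise-constant-rate Poisson train:
baseline (default 5 impulses/s, below the 8 impulses/s ceiling typical of
the cell type) everywhere except a phasic window (onset 0.1 s, duration
0.3 s) where the rate is shifted by the utility prediction error — gain 20
impulses/s per util for positive errors, attenuated by 0.2 for negative
ones (the ~5-fold asymmetric dynamic range), perturbed by Gaussian
trial-to-trial noise (SD 2 impulses/s) and floored at zero.
`simulate_session()` draws cues without replacement from a balanced pool,
delivers one gamble outcome per trial, and spaces trials by truncated
Poisson intertrial intervals (mean 5 s, truncated to 2–8 s).

Analysis mirrors standard practice: 10 ms non-overlapping PSTH bins
(`bin_psth()`; a 70 ms moving average can be attached for display and is
never used in statistics), windowed rates minus baseline
(`window_response()`), Pearson correlation of responses with condition
marginal utilities, Hedges' g with a bootstrap percentile CI (default
10,000 resamples), and min–max normalisation of population condition
means. Outcome responses are aligned to the time the smaller reward would
have ended under the 0.004 ml/ms valve flow (25/125/225 ms for the three
task gambles) — at juice onset nothing is learned; the prediction error
arrives when flow continues past the smaller outcome's duration.

At 52 synthetic neurons the +0.15 ml outcome response is largest for the
middle gamble (the steep part of the function) and the response–marginal
utility correlation is ~0.7; responses to 12 unpredicted reward magnitudes
(prediction pinned at zero, so marginal utility coincides with utility)
trace the normalised utility function within a few hundredths. Negative
prediction-error responses, attenuated 5-fold, yield marginal-disutility
correlations that often fail significance at these population sizes — a
statistical-power consequence of the asymmetry, reproduced as such.

## TD(λ) on response magnitudes

`td_config()` fixes the learner: accumulating eligibility traces with
λ = 0.9 over a complete serial compound of 10 within-trial states, cue at
step 1, reward at step 8, discount 1 within the trial, learning rate 0.1
(the representation, rate and read-out are not pinned by any source and
follow the standard construction for this cell type; the "cue response" is
the learned value of the cue state, whose fixed point under a constant
reward r is exactly r). `train_on_outcomes()` delivers two response
magnitudes in balanced pseudorandom alternation (draws without replacement
from an equal pool), runs 1,000 trials, and returns the mean cue value
over the last 200 trials; repeated 2,000 times by default (the comparisons
in the tests use 200 repetitions, which leaves the Monte-Carlo error far
below the effects examined). Stable predictions centre on the mean
delivered magnitude for any λ, so a learner fed the normalised responses
to {0.1, 1.2} ml acquires a larger cue value than one fed {0.5, 0.8} ml —
the expected-utility ordering of the equal-EV pair, by the convexity of
the lower range.

## What the defaults are, and what passing does not show

| Parameter | Default | Units | Why |
|---|---|---|---|
| ground truth a, b | 4, 2.77 | – | CE(full) = 0.76 ml, inflection right of mid, 2:1 slope profile |
| sensitivity | 50 | 1/util | CE measurement SD ~0.02 ml, the scale of the exit rule |
| ε initial / exit | 0.2 / 0.02 | ml | range/5.5; exit rule 20 µl |
| baseline / gain | 5 / 20 | imp/s; per util | sub-8 baseline; phasic peaks ~25 imp/s |
| attenuation | 0.2 | – | 5-fold asymmetry |
| λ, α, steps | 0.9, 0.1, 10 | – | standard trace/step choices |

The generator emulates rate codes, balanced pools and Poisson variability;
it does not emulate adaptation, drift, lapses of attention, licking or eye
movements, cue-onset temporal dynamics beyond one phasic window, or any
loss-domain ("kinked") utility. Tests passing on this agent certify that
the estimation chain recovers what generated the data — not that real
neurons or subjects behave this way.

Problem sizes used throughout the packaged tests: 1,000 staircases for the
sequence-length statistics, 14 sessions × 3 repeats for utility recovery,
200 paired replicates for validation, 52 neurons × 150 trials for outcome
responses, 1,000 trials per magnitude for the unpredicted-reward curve,
and 200 TD repetitions of 1,000 trials.
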