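---
title: "Models and methods behind viptask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind viptask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

viptask simulates and analyzes a poker-based sequential investment task
used to study escalation of commitment (EoC) and its mirror image,
premature opt-out. A participant holds two cards, an opponent holds two
cards, and five shared cards are revealed one at a time. At each stage the
participant either pays the next stage cost to reveal another shared card
or opts out and banks the remaining endowment. If all five shared cards
are revealed, the best five-card hands (out of each player's seven) are
compared under standard Texas hold'em rules: a win returns twice the
invested points, a tie returns them, a loss forfeits them.

Three variants are implemented:

* **exp1** — up to five investment stages; endowment 310 points, stage
  costs 10/20/40/80/160. Half the trials start mid-sequence with 1-4
  computer-made investments ("assigned" decisions), the other half fresh
  ("personally responsible" decisions after the participant's own first
  investment).
* **exp2** — every trial starts with three shared cards revealed; one
  initial investment (50 points) and one reinvestment (100 points) from a
  150-point endowment. The initial decision is made by the participant
  (responsible), by a random advisor (fair coin), or by an optimal advisor
  (invest iff winning-or-tying is at least as likely as losing). The
  stage-two reinvestment decision is the analyzed outcome. A dichotomous
  pre-task *preference* for each trial's initial configuration is elicited
  beforehand.
* **exp3** — the exp2 structure with 90 trials and a between-participant
  gain/loss *framing* of the (payout-identical) outcome display; 5000
  session points convert to 1 GBP, so a perfect 90-win session (27000
  points) is worth 5.4 GBP.

## Outcome probabilities

The central covariate is `p_lose`, the probability of losing the showdown
if the trial is played to the end, computed over all equally likely
completions of the hidden cards. With the opponent's cards on the table
(the default; assigned-advisor variants state this explicitly) and `r`
revealed shared cards, there are `choose(48 - r, 5 - r)` completions —
990 at the exp2 start, 44 at its reinvestment stage — and the package
enumerates them exactly in C++. The exact path is allowed up to 250,000
completions, which covers every state with a known opponent and at least
one revealed card; larger state spaces (e.g. a fresh exp1 trial viewed
without the opponent's cards, ~10^9 completions) must use seeded Monte
Carlo sampling (default 20,000 draws). Requesting the exact method above
the cap is an error, never a silent fallback, and Monte Carlo without a
seed is likewise refused. Inside a seeded simulation session, per-call
Monte Carlo sub-seeds are drawn from the session stream, so a single
session seed reproduces every number bit for bit.

The hand evaluator encodes a five-card hand as one comparable integer
(category plus kicker nibbles), giving a total order in which suits never
break ties; the ace plays high and low. The seven-card evaluator is a
direct O(1) computation, tested for exact equivalence against the
21-subset maximum (an in-package subset route and an independently coded
pure-R oracle in the test suite).

Ties are kept as a separate probability rather than folded into wins: the
task pays ties differently, and the triple (`p_win`, `p_tie`, `p_lose`)
sums to one exactly under enumeration.

## Synthetic participants

Agents choose to invest with probability

$$\Pr(\text{invest}) = \operatorname{logit}^{-1}\!\big(\beta_0 +
\beta_{p}\, p_{\text{lose}} + \beta_{\text{resp}}\,\mathbb{1}[\text{responsible}] +
\beta_{\text{opt}}\,\mathbb{1}[\text{optimal}] + \beta_{\text{pref}}\,\text{pref} +
\beta_{\text{loss}}\,\mathbb{1}[\text{loss frame}] + u_i\big),
\qquad u_i \sim N(0, \sigma^2_u),$$

with the random intercept drawn once per participant. The default
coefficients are the fitted point estimates of the corresponding
experiment's published decision model (exp2: 1.39, −3.18, 1.77, 0.51,
1.24, $\sigma^2_u$ = 0.25; exp3 adds a 0.54 loss-framing effect; exp1
uses its own stage-wise model including its significant interaction
terms), so the published tables serve as the canonical generating
fixtures. Interaction coefficients for exp2/exp3 default to zero — the
corresponding published estimates are small and non-significant, and a
zero-interaction generator makes the main-effects model exactly correctly
specified for recovery tests.

Design choices worth knowing:

* **Preference generation.** The elicited preference is a Bernoulli draw
  from the agent's stage-one policy (intercept + `p_lose` slope + random
  intercept) on the initial configuration. The same policy governs the
  stage-one play decision in responsible trials. This is one admissible
  mechanism linking preference and play — the underlying studies measured
  preference rather than modeling it — and it is configurable. A side
  effect: because preference shares the participant intercept, a joint
  fit of decision on preference partially absorbs the random intercept,
  so marginal refits of full sessions show a mildly smaller intercept,
  preference effect, and participant variance than the generator values.
  Recovery and coverage tests therefore resimulate decisions
  conditionally on a fixed design (fresh intercepts, fixed covariates),
  the standard parametric-bootstrap route, under which the fitted model
  is exactly the generating model.
* **Advisor tie-break.** The optimal advisor invests when
  `p_win + p_tie >= p_lose`; the published rule only defines the strict
  cases, and the equality case (probability ~0 under enumeration) is
  resolved toward the advisor's maximizing role.
* **Regeneration.** Assigned trials whose advisor opts out are discarded
  and regenerated, so they count neither toward payouts nor toward the
  per-condition trial counts.
* **exp1 start stages.** Assigned exp1 trials start at a stage drawn
  uniformly from {2,...,5} (1-4 computer investments); the source design
  does not state the distribution, and uniform is the natural default.
* **Fresh stage-one decisions** (exp1, and exp2/exp3 responsible trials)
  use the stage-one policy above; they are played but excluded from the
  analyzed decision rows, which begin only once a prior investment
  exists.

## Model fitting and inference

`fit_logistic_ri()` and `fit_linear_ri()` estimate the random-intercept
models by maximum marginal likelihood: adaptive Gauss–Hermite quadrature
(default 15 nodes) for a single grouping factor, the Laplace
approximation when intercepts are crossed (exp1's participants and
trials; the trial variance there is reported but typically near zero).
Estimation is delegated to lme4 behind this interface; the test suite
verifies the reported marginal log-likelihood against an independently
coded fine-grid numerical integration (4001-node trapezoid) to 1e-4 on
small instances, and the variance components against closed-form balanced
ANOVA estimators. Inference is Wald (`z = B/SE`, two-sided p; odds ratios
`exp(B)`), matching the published table layout. Separation in the fixed
design is detected via a fixed-effects-only fit and raised as a warning;
non-convergence is flagged on the result object; a boundary (singular)
fit counts as a converged zero-variance estimate.

`predicted_probabilities()` returns inverse-logit predictions at a random
intercept of zero with delta-method confidence bands computed on the
logit scale and transformed (monotone-equivalent to the delta method on
the probability scale, and respects [0, 1]).

`simulate_power()` reproduces the simr-style design analysis: each
replicate simulates a balanced within-participant binary factor directly
from the generating model (baseline logit 1.39, random-intercept variance
0.25 — the assumed components are documented defaults, since the original
computation's settings are not stated), fits the random-intercept
logistic model, and tests the factor by Wald at `alpha`. Replicates are
simulated from the model rather than through the card engine: that is
what a design-analysis of this model estimates, and it is how simr
operates. Non-converged replicates are counted and reported, never
silently dropped.

## Decision quality

For the single-reinvestment variants the expected value of a reinvestment
decision needs no assumptions about future play: opting out is worth a
sure 100 points and investing `300 (1 − p_lose)`, so the two cross at
`p_lose = 2/3`. The benchmark policy invests strictly below 2/3 and opts
out at or above it (at the indifference point both actions have equal
value and either is classified optimal). Investing above the threshold is
*escalation of commitment*; opting out below it is a *premature
opt-out*. The nominal formula implicitly grants ties the win payout; an
exact variant `300 p_win + 150 p_tie` is available for sensitivity
analysis (`score_decisions(ev_method = "exact")`), while classification
always uses the nominal 2/3 rule. Multi-stage exp1 trials are rejected
by the scoring functions: their per-decision value depends on future
decisions, so no fair static benchmark exists.

## Numerical and testing choices

* Exact probabilities are ratios of integer counts; their sum is exactly 1.
* Quadrature: 15 nodes by default, 25 in likelihood-oracle tests; model
  checks at scale use the Laplace approximation for speed (nAGQ = 1),
  whose fixed-effect differences from 15-node AGQ are far below the
  tolerances tested.
* Test problem sizes: the hand evaluator is checked against oracles on
  10^5 sampled hands; property tests of the task engine use hundreds of
  random trials; coverage and power checks use the exp2 study scale (49
  participants × 150 trials) with 100 and 200 replicates respectively;
  exp1 session tests use small sessions with a reduced enumeration cap
  and Monte Carlo sample size, since fresh exp1 stages are the one place
  exact enumeration is genuinely expensive.
* All randomness flows from explicit seeds; identical seeds give
  byte-identical decision logs and CSV files.

## What the generator does and does not emulate

The synthetic agents reproduce the *structure* the analysis models
assume: logistic dependence on `p_lose`, additive condition, preference
and framing effects, and normally distributed participant intercepts.
They do not emulate learning across trials, sequential dependence,
response times, or any preference mechanism beyond the shared-coefficient
link above. Passing tests therefore validate the pipeline's arithmetic
and statistical machinery on faithful synthetic data — they do not
reproduce the human coefficient estimates, which would require the
deposited participant data. Conversions to currency are implemented only
for exp3 (5000 points/GBP, rounded half-up to a penny); the other
variants' rates are not stated and are refused rather than guessed.
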