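# viptask

Simulation and analysis of a poker-based sequential investment task for
studying **escalation of commitment** (EoC) — throwing good money after
bad — and its mirror error, **prematurely abandoning** a profitable
course of action.

In the task a participant and a computer opponent each hold two cards;
five shared cards are revealed one at a time. At each stage the
participant either pays the next (increasing) stage cost to reveal
another shared card or opts out and banks the remaining endowment. If all
shared cards are revealed the best five-card hands are compared under
standard Texas hold'em rules: a win returns twice the invested points, a
tie returns them, a loss forfeits them. Because every trial's exact
probability of losing, $p_{\text{lose}}$, can be enumerated from the
visible cards, each decision can be scored against the expected-value
benchmark — in the single-reinvestment variants opting out is worth a
sure 100 points and investing $300\,(1 - p_{\text{lose}})$, so the
optimal policy invests exactly while $p_{\text{lose}} < 2/3$.

The package provides, end to end:

* **Poker core** — five-card hand ranking (total order, suits never break
  ties, ace plays high and low), best-of-seven evaluation, showdowns; hot
  loops in C++.
* **Probabilities** — exact enumeration of win/tie/lose over all
  completions of the hidden cards (e.g. all $\binom{45}{2} = 990$
  board completions of a three-card start), with seeded Monte Carlo above
  an explicit enumeration cap.
* **Task engine** — the three study variants (multi-stage; three-cards
  revealed with one reinvestment; the same with gain/loss framing),
  cost schedules, random and expected-value-optimal advisors,
  responsibility coding, payout accounting, bonus conversion.
* **Synthetic participants** — logistic decision policies with
  participant random intercepts, defaulting to the published fitted
  coefficients, so complete decision logs can be simulated without any
  participant data.
* **Mixed models** — random-intercept logistic/linear fitting (adaptive
  Gauss–Hermite quadrature / Laplace via lme4) with Wald inference in the
  published table layout, predicted-probability grids, and simr-style
  simulation-based power analysis.
* **Evaluation** — expected-value scoring and classification of every
  decision as optimal, escalation, or premature opt-out.
* **CLI** — `simulate | fit | evaluate | power` subcommands
  (`inst/cli/vip.R`) over seeded, losslessly round-tripping CSV logs.

## Worked example

```r
library(viptask)

# exact outcome probabilities of a three-cards-revealed trial state
st <- game_state(c("Qh", "9c"), c("Jd", "Js"), c("2c", "9d", "Kh"))
outcome_probabilities(st)
#> <outcome_probs> win 0.1980 / tie 0.0000 / lose 0.8020 (exact, n = 990)

# a synthetic session: 10 participants x 150 trials, 50 per condition
d <- simulate_experiment("exp2", n_participants = 10, seed = 42)
nrow(d)
#> [1] 1256

# the decision model: invest ~ p_lose + trial type + preference,
# random intercepts per participant (random assignment as baseline)
fit_logistic_ri(decision ~ p_lose + condition + preference +
                  (1 | participant_id), d)
#> <vip_fit> random-intercept logistic
#>                       term     or estimate    se      z        p
#>                (Intercept) 4.7400    1.560 0.237   6.56 5.44e-11
#>                     p_lose 0.0538   -2.920 0.244 -12.00 4.72e-33
#>  conditionoptimal_assigned 1.4900    0.399 0.202   1.98 4.75e-02
#>       conditionresponsible 3.1100    1.130 0.237   4.78 1.75e-06
#>                 preference 3.7000    1.310 0.168   7.78 7.20e-15
#> Random effects (s^2): participant_id 0.167

# decision quality against the expected-value-optimal policy
session_summary(score_decisions(d))
#>          condition   n invest_rate  mean_ev mean_optimal_ev ev_shortfall
#> 1 optimal_assigned 500   0.8760000 231.6318        250.1818     18.55000
#> 3  random_assigned 500   0.6360000 162.4409        183.4773     21.03636
#> 2      responsible 256   0.8671875 198.1445        212.1271     13.98260
#>   rate_optimal rate_escalation rate_premature
#> 1    0.8440000          0.0620      0.0940000
#> 3    0.7380000          0.1860      0.0760000
#> 2    0.7890625          0.1875      0.0234375
```

Reading the output: investing is strongly discouraged by the probability
of losing (OR 0.054 per unit of $p_{\text{lose}}$), and — at any given
$p_{\text{lose}}$ — more likely after one's own initial investment
(`conditionresponsible`, OR 3.1 vs the random advisor here) and for
preferred initial configurations (OR 3.7). The summary shows the
resulting error mix per condition: escalation (investing past the 2/3
break-even) and premature opt-out rates, and the mean expected-value
shortfall relative to the optimal policy.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/vip.R simulate --experiment 2 --participants 10 --seed 42 --out log.csv
Rscript inst/cli/vip.R fit --data log.csv --out fit.csv
Rscript inst/cli/vip.R evaluate --data log.csv --out scored.csv
```

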