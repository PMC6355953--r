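---
title: "Modelling level dynamics in repeated public goods games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling level dynamics in repeated public goods games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggmarkov)
```

## The experiment this package models

In a repeated public goods game, each of $n = 4$ group members receives an
endowment of $w = 20$ tokens per round and privately contributes
$c_i \in \{0, \dots, 20\}$ to a common pool. The pool is multiplied by a
synergy factor $r$ and split evenly, so player $i$'s round payoff is

$$g_i = w - c_i + \frac{r G}{n}, \qquad G = \sum_{k=1}^{n} c_k .$$

With $r < n$ each contributed token returns $r/n < 1$ to its contributor:
free riding is the dominant action and the Nash equilibrium is $c_i = 0$.
With $r > n$ the return exceeds one token and full contribution
($c_i = w$) is dominant. The package supports two treatment presets over 30
rounds: a *homogeneous* design with $r = 2$ in every round, and a
*heterogeneous* design alternating $r = 2$ (odd rounds) with $r = 6$ (even
rounds), so that players repeatedly switch between a social dilemma and an
environment where cooperation is individually optimal. Groups are
re-shuffled uniformly at random each round, and a session whose size is not
a multiple of 4 has its short group completed by robots that contribute
zero — both features of the experimental protocol the simulator reproduces.

Contributions are discretized into five behavioural levels,
$L_1 = \{0\}$, $L_2 = [1,5]$, $L_3 = [6,14]$, $L_4 = [15,19]$,
$L_5 = \{20\}$, the extreme levels being the two Nash actions. All
statistical machinery operates on these levels.

## The synthetic-data generator

`simulate_session()` plays the game forward with agent policies:

* **Markov-level agents** occupy a level, move by a $5 \times 5$ transition
  matrix, and emit a token amount uniformly within the level's range
  (degenerate at 0 and 20). Uniform within-level emission is the
  maximum-entropy choice given that the model lives at level resolution.
* **Free riders** and **full contributors** are the two constant corners.
* **Conditional cooperators** match the other members' previous-round
  average: $c_t = \mathrm{clip}(\mathrm{round}(\alpha + \beta
  (G_{t-1} - c_{t-1})/(n-1)), 0, w)$.

`make_reference_generator()` equips a session with Markov agents driven by
the packaged round-10 transition-matrix estimates (see below). Default
choices that the data do not dictate, made once:

* the initial level distribution is $(0.10, 0.15, 0.40, 0.15, 0.20)$ —
  repeated public goods play typically opens near half the endowment with
  minorities at both corners;
* in the heterogeneous preset the $r = 2$ level chain lives on the odd
  rounds (matching the analysis window), and even ($r = 6$) rounds emit
  from $(0.05, 0.05, 0.15, 0.14, 0.61)$, placing 61% of the mass on full
  contribution — the share of high contributors reported for $r = 6$
  rounds;
* an optional `drift` mixes the transition matrix toward an
  all-mass-on-$L_1$ matrix at a linear rate, emulating the familiar decline
  of cooperation; the default is no drift, i.e. a time-constant generator.

Per-session seeds are drawn sequentially from the master seed, so
appending a session to a study never changes earlier sessions.

What the generator does *not* emulate: learning dynamics, strategy
switching between policy classes, payoff feedback on level choice, or
session-level dependence. Tests that pass on these panels therefore
establish that the *estimators* are correct and calibrated, not that the
behavioural model is right for any particular human dataset.

## Packaged transition-matrix estimates

Two round-10 level-transition matrices ship as CSV fixtures, one per
treatment ($r = 2$ rounds only in the alternating design). They serve as
reference generators and recovery targets. They are stored as printed, to
two decimals; one row sums to 0.99 from rounding, so `reference_matrix()`
renormalizes rows by default. Their two headline cells are the $L_5$
retention probabilities — 0.54 (homogeneous) versus 0.76 (heterogeneous
$r = 2$) — and their diagonal sums (2.46 versus 3.31) summarize how much
more conservative play is when positive interactions alternate with the
social dilemma.

```{r}
reference_matrix("heterogeneous_r2")["L5", "L5"]
sum(diag(reference_matrix("heterogeneous_r2")))
```

## The multi-state Markov model

Let $X_t \in \{L_1,\dots,L_5\}$ be a player's level at round $t$. The
underlying theory is a non-homogeneous multi-state process with rates
$\lambda_{x,y}(t)$ forming a matrix with zero row sums. Observations,
however, exist only at integer rounds, and the reported objects are
per-round probability matrices. The estimation core is therefore
discrete-time: for origin state $i$ and covariate vector $z_t$,

$$\Pr(X_{t+1} = j \mid X_t = i) =
  \frac{\exp(z_t^\top \beta_{ij})}{\sum_k \exp(z_t^\top \beta_{ik})},
  \qquad \beta_{i1} = 0,$$

a multinomial-logistic link per origin state. Covariate terms are drawn
from intercept, round (centered at mid-experiment), a treatment dummy
(1 = heterogeneous), and their interaction; with $p$ terms the model has
$5 \times 4 \times p$ parameters. A continuous-time view is available via
`transition_to_rate()` (matrix logarithm; rows sum to zero, with a warning
when the matrix is not embeddable) and `rate_to_transition()` (matrix
exponential).

**Estimation.** The likelihood is a product over all players' consecutive
observed round pairs; transitions with identical covariates are aggregated
into counts, so each origin state is an independent convex optimization
solved by BFGS with the analytic gradient, initialized deterministically at
zero coefficients (uniform matrices) — fits are reproducible without
seeds. Convergence targets a gradient max-norm below $10^{-6}$; when a
destination cell has zero observed count the MLE sits at the boundary
(coefficient $\to -\infty$) and that norm is unreachable, so a likelihood
plateau (relative improvement below $10^{-10}$ between BFGS restarts) is
also accepted, with the achieved norm stored in the fit's `convergence`
field and a hard error above $10^{-3}$.

**Observation windows.** In the homogeneous treatment transitions are
round-to-next-round. In the heterogeneous $r = 2$ analysis only odd rounds
carry $r = 2$, so consecutive observed states are two rounds apart; the
model treats each observed pair as one step indexed by its origin round,
and the round covariate lets `predict_matrix()` return a matrix for *any*
round 1..30 — the extrapolation that makes the two treatments comparable
on a common round axis. The one-step square root of a two-round matrix is
deliberately not attempted (it is ill-defined in general).

**The saturated mode** estimates one empirical matrix per origin round
with an additive pseudo-count of 0.5 per cell (configurable, disclosed in
the fit object) to avoid zero rows; rounds or origin states never observed
fall back to uniform rows with a warning. It is the model-free foil to the
parametric fit: on data from a time-constant generator the two agree
within sampling error, which the tests assert at 500 agents (max absolute
cell error below 0.05, comparing the parametric matrix and the
round-averaged saturated matrices against the generator).

**Treatment test.** `lrt()` compares nested covariate specifications
fitted on the same transitions: $2(\ell_1 - \ell_0)$ against a chi-square
with the parameter-count difference as degrees of freedom. Calibration is
checked by simulation at the study's scale (200 null replicates with sham
treatment labels on a common generator; rejection at $\alpha = 0.05$
inside the binomial interval) together with power above 0.8 when the two
packaged matrices truly generate the two arms (40 + 40 players, 15
transitions).

## Occupancy and probability flux

Iterating $d_{t+1} = d_t P_t$ from the round-1 level shares gives the
occupancy trajectory. The flux from state set $A$ into $B$ is

$$F(A \to B) = \sum_{i \in A} \sum_{j \in B} d(i) \, P(i, j),$$

the expected fraction of players moving from $A$ into $B$ in one step;
with $d = \pi$ (the stationary law, `stationary_distribution()`, computed
as the leading left eigenvector after an irreducibility check that names
any closed communicating classes) it is the long-run transition rate.
`flux_to_nash()` reports the per-round flux into the Nash state of the
analysed multiplier — $L_1$ for $r = 2$, $L_5$ for $r = 6$ — with the full
state space as the default source, so the round-$t$ flux is the predicted
occupancy of the Nash state at $t + 1$. Under a generator drifting toward
an absorbing $L_1$ this trajectory is provably non-decreasing, which the
tests verify.

## Trajectory clustering

Each player's retained contribution vector (30 dimensions unfiltered, 15
for the odd rounds) is a point in Euclidean space; `complete_linkage()`
agglomerates with the maximum inter-cluster distance criterion, which
guarantees monotone merge heights. Ties (rare with real-valued distances)
are broken deterministically toward the pair containing the lowest player
index, so results are independent of input order. `cut_clusters()` removes
the $k - 1$ highest merges and numbers clusters by their smallest member.
The implementation is checked against exhaustive search on random
instances and against `stats::hclust` heights.

The experiment's cluster count is an empirical finding, not a criterion,
so `cut_clusters()` always takes an explicit `k`; `suggest_k()` (largest
relative height gap) is offered as a labelled heuristic and never applied
silently. "Significant clustering" has no canonical test; the package's
`cluster_significance()` uses the cophenetic correlation against a null
that permutes each round's contributions across players — one reasonable
operationalization, flagged as an interpretation.

## Numerical choices and edge cases

* Payoffs are doubles and never rounded; $rG/n$ can be fractional. The
  conservation identity $\sum_i g_i = n w + (r - 1) G$ holds to machine
  precision and is asserted on grids.
* Shares and occupancy vectors are renormalized after every operation;
  row-stochasticity is enforced at $10^{-9}$.
* Zero-variance correlation inputs return an `undefined` flag rather than
  NaN; lag significance uses per-player circular-shift permutations because
  pooled transition pairs are not i.i.d.
* Confidence intervals for per-round means are t intervals over players by
  default, with a percentile bootstrap behind an argument — the original
  figure's interval construction is not stated, so both are offered.
* `validate_panel()` cross-checks every payoff against the payoff equation
  at $10^{-6}$ and reports row-level problems instead of failing wholesale.

## Problem sizes used in the tests

The test-suite simulations use the study's own design where the claim
concerns the study (session sizes 13/16/7 and 14/14/7, 30 rounds), 500
agents for parameter-recovery checks, 200 replicates per arm for LRT
calibration and power (40 + 40 players, 15 transitions each), and 100
random 6-point instances for the clustering oracle. These sizes keep every
check sharp at conventional tolerances while remaining quick to run.

## Known limitations

* The behavioural generator is a stationary level-Markov population;
  humans are not. Recovery and calibration results transfer to real panels
  only insofar as the first-order Markov description holds — which is
  itself the modelling assumption under study.
* The parametric model links covariates linearly on the logit scale;
  sharply non-monotone round effects require the saturated mode.
* Random effects per player, hidden states, and misclassification models
  are out of scope.
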