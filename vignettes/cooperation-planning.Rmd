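---
title: "Simulating and planning cooperation on dynamic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and planning cooperation on dynamic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnet)
```

## The game

`coopnet` simulates a turn-based cooperation game played on a dynamic
network. Each of *n* players (default 16) occupies a vertex of a simple
undirected graph and plays *T* rounds (default 15). Each round has five
phases:

1. **Act.** Every player simultaneously chooses to cooperate or defect.
2. **Payoff.** A cooperator pays a cost *c* = 0.05 per linked neighbour;
   each of its neighbours receives a benefit *b* = 0.1. Defectors pay and
   confer nothing. Because *b* > *c*, group welfare is maximized by
   universal cooperation, but each individual is tempted to free-ride.
3. **Recommend.** A *social planner* observes the graph and the decisions
   just made and recommends edge changes: "make link" for unlinked pairs,
   "break link" for linked pairs, delivered to both endpoints.
4. **Accept/reject.** Each endpoint accepts or rejects independently.
5. **Rewire.** By default link formation is bilateral (both endpoints must
   accept an addition) and severance unilateral (one acceptance suffices
   for a deletion). This convention is standard in dynamic-network
   cooperation experiments, where either party can walk away from a
   relationship but partnerships require mutual consent; both rules are
   switches in `game_config()`.

Placing the planner phase after the action phase means every player has a
"most recent decision" from round 1 onward, so recommendation acceptance —
which conditions on the other endpoint's last decision — is always well
defined.

The per-round capital identity `sum(delta) = (b - c) * sum_i deg(i) *
cooperates(i)` is asserted inside the engine on every simulated round.

## The bots

Simulated players follow a logistic discrete-choice model with
heterogeneous cooperative dispositions. Bot *i* draws `theta_i ~
N(mu_theta, sigma_theta)` once at creation. In round 1 it cooperates with
probability `plogis(beta0p + beta1p * theta_i)`; afterwards with
probability `plogis(beta0 + beta1*x_s + beta2*x_n + beta3*x_r + theta_i)`,
where `x_s` is its degree, `x_n` its number of neighbours who cooperated
last round, and `x_r = x_n / x_s` (defined as 0 for isolates, resolving the
0/0 the ratio leaves open). Recommendations are accepted with probabilities
`phi0..phi3` indexed by (valence, referent's last decision).

**The default parameter values are not fitted to human data** — the fitted
values live outside what this package can reproduce. They are calibrated,
once, by simulation, to the canonical signature of static-network
cooperation experiments: mean round-1 cooperation near 70% declining to
roughly 43% by round 15. The calibrated defaults (`bot_params()`) are
`beta0p = 1.0, beta1p = 1, beta0 = -1.3, beta1 = -0.03, beta2 = 0.05,
beta3 = 2.1, sigma_theta = 1, phi = (0.85, 0.55, 0.50, 0.90)`. The
dominant term is `beta3 * x_r`: bots mostly reciprocate their
neighbourhood's cooperation rate, with a mild crowding penalty (`beta1 <
0`) and a mild benefit of cooperating company (`beta2 > 0`). The phi
values encode that breaking with a defector is easy (0.85), linking to a
cooperator attractive (0.90), and the converse moves roughly coin-flips.
Under these defaults the planner conditions reproduce the qualitative
ordering reported for human groups — encouragement > clustering > random
≳ static > maximum-density — which is exactly what the campaign-level
tests check, and no more: passing them shows the generative model behaves
like the stylized facts, not that it predicts human play.

Every bot owns an independent L'Ecuyer-CMRG RNG substream, so its decisions
do not depend on how many random numbers the planner consumed — a
prerequisite for paired cross-condition comparisons with shared seeds.

### Fitting

`fit_bot_params()` estimates the model from logged games by maximizing the
marginal likelihood, integrating the disposition out with Gauss–Hermite
quadrature (25 nodes by default) and sharing `theta_i` across both
logistic branches; this is what identifies `beta1p` — the round-1 slope on
an otherwise-latent quantity — from the posterior the later rounds induce.
`mu_theta` is not separately identified (it is absorbed by the two
intercepts) and is fixed at 0. The acceptance table is estimated cell-wise
with binomial standard errors; empty cells are reported `NA`, never 0.
Degenerate all-identical logs raise a separation error. An independent
mixed-logit implementation (`lme4::glmer` on the later-round subset)
serves as a cross-check oracle in the test suite.

At desk scale (≈ 250 players, 15 rounds), `x_n` and `x_r` are nearly
collinear, so individual coefficients carry substantial sampling noise
even though the linear predictor is well determined; the parameter-recovery
test at 256 bots bounds coefficient errors at ±0.5.

## The planners

* `planner_static()` — never recommends; the rigidity baseline.
* `planner_random(frac = 0.30)` — toggles `round(0.30 * choose(n, 2))`
  uniformly sampled pairs per turn. The fraction applies to *possible*
  edges, i.e. all pairs, not current edges.
* `planner_clustering(frac_extra = 0.05)` — assortment by rule: delete
  every cooperator–defector edge, add every absent cooperator–cooperator
  pair, plus a 5% random component; rule-based recommendations take
  precedence on collision.
* `planner_encouragement(table)` — a per-(pair class, valence, round)
  probability table. The default table fixes the two published
  cooperator–defector deletion anchors — 4.8% in round 1, 72.2% in round
  15 — and interpolates linearly between them. The remaining cells follow
  the trained planner's empirical recommendation frequencies: CC-add 0.99,
  CC-delete 0.03, DD-add 0, DD-delete 1, and a linearly declining CD-add
  schedule with mean 0.58 (0.78 down to 0.38; the published constraints
  are the mean and the declining shape, the endpoints are this package's
  choice). The whole table is replaceable from CSV.
* `planner_neutral(density_schedule)` — choice-agnostic connectivity
  matching: recommends uniform additions or deletions sized to close the
  gap to a per-round target density. The reference schedule should be
  measured from graph-network planner logs with
  `density_schedule_from_logs()`; it cannot ship as a constant because it
  is a property of a locally trained agent.
* `planner_max_density()` — adds every absent edge, never deletes.

## The graph-network planner

`encode_observation()` produces global features (normalized round index
`t/T` — the architecture is non-recurrent, so round-awareness must enter
through the input), node features (last-decision one-hot, normalized
degree), and per-pair features for **all** `choose(n, 2)` unordered pairs
(existence indicator plus an endpoint-decision summary), so a policy logit
exists for every possible edge.

The network applies two message-passing blocks. Each block updates pair
latents from (pair, endpoints, global), sums incident pair latents onto
nodes, updates nodes, sums everything into a global update. Endpoint
features enter the pair update through their sum and elementwise product,
making the update symmetric under endpoint exchange — together with the
shared weights this gives exact permutation equivariance of the logits and
invariance of the value, which the test suite checks on random weights.
Readouts are a scalar logit per pair (`E'`) and a scalar value (`u'`). All
MLPs are single-hidden-layer tanh networks written in base R with
hand-derived gradients (verified against finite differences at tolerance
1e-4).

**Action distribution.** The policy is factorized: each pair is
recommended independently with probability `sigmoid(logit)`, valence
determined by the current edge state. This keeps the `2^choose(n,2)`
action space tractable and matches a per-pair-logit readout.

**Reward.** `mean per-player capital gain + lambda * fraction of issued
recommendations that executed`, `lambda = 0.1`. The quality term gives the
agent a dense signal for making acceptable recommendations before the
capital consequences are distinguishable; its weight and the choice of
"executed fraction" as the quality measure are this package's design,
exposed in the config.

**Training.** Advantage actor–critic: full-episode discounted returns
(`gamma = 0.99`; episodes are 15 rounds, so n-step bootstrapping adds
little and the default uses Monte-Carlo returns), advantage `R_t - v(s_t)`
with the critic as baseline, value-loss weight 0.5, entropy bonus 0.003,
Adam at 5e-3 on the flattened parameter vector. Bot groups are resampled
every episode. Divergence (non-finite loss) halts training and keeps the
last good parameters. Training is single-process; the configuration
accepts budgets up to the 5e7-round ceiling, with a desk-scale default of
2e5 simulated rounds and width-16 latents (minutes on one core).

Three numerical choices matter for making this learn at desk scale, where
the factorized policy's credit assignment — which of ~30 simultaneous
per-pair emissions moved a single scalar round reward — is extremely
noisy:

* *Batched updates and normalized advantages.* Ten episodes are
  accumulated per gradient step and advantages are standardized within
  each batch, trading optimizer steps for much cleaner gradients.
* *A sparse-recommendation prior.* The policy readout bias starts at -2
  (each pair recommended with probability ~0.12). Started symmetric, the
  capital term's appetite for density drives the policy into an
  everything-at-once saturation where per-pair gradients vanish before
  any class discrimination can form.
* *A large Adam epsilon (1e-4).* Near a saturated policy the gradients
  shrink toward zero and the `1/sqrt(v)` rescaling of a small-epsilon
  Adam amplifies residual noise into a random walk of the logits — which
  empirically destroyed learned discrimination late in training.

The desk-scale recipe additionally trains on 8-player groups (28
candidate pairs instead of 120, so each emission carries ~4x more credit)
and relies on the network's permutation equivariance and shared weights
to transfer to full 16-player evaluation games; at the 2e5-round budget
this reliably develops the qualitative policy signature — adding
cooperator–cooperator links far more readily than defector–defector links
and protecting cooperator–cooperator edges while breaking
defector–defector ones — but should not be expected to reach the
performance of a full-scale training run.

## The analysis suite

* `cooperation_rate()` — per-round cooperator fraction.
* `recommendation_breakdown()` — emission probabilities by pair class and
  valence, with denominators counting *chances* (pair-rounds where the
  valence applied) and 95% credible intervals from a uniform Beta(1, 1)
  prior.
* `choice_assortativity()` — edge-wise correlation of the binary
  cooperate/defect label (computed via igraph's assortativity; an
  exhaustive edge-enumeration oracle backs it in the tests). Undefined
  (NA) when all labels agree.
* `degree_bias()` — mean cooperator degree minus mean defector degree.
* `core_periphery()` — discrete Borgatti–Everett-style estimator: the
  core assignment maximizing the Pearson correlation between the adjacency
  and the ideal pattern (pair linked iff either endpoint is core). Exact
  search over all `2^n - 2` assignments up to n = 16, using a closed form
  for the correlation in terms of core size and periphery-internal edge
  count; a greedy single-swap ascent beyond. Ties break to the smallest
  core, then the smallest membership encoding; on saturated graphs (every
  assignment tied, e.g. complete graphs) the score is NA. The continuous
  variant of the estimator is a known alternative; the discrete one is
  used because its exact optimum is testable by enumeration.
* `core_composition_test()` — label-permutation test of the cooperator
  share of the core, with a +1/+1 small-sample correction.
* `gini_and_lorenz()` — mean-scaled pairwise-difference Gini plus the
  Lorenz curve. Capital can be negative in this game and the Gini is then
  undefined; negative vectors are shifted so the minimum is zero and the
  shift reported (an explicit, logged choice — reference treatments of
  negative-wealth Gini differ).

## Campaigns and reproducibility

`campaign()`/`run_campaign()` simulate groups-per-condition; group *g*
uses seed `base_seed + g`, and because bot dispositions derive from the
group seed, conditions sharing a base seed face identical populations —
enabling the paired sign-flip permutation test
(`paired_final_round_test()`) used for condition contrasts. Logs are JSONL
(one record per round), graphs export to CSV edge lists or GraphML, and
`campaign_digest()` fingerprints a campaign for end-to-end reproducibility
checks.

## Problem sizes used in the tests

The test suite runs campaigns of 20 groups (16 players, 15 rounds) for
condition contrasts, parameter recovery at 256 bots x 15 rounds, exhaustive
metric-oracle sweeps over all graphs with up to 6 nodes plus 200 random
10-node graphs, and one desk-scale training run of 2e5 rounds at width 16.
These sizes were chosen so the full suite completes on a single core in
well under half an hour while leaving each statistical check comfortably
powered.

## Known limitations

* Bot parameters are calibrated, not fitted to human data; conclusions
  about *human* play cannot be drawn from these simulations.
* The bots have no memory beyond the previous round and no within-game
  learning, matching the generative model but not necessarily people.
* Desk-scale training demonstrates the learning machinery and the policy's
  qualitative signature, not a converged full-scale policy.
* The exact starting topology of the reference experiments is not
  recoverable; Erdős–Rényi G(n, 0.3) is the seeded default and is
  configurable.
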