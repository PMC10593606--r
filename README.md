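# coopnet

Social planners for networked cooperation games: simulation, bot
modelling, rule-based and learned planners, and network analysis, in R.

## The problem

Groups playing a repeated cooperation game on a network face a social
dilemma: cooperation pays a per-neighbour cost *c* = 0.05 and delivers a
per-neighbour benefit *b* = 0.1, so everyone cooperating maximizes group
welfare while each individual is tempted to free-ride — and cooperation
reliably decays on static networks. A *social planner* that observes the
network and the players' latest decisions can recommend making or
breaking specific links; players accept or reject each recommendation
(additions need both endpoints, deletions one). The question this package
supports studying is *which recommendation policies sustain cooperation*:
classic assortment rules that cluster cooperators and ostracize
defectors, density heuristics, distilled probability tables, or a policy
learned end-to-end by reinforcement learning.

At its core are:

* a **game engine** for the act → payoff → recommend → accept → rewire
  loop, fully seeded and log-replayable;
* **bots** — a logistic discrete-choice model of play,
  `P(cooperate) = plogis(beta0 + beta1*x_s + beta2*x_n + beta3*x_r + theta_i)`
  after round 1 (`x_s` degree, `x_n` cooperating neighbours, `x_r` their
  ratio, `theta_i ~ N(mu, sigma)` a fixed disposition), with a
  four-cell acceptance table `phi(valence, referent's last action)` —
  plus marginal maximum-likelihood fitting of all of it from logs
  (`fit_bot_params()`, Gauss–Hermite quadrature, classic `coef`/`summary`
  methods);
* six **rule-based planners** (static, random 30%, cooperative
  clustering + 5%, encouragement table, density-matching "neutral",
  maximum density);
* a **graph-network planner** — two message-passing blocks over global /
  node / pair features producing a logit per candidate pair and a value
  estimate, trained by advantage actor–critic against simulated groups,
  implemented in base R with hand-derived gradients;
* the **analysis suite**: cooperation trajectories, recommendation
  breakdowns by pair class × valence with uniform-prior credible
  intervals, choice assortativity, degree bias toward cooperators,
  exact core–periphery detection with a label-permutation composition
  test, and Gini/Lorenz inequality.

## A worked example

Compare a static planner with the encouragement planner over 20 paired
groups of 16 bots:

```r
library(coopnet)

cfg  <- game_config()                 # 16 players, 15 rounds, c = 0.05, b = 0.1
stat <- run_campaign(campaign("static",        20, cfg, base_seed = 100))
enc  <- run_campaign(campaign("encouragement", 20, cfg, base_seed = 100))

round(tail(stat$summary$mean_cooperation, 1), 3)
#> [1] 0.416
round(tail(enc$summary$mean_cooperation, 1), 3)
#> [1] 0.653
paired_final_round_test(enc$logs, stat$logs)$p_value
#> [1] 9.999e-05
```

Cooperation among the calibrated bots decays to ~43% on static networks,
while the encouragement planner — which deletes cooperator–defector
links with probability rising from 4.8% (round 1) to 72.2% (round 15),
adds cooperator–cooperator links almost surely, and never links two
defectors — holds it near 65%; the paired sign-flip test (identical bot
populations under both conditions, thanks to the shared base seed) puts
the contrast at the permutation floor.

Train and inspect a planner of your own:

```r
fit <- train_agent(a2c_config(budget_rounds = 2e5, seed = 7))
logs <- lapply(1:20, function(g)
  run_game(game_config(), planner_graphnet(fit$params),
           make_bots(bot_params(), 16, 9000 + g), 9000 + g))
recommendation_breakdown(logs)       # CC-add vs DD-add emission rates
```

A thin CLI wraps the same functions: `exec/coopnet run-campaign
--condition clustering --groups 20 --seed 1 --out logs/`.

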