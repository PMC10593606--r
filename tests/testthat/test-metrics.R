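# Analysis suite: assortativity, degree bias, core-periphery, inequality,
# recommendation breakdowns, permutation test.

test_that("cooperation rate is a straight count", {
  cfg <- game_config(n_players = 16, n_rounds = 3)
  acts <- matrix(0L, 16, 3)
  acts[1:11, 2] <- 1L
  acts[, 3] <- 1L
  lg <- run_game(cfg, planner_static(), make_fixture(acts), 1)
  expect_equal(cooperation_rate(lg, 1), 0)
  expect_equal(cooperation_rate(lg, 2), 11 / 16)
  expect_equal(cooperation_rate(lg, 3), 1)
  expect_error(cooperation_rate(lg, 4), "round not in log")
})

test_that("choice assortativity matches hand-checkable extremes", {
  # two disjoint monochrome triangles: perfectly assortative
  adj <- adj_from_edges(6, c(1, 2, 1, 3, 2, 3, 4, 5, 4, 6, 5, 6))
  expect_equal(choice_assortativity(adj, c(1, 1, 1, 0, 0, 0)), 1)
  # complete bipartite cooperator-defector graph: perfectly disassortative
  adjb <- adj_from_edges(4, c(1, 3, 1, 4, 2, 3, 2, 4))
  expect_equal(choice_assortativity(adjb, c(1, 1, 0, 0)), -1)
  # path C-C-D-D equals the brute-force edge-label correlation
  expect_equal(choice_assortativity(adj_path4(), c(1, 1, 0, 0)),
               assortativity_oracle(adj_path4(), c(1, 1, 0, 0)))
  # all labels identical: undefined
  expect_true(is.na(choice_assortativity(adj_path4(), c(1, 1, 1, 1))))
})

test_that("choice assortativity equals the edge-correlation oracle on random graphs", {
  set.seed(7)
  done <- 0
  while (done < 40) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, 0.45)
    labels <- rbinom(n, 1, 0.5)
    if (sum(adj) == 0 || length(unique(labels)) < 2) next
    ours <- choice_assortativity(adj, labels)
    oracle <- assortativity_oracle(adj, labels)
    if (is.na(oracle) || is.na(ours)) {
      expect_identical(is.na(ours), is.na(oracle))
    } else {
      expect_equal(ours, oracle, tolerance = 1e-12)
    }
    done <- done + 1
  }
})

test_that("degree bias is the cooperator-defector mean degree gap", {
  # regular graph: zero for any labelling
  ring <- adj_from_edges(6, c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 1, 6))
  expect_equal(degree_bias(ring, c(1, 0, 1, 0, 1, 0)), 0)
  # 16-node star with a cooperating hub: 15 - 1 = 14
  expect_equal(degree_bias(adj_star(16), c(1, rep(0, 15))), 14)
  # label swap negates
  adj <- random_adjacency(8, 0.4)
  lab <- c(1, 1, 1, 0, 0, 0, 1, 0)
  expect_equal(degree_bias(adj, lab), -degree_bias(adj, 1 - lab))
  # one empty class: undefined
  expect_true(is.na(degree_bias(adj, rep(1, 8))))
})

test_that("core-periphery recovers the star and matches the exhaustive oracle", {
  cp <- core_periphery(adj_star(7))
  expect_equal(cp$core, 1)
  expect_equal(cp$score, 1)
  # complete graph: correlation undefined, tie-break to the smallest core
  cpc <- core_periphery(matrix(1L, 5, 5) - diag(5L))
  expect_true(is.na(cpc$score))
  expect_equal(cpc$core, 1)
  # random graphs vs the naive enumeration oracle
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    adj <- random_adjacency(n, 0.4)
    if (sum(adj) == 0) next
    got <- core_periphery(adj)
    want <- core_periphery_oracle(adj)
    if (is.finite(want$score)) {
      expect_equal(got$score, want$score, tolerance = 1e-10)
      expect_equal(length(got$core), length(want$core))
    }
  }
  expect_error(core_periphery(matrix(0L, 2, 2)), "at least 3 nodes")
})

test_that("greedy core-periphery search approximates the exact optimum", {
  set.seed(3)
  for (rep in 1:5) {
    adj <- random_adjacency(12, 0.3)
    exact <- core_periphery(adj)                       # exhaustive (n <= 16)
    greedy <- core_periphery(adj, max_exact = 8)       # forces the heuristic
    expect_gte(greedy$score, exact$score - 0.1)
  }
})

test_that("core composition shares and permutation test behave", {
  # core exactly the cooperators in a split graph
  adj <- adj_from_edges(6, c(1, 2, 1, 3, 2, 3, 1, 4, 2, 5, 3, 6))
  lab <- c(1, 1, 1, 0, 0, 0)
  cp <- core_periphery(adj, last_actions = lab)
  expect_equal(cp$core_coop_share, mean(lab[cp$core] == 1))
  # all-cooperator labels: the statistic is permutation-invariant, p = 1
  expect_equal(core_composition_test(c(1, 2), rep(1, 6), n_perm = 200, seed = 1), 1)
  # doubling n_perm leaves p within Monte-Carlo error
  p1 <- core_composition_test(1:3, lab, n_perm = 4000, seed = 2)
  p2 <- core_composition_test(1:3, lab, n_perm = 8000, seed = 3)
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("permutation p-value matches the hypergeometric tail", {
  # 16 nodes, 8 cooperators, core = exactly the cooperator set: the only
  # permutation with share >= 1 puts all 8 cooperators in the core,
  # P = 1 / C(16, 8)
  lab <- c(rep(1, 8), rep(0, 8))
  p <- core_composition_test(1:8, lab, n_perm = 2e4, seed = 4)
  target <- 1 / choose(16, 8)                          # 7.77e-5
  # with the +1/+1 correction, E[p] ~ (1 + n_perm * target) / (1 + n_perm)
  expect_lt(p, 1e-3)
  expect_gte(p, 1 / (1 + 2e4))
})

test_that("Gini and Lorenz agree with the pairwise-difference formula", {
  eq <- gini_and_lorenz(rep(3, 8))
  expect_equal(eq$gini, 0)
  expect_equal(eq$lorenz$share, eq$lorenz$p)  # 45-degree line
  g <- gini_and_lorenz(c(1, 0, 0, 0))
  expect_equal(g$gini, 0.75)                  # 6 / (2 * 16 * 0.25)
  # scale invariance
  x <- c(0.2, 1.4, 3, 0.9)
  expect_equal(gini_and_lorenz(x)$gini, gini_and_lorenz(10 * x)$gini)
  # Lorenz curve is convex and ends at 1
  lz <- gini_and_lorenz(x)$lorenz
  expect_equal(lz$share[length(lz$share)], 1)
  expect_true(all(diff(diff(lz$share)) > -1e-12))
  # bounds for non-negative data
  set.seed(8)
  for (rep in 1:10) {
    v <- rexp(6)
    gi <- gini_and_lorenz(v)$gini
    expect_gte(gi, 0); expect_lte(gi, 1 - 1 / 6)
  }
  # negatives: shifted so min = 0, shift reported; "none" errors
  sh <- gini_and_lorenz(c(-1, 0, 1, 2))
  expect_equal(sh$shift, 1)
  expect_error(gini_and_lorenz(c(-1, 0, 1), shift = "none"), "negative capital")
})

test_that("recommendation breakdown counts chances and applies uniform-prior CrIs", {
  # static planner: all probabilities zero, denominators cover all pair-rounds
  cfg <- game_config(n_players = 6, n_rounds = 4)
  lg <- run_game(cfg, planner_static(), fixture_all(6, 4, 1L), 2)
  bd <- recommendation_breakdown(lg)
  expect_equal(sum(bd$chances), choose(6, 2) * 4)
  expect_true(all(bd$prob[bd$chances > 0] == 0))
  # Beta(1, 1)-posterior CrI for 0 successes in n chances
  cc_del <- bd[bd$pair_class == "CC" & bd$valence == "delete", ]
  expect_equal(cc_del$ci_lo, stats::qbeta(0.025, 1, cc_del$chances + 1))
  expect_equal(cc_del$ci_hi, stats::qbeta(0.975, 1, cc_del$chances + 1))
  # direct check of the 0-successes-in-100 case against the Beta(1, n)
  # closed form x = 1 - (1 - q)^(1/n)
  expect_equal(stats::qbeta(c(0.025, 0.975), 1, 101),
               c(1 - 0.975^(1 / 101), 1 - 0.025^(1 / 101)), tolerance = 1e-6)
  # cells with no chances are reported missing: all-cooperate game has no
  # CD or DD pairs
  expect_true(all(is.na(bd$prob[bd$pair_class != "CC"])))
})

test_that("breakdown recovers a known emission probability", {
  # encouragement planner on a permanent CD edge: round-1 cells aggregate
  # to the table anchor
  cfg <- game_config(n_players = 2, n_rounds = 1,
                     initial_graph = list(generator = "complete"))
  acts <- matrix(c(1L, 0L), 2, 1)
  logs <- lapply(1:3000, function(g)
    run_game(cfg, planner_encouragement(), make_fixture(acts, accept = "none"), g))
  bd <- recommendation_breakdown(logs, by_round = TRUE)
  cell <- bd[bd$pair_class == "CD" & bd$valence == "delete" & bd$round == 1, ]
  expect_equal(cell$chances, 3000)
  ci <- stats::qbinom(c(5e-4, 1 - 5e-4), 3000, 0.048) / 3000
  expect_gte(cell$prob, ci[1]); expect_lte(cell$prob, ci[2])
})

test_that("log summaries tabulate one row per group, round and statistic", {
  cfg <- game_config(n_players = 6, n_rounds = 3)
  logs <- lapply(1:2, function(g)
    run_game(cfg, planner_random(), make_bots(bot_params(), 6, g), g))
  sm <- summarize_logs(logs)
  expect_equal(nrow(sm), 2 * 3 * 4)
  expect_true(all(sm$value[sm$statistic == "cooperation"] >= 0))
  expect_true(all(sm$value[sm$statistic == "density"] <= 1))
})
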