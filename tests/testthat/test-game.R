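# Game engine: payoffs, recommendation resolution, turn loop, determinism.

test_that("payoff arithmetic matches the cost/benefit rule", {
  # isolated cooperator: no neighbours, no cost, no benefit
  st <- game_state(matrix(0L, 3, 3))
  expect_equal(payoff_phase(st, c(1, 1, 0))$delta, c(0, 0, 0))

  # cooperator with degree 4, two cooperating neighbours: -4c + 2b = 0
  st <- game_state(adj_from_edges(5, c(1, 2, 1, 3, 1, 4, 1, 5)))
  out <- payoff_phase(st, c(1, 1, 1, 0, 0))
  expect_equal(out$delta[1], -4 * 0.05 + 2 * 0.1)

  # defector with 3 cooperating neighbours: pays nothing, receives 3b
  out <- payoff_phase(game_state(adj_star(4)), c(0, 1, 1, 1))
  expect_equal(out$delta[1], 0.3)
  # ... and confers nothing: its neighbours receive no benefit from it
  expect_equal(out$delta[2:4], rep(-0.05, 3))
})

test_that("payoff phase rejects incomplete action vectors", {
  st <- game_state(matrix(0L, 3, 3))
  expect_error(payoff_phase(st, c(1, 0)), "contract violation")
  expect_error(payoff_phase(st, c(1, 0, NA)), "contract violation")
})

test_that("per-round capital deltas conserve (b - c) * cooperator degree mass", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    st <- game_state(random_adjacency(n))
    acts <- stats::rbinom(n, 1, 0.5)
    out <- payoff_phase(st, acts, cost = 0.05, benefit = 0.1)
    expect_equal(sum(out$delta),
                 (0.1 - 0.05) * sum(rowSums(st$adjacency) * acts))
  }
})

test_that("acceptance semantics: bilateral formation, unilateral severance", {
  st <- game_state(adj_from_edges(3, c(1, 2)), last_action = c(1, 0, 1))
  recs <- recommendations(c(1, 1), c(2, 3), c("delete", "add"))

  # add with one rejection -> not created; delete with one acceptance -> removed
  res <- resolve_recommendations(st, recs, cbind(c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_equal(res$state$adjacency[1, 2], 0L)  # delete executed
  expect_equal(res$state$adjacency[1, 3], 0L)  # add not executed
  expect_equal(res$changes$executed, c(TRUE, FALSE))

  # both accept -> add executes
  res2 <- resolve_recommendations(st, recs, cbind(c(TRUE, TRUE), c(FALSE, TRUE)))
  expect_equal(res2$state$adjacency[1, 3], 1L)

  # configurable: "both" rule for deletes blocks the unilateral severance
  res3 <- resolve_recommendations(st, recs, cbind(c(TRUE, TRUE), c(FALSE, FALSE)),
                                  rule_delete = "both")
  expect_equal(res3$state$adjacency[1, 2], 1L)
})

test_that("empty recommendation set leaves the graph unchanged", {
  st <- game_state(adj_path4(), last_action = c(1, 1, 0, 0))
  res <- resolve_recommendations(st, recommendations(), matrix(logical(0), 0, 2))
  expect_identical(res$state$adjacency, st$adjacency)
  expect_equal(nrow(res$changes), 0)
})

test_that("invalid recommendations are rejected with the offending pair named", {
  st <- game_state(adj_from_edges(3, c(1, 2)), last_action = c(1, 1, 1))
  expect_error(
    resolve_recommendations(st, recommendations(1, 2, "add"),
                            cbind(TRUE, TRUE)),
    "add.*\\(1, 2\\)")
  expect_error(
    resolve_recommendations(st, recommendations(1, 3, "delete"),
                            cbind(TRUE, TRUE)),
    "delete.*\\(1, 3\\)")
  expect_error(
    resolve_recommendations(st, recommendations(c(1, 1), c(3, 3), c("add", "add")),
                            cbind(c(TRUE, TRUE), c(TRUE, TRUE))),
    "duplicate")
  expect_error(
    resolve_recommendations(st, recommendations(1, 9, "add"), cbind(TRUE, TRUE)),
    "invalid pair")
})

test_that("scripted games produce the scripted outcomes", {
  cfg <- game_config(n_players = 6, n_rounds = 8,
                     initial_graph = list(generator = "gnp", p = 0.5))
  # always-cooperate population: cooperation rate 1 in every round
  lg <- run_game(cfg, planner_static(), fixture_all(6, 8, 1L), seed = 3)
  expect_equal(cooperation_rate(lg), rep(1, 8))
  # all-defect: nobody pays, nobody receives; capital pinned at 0
  lg0 <- run_game(cfg, planner_static(), fixture_all(6, 8, 0L), seed = 3)
  for (r in lg0$records) expect_equal(r$capital, rep(0, 6))
  # static planner: the edge set never changes
  e0 <- lg$initial_edges
  for (r in lg$records) expect_equal(r$edges_after, e0)
})

test_that("a game is a pure function of (config, planner, population, seed)", {
  cfg <- game_config(n_players = 8, n_rounds = 6)
  bots <- make_bots(bot_params(), 8, seed = 11)
  a <- run_game(cfg, planner_random(), bots, seed = 5)
  b <- run_game(cfg, planner_random(), bots, seed = 5)
  expect_identical(campaign_digest(list(a)), campaign_digest(list(b)))
  # and JSONL serialization is byte-identical
  fa <- tempfile(); fb <- tempfile()
  write_game_log(a, fa); write_game_log(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed changes the log
  c <- run_game(cfg, planner_random(), bots, seed = 6)
  expect_false(identical(campaign_digest(list(a)), campaign_digest(list(c))))
})

test_that("graphs stay simple through arbitrary rewiring", {
  cfg <- game_config(n_players = 10, n_rounds = 10)
  bots <- make_bots(bot_params(), 10, seed = 2)
  for (pl in list(planner_random(), planner_clustering(), planner_max_density())) {
    lg <- run_game(cfg, pl, bots, seed = 7)
    for (r in lg$records) {
      e <- r$edges_after
      if (nrow(e)) {
        expect_true(all(e[, 1] < e[, 2]))
        expect_false(anyDuplicated(paste(e[, 1], e[, 2])) > 0)
      }
    }
  }
})

test_that("JSONL round trip preserves the log", {
  cfg <- game_config(n_players = 6, n_rounds = 5)
  bots <- make_bots(bot_params(), 6, seed = 4)
  lg <- run_game(cfg, planner_clustering(), bots, seed = 12)
  f <- tempfile(fileext = ".jsonl")
  write_game_log(lg, f)
  lg2 <- read_game_log(f)
  expect_identical(campaign_digest(list(lg)), campaign_digest(list(lg2)))
  expect_equal(lg2$config$n_players, 6)
  expect_equal(length(lg2$records), 5)
  expect_equal(lg2$records[[3]]$recs$valence, lg$records[[3]]$recs$valence)
})
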