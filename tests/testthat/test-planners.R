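# Rule-based planners: budgets, rule coverage, table lookups, validity.

rec_count <- function(planner, state, seed = 1) {
  s <- coopnet:::rng_streams(seed, 1)
  nrow(coopnet:::with_stream(s[[1]], recommend(planner, state)))
}

test_that("static planner never recommends anything", {
  st <- game_state(random_adjacency(16), last_action = rbinom(16, 1, 0.5))
  expect_equal(nrow(recommend(planner_static(), st)), 0)
  lg <- run_game(game_config(), planner_static(), fixture_all(16, 15, 1L), 1)
  expect_equal(sum(sapply(lg$records, function(r) nrow(r$recs))), 0)
})

test_that("random planner samples exactly round(frac * C(n,2)) distinct pairs", {
  set.seed(5)
  for (n in 2:32) {
    st <- game_state(random_adjacency(n), last_action = rbinom(n, 1, 0.5))
    m <- rec_count(planner_random(0.30), st, seed = n)
    expect_equal(m, round(0.30 * choose(n, 2)))
  }
  # complete graph: every sampled recommendation must be a deletion
  stc <- game_state(matrix(1L, 8, 8) - diag(8L), last_action = rep(1L, 8))
  s <- coopnet:::rng_streams(2, 1)
  recs <- coopnet:::with_stream(s[[1]], recommend(planner_random(), stc))
  expect_true(all(recs$valence == "delete"))
})

test_that("clustering planner applies its rules exhaustively, then the 5% extra", {
  # one defector (node 1) linked to three cooperators: all three edges deleted
  st <- game_state(adj_star(4), last_action = c(0, 1, 1, 1))
  s <- coopnet:::rng_streams(3, 1)
  recs <- coopnet:::with_stream(s[[1]], recommend(planner_clustering(), st))
  del <- recs[recs$valence == "delete", ]
  expect_true(all(paste(1, 2:4) %in% paste(del$i, del$j)))
  # absent cooperator pairs all get add recommendations
  add <- recs[recs$valence == "add", ]
  expect_true(all(c("2 3", "2 4", "3 4") %in% paste(add$i, add$j)))
  # random component size recorded before de-duplication
  expect_equal(attr(recs, "n_random_sampled"), round(0.05 * 6))

  # all cooperating on a complete graph: rules are empty, only the 5% fires,
  # necessarily as deletions
  stc <- game_state(matrix(1L, 16, 16) - diag(16L), last_action = rep(1L, 16))
  s2 <- coopnet:::rng_streams(4, 1)
  recs2 <- coopnet:::with_stream(s2[[1]], recommend(planner_clustering(), stc))
  expect_equal(attr(recs2, "n_random_sampled"), 6)  # round(0.05 * 120)
  expect_lte(nrow(recs2), 6)
  expect_true(all(recs2$valence == "delete"))
})

test_that("encouragement table carries the published CD-delete anchors", {
  tab <- default_encouragement_table(15)
  expect_equal(coopnet:::encouragement_prob(tab, 1, "CD", "delete"), 0.048)
  expect_equal(coopnet:::encouragement_prob(tab, 15, "CD", "delete"), 0.722)
  # DD pairs are never recommended for addition, always for deletion
  expect_equal(coopnet:::encouragement_prob(tab, 7, "DD", "add"), 0)
  expect_equal(coopnet:::encouragement_prob(tab, 7, "DD", "delete"), 1)
  # CD-add declines linearly with mean 0.58
  cd_add <- sapply(1:15, function(t) coopnet:::encouragement_prob(tab, t, "CD", "add"))
  expect_equal(mean(cd_add), 0.58)
  expect_true(all(diff(cd_add) < 0))
  # beyond the table -> error
  st <- game_state(adj_path4(), round_t = 16L, last_action = c(1, 0, 1, 0))
  expect_error(recommend(planner_encouragement(tab), st), "does not cover round 16")
})

test_that("encouragement emission frequencies match the table", {
  # one existing CD edge observed many times in round 1 and round 15
  st1 <- game_state(adj_from_edges(2, c(1, 2)), round_t = 1L, last_action = c(1, 0))
  st15 <- game_state(adj_from_edges(2, c(1, 2)), round_t = 15L, last_action = c(1, 0))
  pl <- planner_encouragement()
  s <- coopnet:::rng_streams(6, 1)
  n_rep <- 1e4
  hits <- coopnet:::with_stream(s[[1]], {
    c(sum(replicate(n_rep, nrow(recommend(pl, st1)))),
      sum(replicate(n_rep, nrow(recommend(pl, st15)))))
  })
  ci1 <- stats::qbinom(c(5e-4, 1 - 5e-4), n_rep, 0.048)
  ci15 <- stats::qbinom(c(5e-4, 1 - 5e-4), n_rep, 0.722)
  expect_gte(hits[1], ci1[1]); expect_lte(hits[1], ci1[2])
  expect_gte(hits[2], ci15[1]); expect_lte(hits[2], ci15[2])
})

test_that("table round-trips through CSV", {
  tab <- default_encouragement_table(15)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  tab2 <- read_encouragement_table(f)
  expect_equal(coopnet:::encouragement_prob(tab2, 15, "CD", "delete"), 0.722)
})

test_that("neutral planner closes the density gap without reading choices", {
  # at target: no recommendations
  st <- game_state(adj_from_edges(4, c(1, 2, 3, 4)), last_action = c(1, 0, 1, 0))
  pl <- planner_neutral(rep(2 / 6, 15))
  expect_equal(rec_count(pl, st, 8), 0)
  # target density 1 from the empty graph: every pair recommended add
  st0 <- game_state(matrix(0L, 5, 5), last_action = rep(0L, 5))
  pl1 <- planner_neutral(rep(1, 15))
  s <- coopnet:::rng_streams(8, 1)
  recs <- coopnet:::with_stream(s[[1]], recommend(pl1, st0))
  expect_equal(nrow(recs), choose(5, 2))
  expect_true(all(recs$valence == "add"))
  # above target: deletions
  stc <- game_state(matrix(1L, 5, 5) - diag(5L), last_action = rep(1L, 5))
  pl0 <- planner_neutral(rep(0.5, 15))
  s2 <- coopnet:::rng_streams(9, 1)
  recs2 <- coopnet:::with_stream(s2[[1]], recommend(pl0, stc))
  expect_equal(nrow(recs2), 5)
  expect_true(all(recs2$valence == "delete"))
})

test_that("neutral planner recommendations are independent of pair class", {
  # chi-square on emission counts by pair class over many rounds
  cfg <- game_config(n_players = 12, n_rounds = 15)
  bots <- make_bots(bot_params(), 12, seed = 14)
  pl <- planner_neutral(seq(0.3, 0.7, length.out = 15))
  logs <- lapply(1:8, function(g) run_game(cfg, pl, make_bots(bot_params(), 12, g), g))
  bd <- recommendation_breakdown(logs)
  # class-independence holds within each valence (the add/delete split is
  # driven by the density gap, not by choices)
  for (v in c("add", "delete")) {
    sub <- bd[bd$valence == v & !is.na(bd$prob) & bd$chances > 30, ]
    tab <- cbind(sub$recs, sub$chances - sub$recs)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("max-density planner recommends the full complement and nothing else", {
  st0 <- game_state(matrix(0L, 16, 16), last_action = rep(0L, 16))
  recs <- recommend(planner_max_density(), st0)
  expect_equal(nrow(recs), 120)
  expect_true(all(recs$valence == "add"))
  stc <- game_state(matrix(1L, 6, 6) - diag(6L), last_action = rep(1L, 6))
  expect_equal(nrow(recommend(planner_max_density(), stc)), 0)
  # density never decreases under this planner with accepting players
  lg <- run_game(game_config(n_players = 8, n_rounds = 6),
                 planner_max_density(),
                 make_bots(bot_params(), 8, 3), seed = 9)
  dens <- sapply(lg$records, function(r) nrow(r$edges_after))
  expect_true(all(diff(dens) >= 0))
})

test_that("every planner emits valid, non-duplicated recommendations", {
  set.seed(99)
  planners <- list(planner_static(), planner_random(), planner_clustering(),
                   planner_max_density(), planner_encouragement(),
                   planner_neutral(runif(15)))
  for (rep in 1:15) {
    n <- sample(4:16, 1)
    st <- game_state(random_adjacency(n), round_t = sample(15, 1),
                     last_action = rbinom(n, 1, 0.5))
    for (pl in planners) {
      s <- coopnet:::rng_streams(rep * 100 + n, 1)
      recs <- coopnet:::with_stream(s[[1]], recommend(pl, st))
      expect_silent(coopnet:::validate_recommendations(recs, st))
    }
  }
})
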