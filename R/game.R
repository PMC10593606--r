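# Game engine: configuration, state, payoffs, recommendation resolution,
# and the turn loop.
#
# One round of the game runs through five phases:
#   act -> payoff -> planner recommends -> accept/reject -> rewire.
# The planner phase follows the action phase, so even in round 1 every
# player has a "most recent decision" the planner and the acceptance model
# can condition on.

#' Game configuration
#'
#' Parameters of the networked cooperation game. Defaults follow the group
#' experiments the package models: 16 players, 15 rounds, cooperation cost
#' c = 0.05 per linked neighbour and benefit b = 0.1 delivered to each
#' neighbour.
#'
#' @param n_players Number of players (>= 2).
#' @param n_rounds Number of rounds (>= 1).
#' @param cost Capital cost per linked neighbour paid by a cooperator each
#'   round (c > 0).
#' @param benefit Capital benefit per cooperating neighbour received each
#'   round (b > c, so mutual cooperation is net-positive).
#' @param initial_graph Starting topology. Either a list
#'   `list(generator = "gnp", p = 0.3)` (Erdős–Rényi G(n, p)),
#'   `list(generator = "empty")`, `list(generator = "complete")`, or
#'   `list(generator = "edges", edges = <2-column matrix>)`.
#' @param accept_rule_add `"both"` (default: link formation is bilateral —
#'   both endpoints must accept) or `"either"`.
#' @param accept_rule_delete `"either"` (default: severance is unilateral —
#'   one accepting endpoint suffices) or `"both"`.
#' @return An object of class `coop_config`.
#' @export
game_config <- function(n_players = 16L, n_rounds = 15L,
                        cost = 0.05, benefit = 0.1,
                        initial_graph = list(generator = "gnp", p = 0.3),
                        accept_rule_add = c("both", "either"),
                        accept_rule_delete = c("either", "both")) {
  assert_that(n_players >= 2, "n_players must be >= 2")
  assert_that(n_rounds >= 1, "n_rounds must be >= 1")
  assert_that(cost > 0, "cost must be positive")
  assert_that(benefit > cost, "benefit must exceed cost")
  structure(list(
    n_players = as.integer(n_players), n_rounds = as.integer(n_rounds),
    cost = cost, benefit = benefit, initial_graph = initial_graph,
    accept_rule_add = match.arg(accept_rule_add),
    accept_rule_delete = match.arg(accept_rule_delete)
  ), class = "coop_config")
}

#' @export
print.coop_config <- function(x, ...) {
  cat(sprintf("Cooperation game: %d players, %d rounds, c = %g, b = %g\n",
              x$n_players, x$n_rounds, x$cost, x$benefit))
  cat(sprintf("  initial graph: %s; add rule: %s accept; delete rule: %s accepts\n",
              x$initial_graph$generator %||% "custom",
              x$accept_rule_add, x$accept_rule_delete))
  invisible(x)
}

# build a simple symmetric 0/1 adjacency matrix from the config spec;
# uses the current RNG stream for stochastic generators
make_initial_adjacency <- function(n, spec) {
  gen <- spec$generator %||% "gnp"
  adj <- switch(gen,
    gnp = {
      g <- igraph::sample_gnp(n, spec$p %||% 0.3)
      as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    },
    empty = matrix(0, n, n),
    complete = matrix(1, n, n) - diag(n),
    edges = {
      a <- matrix(0, n, n)
      e <- spec$edges
      assert_that(is.matrix(e) && ncol(e) == 2, "edges must be a 2-column matrix")
      a[e] <- 1; a[e[, 2:1, drop = FALSE]] <- 1
      a
    },
    stop("unknown initial graph generator: ", gen)
  )
  diag(adj) <- 0
  storage.mode(adj) <- "integer"
  adj
}

#' Create a game state
#'
#' @param adjacency Simple symmetric 0/1 adjacency matrix (no self-loops).
#' @param round_t Current round index.
#' @param last_action Per-player most recent decision (1 = cooperate,
#'   0 = defect); `NA` before the first action phase resolves.
#' @param capital Per-player cumulative capital.
#' @return Object of class `coop_state`.
#' @export
game_state <- function(adjacency, round_t = 1L,
                       last_action = rep(NA_integer_, nrow(adjacency)),
                       capital = rep(0, nrow(adjacency))) {
  n <- nrow(adjacency)
  assert_that(is.matrix(adjacency) && ncol(adjacency) == n, "adjacency must be square")
  assert_that(all(diag(adjacency) == 0), "self-loops are precluded")
  assert_that(all(adjacency == t(adjacency)), "adjacency must be symmetric")
  assert_that(all(adjacency %in% c(0, 1)), "adjacency must be 0/1")
  assert_that(length(last_action) == n && length(capital) == n,
              "last_action and capital must have one entry per player")
  structure(list(round_t = as.integer(round_t),
                 adjacency = adjacency,
                 last_action = as.integer(last_action),
                 capital = as.numeric(capital)),
            class = "coop_state")
}

#' @export
print.coop_state <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("Game state: round %d, %d players, %d edges, %d cooperators\n",
              x$round_t, n, sum(x$adjacency) / 2,
              sum(x$last_action == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Per-round capital change from cooperation decisions
#'
#' A cooperator pays `cost` for each linked neighbour and every one of its
#' neighbours receives `benefit`; defectors pay nothing and confer nothing.
#'
#' @param state A `coop_state`.
#' @param actions Per-player 0/1 decisions for this round.
#' @param cost,benefit Game payoff parameters.
#' @return List with `state` (capital updated) and `delta`, the per-player
#'   capital change.
#' @export
payoff_phase <- function(state, actions, cost = 0.05, benefit = 0.1) {
  n <- nrow(state$adjacency)
  if (length(actions) != n || anyNA(actions)) {
    stop("contract violation: actions must be a complete 0/1 vector of length ", n)
  }
  actions <- as.integer(actions)
  assert_that(all(actions %in% c(0L, 1L)), "actions must be 0/1")
  deg <- rowSums(state$adjacency)
  coop_neigh <- as.numeric(state$adjacency %*% actions)
  delta <- -cost * deg * actions + benefit * coop_neigh
  state$capital <- state$capital + delta
  list(state = state, delta = delta)
}

#' Construct a set of edge-change recommendations
#'
#' @param i,j Player indices (unordered pairs; stored with i < j).
#' @param valence `"add"` or `"delete"` per pair.
#' @return A data frame with columns `i`, `j`, `valence`.
#' @export
recommendations <- function(i = integer(), j = integer(), valence = character()) {
  stopifnot(length(i) == length(j), length(j) == length(valence))
  lo <- pmin(i, j); hi <- pmax(i, j)
  assert_that(all(lo != hi) || length(i) == 0, "self-pair recommendation")
  structure(list(i = as.integer(lo), j = as.integer(hi),
                 valence = as.character(valence)),
            class = "data.frame",
            row.names = if (length(lo)) seq_along(lo) else integer())
}

# check the planner contract: known players, no duplicate pairs, valence
# consistent with the current edge state
validate_recommendations <- function(recs, state) {
  n <- nrow(state$adjacency)
  if (nrow(recs) == 0) return(invisible(recs))
  bad <- recs$i < 1 | recs$j > n | recs$i >= recs$j
  if (any(bad)) {
    stop(sprintf("recommendation references invalid pair (%d, %d)",
                 recs$i[which(bad)[1]], recs$j[which(bad)[1]]))
  }
  key <- paste(recs$i, recs$j)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate recommendation for pair (", gsub(" ", ", ", d), ")")
  }
  exists <- state$adjacency[cbind(recs$i, recs$j)] == 1
  wrong_add <- recs$valence == "add" & exists
  wrong_del <- recs$valence == "delete" & !exists
  if (any(wrong_add | wrong_del)) {
    k <- which(wrong_add | wrong_del)[1]
    stop(sprintf("recommendation valence '%s' inconsistent with edge state for pair (%d, %d)",
                 recs$valence[k], recs$i[k], recs$j[k]))
  }
  invisible(recs)
}

#' Apply accept/reject decisions to a set of recommendations
#'
#' By default link formation is bilateral (an `add` executes only if both
#' endpoints accept) while severance is unilateral (a `delete` executes if
#' at least one endpoint accepts); both rules are configurable.
#'
#' @param state A `coop_state` whose graph the recommendations refer to.
#' @param recs Recommendation data frame (see [recommendations()]).
#' @param decisions Logical matrix with one row per recommendation and
#'   columns `accept_i`, `accept_j`.
#' @param rule_add,rule_delete `"both"` or `"either"`.
#' @return List with `state` (rewired graph) and `changes`, the per-pair
#'   log of executed/unexecuted changes.
#' @export
resolve_recommendations <- function(state, recs, decisions,
                                    rule_add = "both", rule_delete = "either") {
  validate_recommendations(recs, state)
  if (nrow(recs) == 0) {
    return(list(state = state,
                changes = data.frame(i = integer(), j = integer(),
                                     valence = character(), accept_i = logical(),
                                     accept_j = logical(), executed = logical())))
  }
  decisions <- matrix(as.logical(decisions), nrow = nrow(recs))
  assert_that(ncol(decisions) == 2, "decisions must have accept_i, accept_j columns")
  both <- decisions[, 1] & decisions[, 2]
  either <- decisions[, 1] | decisions[, 2]
  exec_add <- if (rule_add == "both") both else either
  exec_del <- if (rule_delete == "both") both else either
  is_add <- recs$valence == "add"
  executed <- exec_del
  executed[is_add] <- exec_add[is_add]
  adj <- state$adjacency
  idx <- cbind(recs$i, recs$j)
  newval <- rep(0L, nrow(recs))
  newval[is_add] <- 1L
  hit <- which(executed)
  if (length(hit)) {
    adj[idx[hit, , drop = FALSE]] <- newval[hit]
    adj[idx[hit, c(2, 1), drop = FALSE]] <- newval[hit]
  }
  state$adjacency <- adj
  list(state = state,
       changes = data.frame(i = recs$i, j = recs$j, valence = recs$valence,
                            accept_i = decisions[, 1], accept_j = decisions[, 2],
                            executed = executed))
}

# ---- population contract --------------------------------------------------
# A "population" stands in for the human group: either a bot population
# (see bots.R) or a scripted fixture (see experiments.R). The engine talks
# to it through three generics.

#' @export
population_size <- function(population) UseMethod("population_size")

# returns a runtime object (per-game RNG streams etc.) derived from the seed
#' @export
population_init <- function(population, seed) UseMethod("population_init")

# per-player 0/1 actions for the current round
#' @export
population_actions <- function(population, runtime, state) {
  UseMethod("population_actions")
}

# logical matrix (accept_i, accept_j), one row per recommendation
#' @export
population_accepts <- function(population, runtime, recs, state) {
  UseMethod("population_accepts")
}

#' Planner contract: map an observed game state to recommendations
#'
#' Every planner implements this generic. The engine installs the planner's
#' own RNG substream before calling it, so stochastic planners simply use
#' `runif()`/`sample()`.
#'
#' @param planner A planner object (see `planner_*` constructors).
#' @param state The current `coop_state` (its `last_action` holds this
#'   round's decisions).
#' @param ... Unused.
#' @return A recommendation data frame.
#' @export
recommend <- function(planner, state, ...) UseMethod("recommend")

#' Run one full game
#'
#' Executes `n_rounds` of the act/payoff/recommend/accept/rewire loop.
#' The whole game is a pure function of `(config, planner, population, seed)`:
#' identical inputs give identical logs.
#'
#' @param config A [game_config()].
#' @param planner A planner object implementing [recommend()].
#' @param population A bot population ([make_bots()]) or scripted fixture
#'   ([make_fixture()]).
#' @param seed Integer seed controlling every random draw in the game.
#' @return Object of class `coop_log`: a list with `config`, `initial_edges`
#'   and `records` (one per round, schema documented in [write_game_log()]).
#' @export
run_game <- function(config, planner, population, seed) {
  assert_that(inherits(config, "coop_config"), "config must be a coop_config")
  n <- config$n_players
  assert_that(population_size(population) == n,
              "population size must equal n_players")
  streams <- rng_streams(seed, 2L)     # 1: engine (initial graph), 2: planner
  pop_rt <- population_init(population, seed)

  adj <- with_stream(streams[[1]], make_initial_adjacency(n, config$initial_graph))
  state <- game_state(adj)
  initial_edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)

  records <- vector("list", config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    state$round_t <- t
    actions <- population_actions(population, pop_rt, state)
    pay <- payoff_phase(state, actions, config$cost, config$benefit)
    state <- pay$state
    # conservation check: total delta = (b - c) * sum over cooperators of degree
    expected <- (config$benefit - config$cost) *
      sum(rowSums(state$adjacency) * actions)
    assert_that(abs(sum(pay$delta) - expected) < 1e-9,
                "internal error: payoff conservation violated")
    state$last_action <- as.integer(actions)

    recs <- with_stream(streams[[2]], recommend(planner, state))
    validate_recommendations(recs, state)
    decisions <- population_accepts(population, pop_rt, recs, state)
    res <- resolve_recommendations(state, recs, decisions,
                                   config$accept_rule_add,
                                   config$accept_rule_delete)
    edges_before <- state$adjacency
    state <- res$state
    assert_that(all(diag(state$adjacency) == 0) &&
                  all(state$adjacency == t(state$adjacency)),
                "internal error: graph no longer simple")

    records[[t]] <- list(
      round_t = t,
      actions = as.integer(actions),
      payoffs = pay$delta,
      capital = state$capital,
      recs = res$changes,
      edges_after = which(upper.tri(state$adjacency) & state$adjacency == 1,
                          arr.ind = TRUE)
    )
  }
  structure(list(config = config, seed = seed,
                 initial_edges = initial_edges, records = records),
            class = "coop_log")
}

#' @export
print.coop_log <- function(x, ...) {
  tr <- vapply(x$records, function(r) mean(r$actions), numeric(1))
  cat(sprintf("Game log: %d players, %d rounds (seed %s)\n",
              x$config$n_players, length(x$records), format(x$seed)))
  cat(sprintf("  cooperation: %.2f (round 1) -> %.2f (round %d)\n",
              tr[1], tr[length(tr)], length(tr)))
  invisible(x)
}
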