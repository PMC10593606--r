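# Campaign orchestration: seeded multi-group simulations per condition,
# scripted fixtures, and config loading.

#' Scripted player fixture
#'
#' Replaces bot sampling with a fully deterministic script: a per-player,
#' per-round action matrix and an acceptance policy.
#'
#' @param actions `n_players x n_rounds` 0/1 matrix of cooperate/defect
#'   decisions.
#' @param accept `"all"`, `"none"`, or a function
#'   `(player, valence, referent_action, round) -> logical` applied per
#'   endpoint decision.
#' @return Object of class `coop_fixture` usable wherever a bot population
#'   is.
#' @export
make_fixture <- function(actions, accept = "all") {
  assert_that(is.matrix(actions), "actions must be a matrix (players x rounds)")
  if (anyNA(actions)) {
    bad <- which(is.na(actions), arr.ind = TRUE)[1, ]
    stop(sprintf("fixture script incomplete: player %d, round %d is missing",
                 bad[1], bad[2]))
  }
  assert_that(all(actions %in% c(0, 1)), "fixture actions must be 0/1")
  if (is.character(accept)) {
    assert_that(accept %in% c("all", "none"), "accept must be all/none or a function")
  }
  structure(list(actions = actions, accept = accept,
                 n = nrow(actions), n_rounds = ncol(actions)),
            class = "coop_fixture")
}

#' @export
population_size.coop_fixture <- function(population) population$n

#' @export
population_init.coop_fixture <- function(population, seed) list()

#' @export
population_actions.coop_fixture <- function(population, runtime, state) {
  t <- state$round_t
  assert_that(t <= population$n_rounds,
              sprintf("fixture script incomplete: no actions for round %d", t))
  as.integer(population$actions[, t])
}

#' @export
population_accepts.coop_fixture <- function(population, runtime, recs, state) {
  m <- nrow(recs)
  if (m == 0) return(matrix(logical(0), 0, 2))
  if (identical(population$accept, "all")) return(matrix(TRUE, m, 2))
  if (identical(population$accept, "none")) return(matrix(FALSE, m, 2))
  f <- population$accept
  t <- state$round_t
  cbind(mapply(f, recs$i, recs$valence, state$last_action[recs$j], t),
        mapply(f, recs$j, recs$valence, state$last_action[recs$i], t))
}

#' Campaign specification
#'
#' A campaign is `n_groups` independent games of one condition. Group `g`
#' runs with seed `base_seed + g`, and — because bot dispositions are drawn
#' from the group seed — campaigns of different conditions sharing a
#' `base_seed` play against identical bot populations (paired comparisons).
#'
#' @param condition One of `"static"`, `"random"`, `"clustering"`,
#'   `"encouragement"`, `"neutral"`, `"max_density"`, `"graphnet"`.
#' @param n_groups Number of groups.
#' @param game_cfg A [game_config()].
#' @param params_bots A [bot_params()].
#' @param planner_args Extra arguments for the condition's planner
#'   constructor (e.g. `list(density_schedule = ...)` for `"neutral"`,
#'   `list(params = ..., n_rounds = ...)` for `"graphnet"`).
#' @param base_seed Integer base seed.
#' @return Object of class `coop_campaign`.
#' @export
campaign <- function(condition, n_groups, game_cfg = game_config(),
                     params_bots = bot_params(), planner_args = list(),
                     base_seed = 1L) {
  valid <- c("static", "random", "clustering", "encouragement", "neutral",
             "max_density", "graphnet")
  if (!condition %in% valid) {
    stop("unknown condition '", condition, "'; valid conditions: ",
         paste(valid, collapse = ", "))
  }
  structure(list(condition = condition, n_groups = as.integer(n_groups),
                 game_cfg = game_cfg, params_bots = params_bots,
                 planner_args = planner_args,
                 base_seed = as.integer(base_seed)),
            class = "coop_campaign")
}

campaign_planner <- function(camp) {
  ctor <- switch(camp$condition,
                 static = planner_static, random = planner_random,
                 clustering = planner_clustering,
                 encouragement = planner_encouragement,
                 neutral = planner_neutral, max_density = planner_max_density,
                 graphnet = planner_graphnet)
  do.call(ctor, camp$planner_args)
}

#' Run a simulation campaign
#'
#' Simulates every group sequentially and (optionally) writes one JSONL log
#' per group plus a campaign-level summary CSV into `out_dir/<condition>/`.
#'
#' @param camp A [campaign()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `logs` (per-group `coop_log`s) and `summary` (data
#'   frame: round, mean/sd cooperation across groups).
#' @export
run_campaign <- function(camp, out_dir = NULL) {
  planner <- campaign_planner(camp)
  logs <- vector("list", camp$n_groups)
  for (g in seq_len(camp$n_groups)) {
    seed <- camp$base_seed + g
    bots <- make_bots(camp$params_bots, camp$game_cfg$n_players, seed)
    logs[[g]] <- run_game(camp$game_cfg, planner, bots, seed)
  }
  tr <- sapply(logs, cooperation_rate)
  summary <- data.frame(round = seq_len(camp$game_cfg$n_rounds),
                        mean_cooperation = rowMeans(as.matrix(tr)),
                        sd_cooperation = apply(as.matrix(tr), 1, stats::sd))
  if (!is.null(out_dir)) {
    dir <- file.path(out_dir, camp$condition)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in seq_len(camp$n_groups)) {
      write_game_log(logs[[g]], file.path(dir, sprintf("group_%02d.jsonl", g)))
    }
    utils::write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  }
  list(logs = logs, summary = summary, condition = camp$condition)
}

#' Paired permutation test of final-round cooperation between conditions
#'
#' Compares two campaigns run with a shared base seed (hence identical bot
#' populations per group): the statistic is the mean within-pair difference
#' in final-round cooperation, and sign-flip permutations give the p-value.
#'
#' @param logs_a,logs_b Lists of `coop_log`s, paired by position.
#' @param n_perm Number of sign permutations.
#' @param seed Integer seed.
#' @return List with `diff` (mean a - b), `p_value` (one-sided, a > b).
#' @export
paired_final_round_test <- function(logs_a, logs_b, n_perm = 10000L, seed = 1L) {
  assert_that(length(logs_a) == length(logs_b), "campaigns must be paired")
  Tt <- length(logs_a[[1]]$records)
  fa <- vapply(logs_a, cooperation_rate, numeric(1), round = Tt)
  fb <- vapply(logs_b, cooperation_rate, numeric(1), round = Tt)
  d <- fa - fb
  obs <- mean(d)
  s <- rng_streams(seed, 1L)
  p <- with_stream(s[[1]], {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), length(d), replace = TRUE)
      if (mean(flip * d) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(diff = obs, p_value = p)
}

#' Digest of a campaign's logs
#'
#' A reproducibility fingerprint: the campaign is a pure function of its
#' specification, so re-running it must reproduce this digest exactly.
#'
#' @param logs List of `coop_log`s.
#' @return A character checksum.
#' @export
campaign_digest <- function(logs) {
  txt <- vapply(logs, function(lg) {
    paste(vapply(lg$records, function(r) {
      paste(c(r$actions, format(r$capital, digits = 12), t(r$edges_after)),
            collapse = ",")
    }, character(1)), collapse = ";")
  }, character(1))
  x <- utf8ToInt(paste(txt, collapse = "|"))
  # simple 31-bit polynomial rolling hash
  h <- 0
  for (ch in x) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Load a config file
#'
#' Reads a YAML or JSON configuration with optional `game`, `bots`,
#' `training` sections into the corresponding parameter objects.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return List with any of `game` ([game_config()]), `bots`
#'   ([bot_params()]), `training` ([a2c_config()]).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  if (!is.null(raw$game)) out$game <- do.call(game_config, raw$game)
  if (!is.null(raw$bots)) out$bots <- do.call(bot_params, raw$bots)
  if (!is.null(raw$training)) out$training <- do.call(a2c_config, raw$training)
  out
}
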