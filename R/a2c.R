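# Advantage actor-critic training of the graph-network planner against
# simulated bot groups.

#' Training configuration for the graph-network planner
#'
#' Defaults are desk-scale: a reduced-width network and a 2e5-round budget
#' that trains in minutes on one core. The paper-scale ceiling (5e7 rounds)
#' is accepted but impractically slow in this implementation.
#'
#' @param discount Return discount factor in (0, 1].
#' @param n_step Return horizon; `Inf` (default) bootstraps nothing and
#'   uses full-episode discounted returns (episodes are short).
#' @param value_weight Critic loss weight.
#' @param entropy_weight Entropy-bonus weight.
#' @param lr Adam learning rate.
#' @param lambda Reward mixing weight on recommendation quality (the
#'   fraction of issued recommendations that execute); the other reward
#'   component is the mean per-player capital gain of the round.
#' @param adv_norm Normalize advantages to zero mean / unit variance within
#'   each update batch (variance reduction for the factorized policy).
#' @param batch_episodes Episodes accumulated into each gradient update;
#'   averaging across groups reduces policy-gradient noise at the cost of
#'   fewer optimizer steps.
#' @param budget_rounds Total simulated game rounds to train for.
#' @param width,hidden Graph-network latent and hidden widths.
#' @param seed Replicate seed (weight init + all simulation randomness).
#' @return Object of class `a2c_config`.
#' @export
a2c_config <- function(discount = 0.99, n_step = Inf, value_weight = 0.5,
                       entropy_weight = 0.003, lr = 5e-3, lambda = 0.1,
                       adv_norm = TRUE, batch_episodes = 10L,
                       budget_rounds = 2e5,
                       width = 16L, hidden = 16L, seed = 1L) {
  assert_that(discount > 0 && discount <= 1, "discount must be in (0, 1]")
  assert_that(budget_rounds <= 5e7, "budget exceeds the 5e7-round ceiling")
  structure(list(discount = discount, n_step = n_step,
                 value_weight = value_weight, entropy_weight = entropy_weight,
                 lr = lr, lambda = lambda, adv_norm = isTRUE(adv_norm),
                 batch_episodes = as.integer(batch_episodes),
                 budget_rounds = budget_rounds,
                 width = as.integer(width), hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "a2c_config")
}

#' Planner reward for one game round
#'
#' `reward = mean per-player capital gain + lambda * fraction of issued
#' recommendations that executed` (the second term is 0 when no
#' recommendations were issued).
#'
#' @param before,after `coop_state` before and after the round's payoff.
#' @param recs Recommendations issued this round.
#' @param executed Logical vector: which recommendations executed.
#' @param lambda Mixing weight.
#' @return Scalar reward.
#' @export
compute_reward <- function(before, after, recs, executed, lambda = 0.1) {
  n <- length(before$capital)
  gain <- (sum(after$capital) - sum(before$capital)) / n
  quality <- if (nrow(recs) > 0) mean(executed) else 0
  gain + lambda * quality
}

# ---- Adam on the flattened parameter vector -------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

# eps is deliberately large: near a saturated policy the gradients shrink
# towards zero, and a small eps would let the 1/sqrt(v) rescaling amplify
# residual noise into a random walk of the logits
adam_step <- function(opt, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-4) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, delta = -lr * mhat / (sqrt(vhat) + eps))
}

# discounted returns; with horizon h < length, bootstrap from the value
a2c_returns <- function(rewards, values, discount, n_step) {
  Tt <- length(rewards)
  R <- numeric(Tt)
  if (is.finite(n_step) && n_step < Tt) {
    for (t in seq_len(Tt)) {
      h <- min(n_step, Tt - t + 1)
      R[t] <- sum(discount^(0:(h - 1)) * rewards[t:(t + h - 1)])
      if (t + h <= Tt) R[t] <- R[t] + discount^h * values[t + h]
    }
  } else {
    acc <- 0
    for (t in rev(seq_len(Tt))) {
      acc <- rewards[t] + discount * acc
      R[t] <- acc
    }
  }
  R
}

#' One advantage actor-critic gradient step
#'
#' Takes a batch of transitions (one episode, or any stack of rounds on the
#' same player count), computes
#' `L = -sum_t A_t * log pi(a_t | s_t) + c_v * sum_t (R_t - v_t)^2 -
#' c_e * sum_t H(pi(. | s_t))` with `A_t = R_t - v_t` held fixed, and
#' applies one Adam update.
#'
#' @param params `graphnet_params`.
#' @param transitions List with `obs` (list of `graph_obs`), `mask`
#'   (matrix, rounds x pairs, the 0/1 emissions sampled), `rewards`
#'   (numeric vector), and optionally `episode` (integer vector marking
#'   episode boundaries; returns never propagate across episodes).
#' @param config An [a2c_config()].
#' @param opt Adam state from a previous call, or `NULL`.
#' @return List with updated `params`, `opt`, and `diagnostics` (policy
#'   loss, value loss, entropy, mean return).
#' @export
a2c_update <- function(params, transitions, config, opt = NULL) {
  obs <- transitions$obs
  Tt <- length(obs)
  assert_that(Tt > 0, "empty transition batch")
  fwd <- graphnet_forward(params, obs, keep_cache = TRUE)
  P <- ncol(fwd$logits)
  lvec <- fwd$cache$logit_vec
  pvec <- logistic(lvec)
  mask <- as.numeric(t(transitions$mask))      # batch pair order (round-major)

  ep <- transitions$episode %||% rep(1L, Tt)
  R <- numeric(Tt)
  for (e in unique(ep)) {
    rows <- which(ep == e)
    R[rows] <- a2c_returns(transitions$rewards[rows], fwd$value[rows],
                           config$discount, config$n_step)
  }
  adv <- R - fwd$value
  if (isTRUE(config$adv_norm) && Tt > 1 && stats::sd(adv) > 1e-8) {
    adv <- (adv - mean(adv)) / stats::sd(adv)
  }
  adv_pair <- rep(adv, each = P)

  # d/dlogit of: -A*log pi(a)  ->  -A * (a - pi)
  #              -c_e * H(pi)  ->  c_e * logit * pi * (1 - pi)
  dlog <- (-adv_pair * (mask - pvec) +
             config$entropy_weight * lvec * pvec * (1 - pvec)) / Tt
  dval <- (-2 * config$value_weight * (R - fwd$value)) / Tt
  grads <- graphnet_backward(params, fwd$cache, dlog, dval)

  gvec <- unlist(grads, use.names = FALSE)
  if (any(!is.finite(gvec))) {
    stop("non-finite loss gradient in a2c_update; diagnostics: mean |adv| = ",
         format(mean(abs(adv))))
  }
  if (is.null(opt)) opt <- adam_init(length(gvec))
  st <- adam_step(opt, gvec, config$lr)
  params <- unflatten_params(params, flatten_params(params) + st$delta)

  logp <- stats::plogis((2 * mask - 1) * lvec, log.p = TRUE)
  ent <- -(pvec * log(pmax(pvec, 1e-12)) +
             (1 - pvec) * log(pmax(1 - pvec, 1e-12)))
  list(params = params, opt = st$opt,
       diagnostics = c(policy_loss = -sum(adv_pair * logp) / Tt,
                       value_loss = config$value_weight * sum((R - fwd$value)^2) / Tt,
                       entropy = sum(ent) / Tt,
                       mean_return = mean(R)))
}

# play one training episode against bots, collecting transitions; uses the
# current RNG stream for everything (bot draws included)
play_episode_collect <- function(params, game_cfg, bots, lambda) {
  n <- game_cfg$n_players
  adj <- make_initial_adjacency(n, game_cfg$initial_graph)
  state <- game_state(adj)
  # lightweight inline bot runtime: one shared stream (training-internal)
  obs_l <- list(); mask_m <- NULL
  rewards <- numeric(game_cfg$n_rounds)
  coop <- numeric(game_cfg$n_rounds)
  for (t in seq_len(game_cfg$n_rounds)) {
    state$round_t <- t
    p <- cooperate_prob(bots, state)
    actions <- as.integer(stats::runif(n) < p)
    before <- state
    pay <- payoff_phase(state, actions, game_cfg$cost, game_cfg$benefit)
    state <- pay$state
    state$last_action <- actions
    obs <- encode_observation(state, game_cfg$n_rounds)
    fwd <- graphnet_forward(params, obs)
    act <- sample_action(fwd$logits[1, ], state)
    recs <- act$recs
    if (nrow(recs)) {
      p_i <- accept_prob(bots$params, recs$valence, state$last_action[recs$j])
      p_j <- accept_prob(bots$params, recs$valence, state$last_action[recs$i])
      dec <- cbind(stats::runif(nrow(recs)) < p_i, stats::runif(nrow(recs)) < p_j)
    } else dec <- matrix(logical(0), 0, 2)
    res <- resolve_recommendations(state, recs, dec,
                                   game_cfg$accept_rule_add,
                                   game_cfg$accept_rule_delete)
    state <- res$state
    rewards[t] <- compute_reward(before, state, recs, res$changes$executed, lambda)
    obs_l[[t]] <- obs
    mask_m <- rbind(mask_m, act$mask)
    coop[t] <- mean(actions)
  }
  list(obs = obs_l, mask = mask_m, rewards = rewards, coop = coop)
}

#' Train the graph-network planner against simulated groups
#'
#' Repeatedly plays full games as the social planner against freshly
#' sampled bot groups, applying one actor-critic update per episode. Fully
#' seeded: two runs with the same configuration produce identical learning
#' curves.
#'
#' @param config An [a2c_config()].
#' @param game_cfg A [game_config()].
#' @param params_bots A [bot_params()] object describing the simulated
#'   humans.
#' @param verbose Print progress every `verbose` episodes (0 = silent).
#' @return Object of class `a2c_fit`: list with trained `params`, the
#'   per-episode `curve` (data frame: episode, mean cooperation, losses),
#'   and the configs.
#' @export
train_agent <- function(config, game_cfg = game_config(),
                        params_bots = bot_params(), verbose = 0) {
  params <- init_graphnet(config$width, config$hidden, seed = config$seed)
  n_episodes <- floor(config$budget_rounds / game_cfg$n_rounds)
  curve <- NULL
  if (n_episodes >= 1) {
    s <- rng_streams(config$seed, 1L)
    opt <- NULL
    curve <- matrix(NA_real_, n_episodes, 5,
                    dimnames = list(NULL, c("episode", "coop", "policy_loss",
                                            "value_loss", "entropy")))
    batch <- NULL
    with_stream(s[[1]], {
      for (ep in seq_len(n_episodes)) {
        bots <- structure(list(params = params_bots,
                               theta = stats::rnorm(game_cfg$n_players,
                                                    params_bots$mu_theta,
                                                    params_bots$sigma_theta),
                               n = game_cfg$n_players),
                          class = "coop_bots")
        tr <- play_episode_collect(params, game_cfg, bots, config$lambda)
        tr$episode <- rep(ep, length(tr$rewards))
        batch <- if (is.null(batch)) tr else {
          list(obs = c(batch$obs, tr$obs), mask = rbind(batch$mask, tr$mask),
               rewards = c(batch$rewards, tr$rewards),
               episode = c(batch$episode, tr$episode), coop = tr$coop)
        }
        diag <- c(policy_loss = NA_real_, value_loss = NA_real_,
                  entropy = NA_real_)
        if (ep %% config$batch_episodes == 0 || ep == n_episodes) {
          upd <- tryCatch(a2c_update(params, batch, config, opt),
                          error = function(e) e)
          if (inherits(upd, "error")) {
            warning("training halted at episode ", ep, ": ",
                    conditionMessage(upd), "; keeping last good parameters")
            curve <- curve[seq_len(ep - 1), , drop = FALSE]
            break
          }
          params <- upd$params; opt <- upd$opt
          diag <- upd$diagnostics[1:3]
          batch <- NULL
        }
        curve[ep, ] <- c(ep, mean(tr$coop), diag)
        if (verbose > 0 && ep %% verbose == 0) {
          cat(sprintf("episode %d: coop %.3f\n", ep, mean(tr$coop)))
        }
      }
    })
  }
  structure(list(params = params, curve = as.data.frame(curve),
                 config = config, game_config = game_cfg,
                 bot_params = params_bots),
            class = "a2c_fit")
}

#' @export
print.a2c_fit <- function(x, ...) {
  ne <- nrow(x$curve) %||% 0
  cat(sprintf("Trained graph-network planner: %d episodes (width %d)\n",
              if (is.null(ne)) 0 else ne, x$config$width))
  if (!is.null(ne) && ne > 1) {
    k <- max(1, ne - 49)
    cat(sprintf("  mean cooperation, last 50 episodes: %.3f\n",
                mean(x$curve$coop[k:ne])))
  }
  invisible(x)
}

#' Write a learning curve to CSV
#'
#' @param fit An `a2c_fit`.
#' @param path Output CSV path.
#' @export
write_learning_curve <- function(fit, path) {
  utils::write.csv(fit$curve, path, row.names = FALSE)
  invisible(path)
}
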