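# Simulated players ("bots"): a disposition-heterogeneous logistic model of
# the cooperate/defect choice plus a valence-conditional acceptance table.
#
# Each bot i draws a fixed cooperative disposition theta_i ~ N(mu_theta,
# sigma_theta) at creation. In round 1 it cooperates with probability
# logistic(beta0p + beta1p * theta_i); in later rounds with probability
# logistic(beta0 + beta1*x_s + beta2*x_n + beta3*x_r + theta_i), where x_s is
# its degree, x_n its number of neighbours who cooperated last round, and
# x_r = x_n / x_s the neighbourhood cooperation rate (0 for isolates).
# Recommendations are accepted with probability phi0..phi3 indexed by
# (valence, referent's last action).

#' Bot model parameters
#'
#' The default values are NOT fitted to human data; they are calibrated by
#' simulation so that static-network games show the canonical signature of
#' group cooperation experiments: roughly 70% cooperation in round 1
#' declining towards roughly 43% by round 15 (see the methods vignette).
#'
#' @param mu_theta,sigma_theta Mean and s.d. of the Gaussian disposition.
#' @param beta0p,beta1p Round-1 logistic coefficients (intercept, loading on
#'   the disposition).
#' @param beta0,beta1,beta2,beta3 Later-round coefficients on the intercept,
#'   neighbourhood size `x_s`, cooperating-neighbour count `x_n`, and
#'   neighbourhood cooperation rate `x_r`.
#' @param phi Length-4 acceptance-probability table, in order
#'   (break, defector), (break, cooperator), (make, defector),
#'   (make, cooperator).
#' @return Object of class `bot_params`.
#' @export
bot_params <- function(mu_theta = 0, sigma_theta = 1,
                       beta0p = 1.0, beta1p = 1,
                       beta0 = -1.3, beta1 = -0.03, beta2 = 0.05, beta3 = 2.1,
                       phi = c(0.85, 0.55, 0.50, 0.90)) {
  assert_that(sigma_theta > 0, "sigma_theta must be positive")
  assert_that(length(phi) == 4 && all(phi >= 0 & phi <= 1),
              "phi must be four probabilities")
  structure(list(mu_theta = mu_theta, sigma_theta = sigma_theta,
                 beta0p = beta0p, beta1p = beta1p,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 phi = as.numeric(phi)),
            class = "bot_params")
}

#' @export
print.bot_params <- function(x, ...) {
  cat("Bot parameters (logistic choice + acceptance table)\n")
  cat(sprintf("  theta ~ N(%.3g, %.3g^2)\n", x$mu_theta, x$sigma_theta))
  cat(sprintf("  round 1: logit p = %.3g + %.3g * theta\n", x$beta0p, x$beta1p))
  cat(sprintf("  round >1: logit p = %.3g + %.3g*x_s + %.3g*x_n + %.3g*x_r + theta\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  accept phi (break/def, break/coop, make/def, make/coop): %s\n",
              paste(format(x$phi), collapse = ", ")))
  invisible(x)
}

#' Create a bot population
#'
#' Disposition draws are fixed at creation (seeded), so the same
#' `(params, n, seed)` triple gives the same population under any planner —
#' the basis for paired cross-condition comparisons.
#'
#' @param params A [bot_params()] object.
#' @param n Number of bots.
#' @param seed Integer seed for the disposition draws.
#' @return Object of class `coop_bots`.
#' @export
make_bots <- function(params, n, seed) {
  assert_that(inherits(params, "bot_params"), "params must be bot_params")
  s <- rng_streams(seed, 1L)
  theta <- with_stream(s[[1]],
                       stats::rnorm(n, params$mu_theta, params$sigma_theta))
  structure(list(params = params, theta = theta, n = as.integer(n)),
            class = "coop_bots")
}

#' Cooperation probability of each bot in a state
#'
#' Evaluates the two-branch logistic choice model for every bot. The
#' neighbourhood covariates are read from `state$adjacency` and
#' `state$last_action` (the previous round's decisions); `state$round_t`
#' selects the branch.
#'
#' @param bots A `coop_bots` population.
#' @param state A `coop_state`.
#' @return Numeric vector of cooperation probabilities.
#' @export
cooperate_prob <- function(bots, state) {
  p <- bots$params
  if (state$round_t == 1L) {
    logistic(p$beta0p + p$beta1p * bots$theta)
  } else {
    xs <- rowSums(state$adjacency)
    last <- as.integer(state$last_action == 1L)
    xn <- as.numeric(state$adjacency %*% last)
    xr <- ifelse(xs > 0, xn / xs, 0)   # isolates: x_r defined as 0
    logistic(p$beta0 + p$beta1 * xs + p$beta2 * xn + p$beta3 * xr + bots$theta)
  }
}

#' Acceptance probability for a recommendation
#'
#' Pure table lookup on (valence, referent's most recent decision):
#' phi0 = (break, defector), phi1 = (break, cooperator),
#' phi2 = (make, defector), phi3 = (make, cooperator).
#'
#' @param params A [bot_params()] object (or a `coop_bots` population, whose
#'   shared parameters are used — acceptance does not depend on the
#'   disposition).
#' @param valence `"add"` or `"delete"`, vectorised.
#' @param referent_last_action 0/1 most recent decision of the
#'   recommendation's other endpoint, vectorised.
#' @return Numeric vector of acceptance probabilities.
#' @export
accept_prob <- function(params, valence, referent_last_action) {
  if (inherits(params, "coop_bots")) params <- params$params
  assert_that(all(valence %in% c("add", "delete")), "valence must be add/delete")
  assert_that(!anyNA(referent_last_action),
              "referent last action undefined (planner phase precedes actions?)")
  idx <- 1L + 2L * (valence == "add") + as.integer(referent_last_action)
  params$phi[idx]
}

# ---- population contract methods ------------------------------------------

#' @export
population_size.coop_bots <- function(population) population$n

#' @export
population_init.coop_bots <- function(population, seed) {
  # one decision substream per bot, decoupled from the engine/planner streams
  list(streams = rng_streams(seed, population$n + 2L)[-(1:2)])
}

#' @export
population_actions.coop_bots <- function(population, runtime, state) {
  p <- cooperate_prob(population, state)
  n <- population$n
  acts <- integer(n)
  for (i in seq_len(n)) {
    u <- with_stream(runtime$streams[[i]], stats::runif(1))
    acts[i] <- as.integer(u < p[i])
  }
  acts
}

#' @export
population_accepts.coop_bots <- function(population, runtime, recs, state) {
  m <- nrow(recs)
  if (m == 0) return(matrix(logical(0), 0, 2))
  dec <- matrix(FALSE, m, 2)
  # endpoint i judges referent j and vice versa; each bot consumes its own
  # stream in recommendation order so draws are planner-independent
  p_i <- accept_prob(population$params, recs$valence, state$last_action[recs$j])
  p_j <- accept_prob(population$params, recs$valence, state$last_action[recs$i])
  for (b in unique(c(recs$i, recs$j))) {
    rows_i <- which(recs$i == b)
    rows_j <- which(recs$j == b)
    k <- length(rows_i) + length(rows_j)
    u <- with_stream(runtime$streams[[b]], stats::runif(k))
    if (length(rows_i)) dec[rows_i, 1] <- u[seq_along(rows_i)] < p_i[rows_i]
    if (length(rows_j)) dec[rows_j, 2] <- u[length(rows_i) + seq_along(rows_j)] < p_j[rows_j]
  }
  dec
}
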