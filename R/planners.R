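# Rule-based social planners. All planners implement the `recommend()`
# generic and emit at most one valid recommendation per pair per round.

# classify every canonical pair by edge state and endpoint decisions
state_pairs <- function(state) {
  n <- nrow(state$adjacency)
  pp <- player_pairs(n)
  exists <- state$adjacency[pp] == 1L
  a_i <- state$last_action[pp[, 1]]
  a_j <- state$last_action[pp[, 2]]
  cls <- ifelse(a_i + a_j == 2L, "CC", ifelse(a_i + a_j == 1L, "CD", "DD"))
  list(pairs = pp, exists = exists, class = cls,
       valence = ifelse(exists, "delete", "add"))
}

new_planner <- function(name, ..., subclass) {
  structure(list(name = name, ...), class = c(subclass, "coop_planner"))
}

#' @export
print.coop_planner <- function(x, ...) {
  cat(sprintf("Social planner: %s\n", x$name)); invisible(x)
}

#' Static planner: never recommends any change
#'
#' @return A planner object.
#' @export
planner_static <- function() new_planner("static", subclass = "planner_static")

#' @export
recommend.planner_static <- function(planner, state, ...) recommendations()

#' Random-rewiring planner
#'
#' Each turn, samples `round(frac * choose(n, 2))` distinct candidate pairs
#' uniformly without replacement and recommends toggling each: add if the
#' pair is unlinked, delete if linked. The canonical experimental setting is
#' `frac = 0.30` of the possible edges.
#'
#' @param frac Fraction of possible edges to sample each turn.
#' @return A planner object.
#' @export
planner_random <- function(frac = 0.30) {
  assert_that(frac >= 0 && frac <= 1, "frac must be in [0, 1]")
  new_planner("random", frac = frac, subclass = "planner_random")
}

#' @export
recommend.planner_random <- function(planner, state, ...) {
  sp <- state_pairs(state)
  m <- round(planner$frac * nrow(sp$pairs))
  if (m == 0) return(recommendations())
  k <- sample.int(nrow(sp$pairs), m)
  recommendations(sp$pairs[k, 1], sp$pairs[k, 2], sp$valence[k])
}

#' Cooperative-clustering planner
#'
#' Rule-based assortment: (1) recommend deleting every existing
#' cooperator-defector edge; (2) recommend adding every absent
#' cooperator-cooperator pair; (3) toggle an additional `round(frac_extra *
#' choose(n, 2))` uniformly sampled pairs, skipping pairs already covered by
#' the rules (rule-based recommendations take precedence). The attribute
#' `n_random_sampled` on the returned set records the size of the random
#' component before de-duplication.
#'
#' @param frac_extra Fraction of possible edges in the random component
#'   (canonical 0.05).
#' @return A planner object.
#' @export
planner_clustering <- function(frac_extra = 0.05) {
  new_planner("clustering", frac_extra = frac_extra,
              subclass = "planner_clustering")
}

#' @export
recommend.planner_clustering <- function(planner, state, ...) {
  sp <- state_pairs(state)
  rule_del <- which(sp$exists & sp$class == "CD")   # first: disengage C-D
  rule_add <- which(!sp$exists & sp$class == "CC")  # second: connect C-C
  covered <- c(rule_del, rule_add)
  k <- round(planner$frac_extra * nrow(sp$pairs))
  extra <- if (k > 0) sample.int(nrow(sp$pairs), k) else integer()
  extra <- setdiff(extra, covered)
  sel <- c(rule_del, rule_add, extra)
  out <- recommendations(sp$pairs[sel, 1], sp$pairs[sel, 2], sp$valence[sel])
  attr(out, "n_random_sampled") <- k
  out
}

# ---- encouragement planner ------------------------------------------------

#' Default encouragement probability table
#'
#' Per-round emission probabilities indexed by pair class (CC, CD, DD) and
#' valence (add, delete). Two cooperator-defector deletion anchors are fixed
#' by the planner's published description — 4.8% in round 1 rising to 72.2%
#' in the final round — and interpolate linearly between. The remaining
#' cells follow the empirical recommendation frequencies of the trained
#' graph-network planner: CC-add 0.99, CC-delete 0.03, DD-add 0.00,
#' DD-delete 1.00, and a CD-add schedule declining linearly with mean 0.58.
#'
#' @param n_rounds Number of rounds the table covers.
#' @return Data frame with columns `round`, `pair_class`, `valence`,
#'   `probability`, of class `encouragement_table`.
#' @export
default_encouragement_table <- function(n_rounds = 15L) {
  t <- seq_len(n_rounds)
  grid <- expand.grid(round = t, pair_class = c("CC", "CD", "DD"),
                      valence = c("add", "delete"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prob <- numeric(nrow(grid))
  # convex-combination form: exact at both anchors
  lin <- function(from, to) {
    w <- (t - 1) / (n_rounds - 1)
    from * (1 - w) + to * w
  }
  sched <- list(
    CC.add = rep(0.99, n_rounds), CC.delete = rep(0.03, n_rounds),
    CD.add = lin(0.78, 0.38),     CD.delete = lin(0.048, 0.722),
    DD.add = rep(0.00, n_rounds), DD.delete = rep(1.00, n_rounds)
  )
  for (key in names(sched)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rows <- grid$pair_class == parts[1] & grid$valence == parts[2]
    prob[rows] <- sched[[key]][grid$round[rows]]
  }
  structure(cbind(grid, probability = prob),
            class = c("encouragement_table", "data.frame"))
}

#' Read an encouragement table from CSV
#'
#' Expects columns `round`, `pair_class`, `valence`, `probability`.
#'
#' @param path CSV file path.
#' @return An `encouragement_table`.
#' @export
read_encouragement_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("round", "pair_class", "valence", "probability") %in% names(d)),
              "encouragement table CSV must have round, pair_class, valence, probability")
  assert_that(all(d$probability >= 0 & d$probability <= 1),
              "probabilities must lie in [0, 1]")
  structure(d[c("round", "pair_class", "valence", "probability")],
            class = c("encouragement_table", "data.frame"))
}

#' Query an encouragement planner's emission probability
#'
#' Returns the probability with which the planner emits a recommendation of
#' the given valence for a pair of the given class in the given round.
#'
#' @param x A `planner_encouragement` or an `encouragement_table`.
#' @param round Round index.
#' @param pair_class `"CC"`, `"CD"` or `"DD"`.
#' @param valence `"add"` or `"delete"`.
#' @return The emission probability.
#' @export
encouragement_probability <- function(x, round, pair_class, valence) {
  tab <- if (inherits(x, "coop_planner")) x$table else x
  assert_that(inherits(tab, "encouragement_table"),
              "x must be an encouragement planner or table")
  encouragement_prob(tab, round, pair_class, valence)
}

# probability lookup, vectorised over pairs
encouragement_prob <- function(table, round_t, pair_class, valence) {
  if (!any(table$round == round_t)) {
    stop("encouragement table does not cover round ", round_t)
  }
  sub <- table[table$round == round_t, ]
  key <- paste(sub$pair_class, sub$valence)
  p <- sub$probability[match(paste(pair_class, valence), key)]
  assert_that(!anyNA(p), "encouragement table is missing a cell")
  p
}

#' Encouragement planner
#'
#' Distils the trained graph-network planner's policy into a table: for
#' every pair, independently emit the applicable-valence recommendation
#' (add if the pair is unlinked, delete if linked) with a probability that
#' depends only on the pair class and the round number.
#'
#' @param table An `encouragement_table`; defaults to
#'   [default_encouragement_table()] for 15 rounds.
#' @return A planner object.
#' @export
planner_encouragement <- function(table = default_encouragement_table()) {
  new_planner("encouragement", table = table,
              subclass = "planner_encouragement")
}

#' @export
recommend.planner_encouragement <- function(planner, state, ...) {
  sp <- state_pairs(state)
  p <- encouragement_prob(planner$table, state$round_t, sp$class, sp$valence)
  sel <- which(stats::runif(length(p)) < p)
  recommendations(sp$pairs[sel, 1], sp$pairs[sel, 2], sp$valence[sel])
}

# ---- density-matching ("neutral") planner ---------------------------------

#' Neutral (connectivity-matching) planner
#'
#' Recreates a target density trajectory without regard for players'
#' choices: each round it recommends uniformly sampled additions (if the
#' current density is below the round's target) or deletions (if above),
#' sized to close the expected post-acceptance gap.
#'
#' @param density_schedule Numeric vector of per-round target densities in
#'   `[0, 1]`, one entry per round.
#' @param accept_rate Anticipated probability that a recommendation
#'   executes; the number of recommendations is the density gap (in pairs)
#'   divided by this. Default 1 (recommend exactly the gap).
#' @return A planner object.
#' @export
planner_neutral <- function(density_schedule, accept_rate = 1) {
  assert_that(all(density_schedule >= 0 & density_schedule <= 1),
              "densities must lie in [0, 1]")
  assert_that(accept_rate > 0 && accept_rate <= 1, "accept_rate in (0, 1]")
  new_planner("neutral", schedule = as.numeric(density_schedule),
              accept_rate = accept_rate, subclass = "planner_neutral")
}

#' @export
recommend.planner_neutral <- function(planner, state, ...) {
  t <- state$round_t
  if (t > length(planner$schedule)) {
    stop("density schedule does not cover round ", t)
  }
  sp <- state_pairs(state)
  npairs <- nrow(sp$pairs)
  gap <- planner$schedule[t] - sum(sp$exists) / npairs
  k <- round(abs(gap) * npairs / planner$accept_rate)
  pool <- if (gap > 0) which(!sp$exists) else which(sp$exists)
  k <- min(k, length(pool))
  if (k == 0) return(recommendations())
  sel <- pool[sample.int(length(pool), k)]
  recommendations(sp$pairs[sel, 1], sp$pairs[sel, 2], sp$valence[sel])
}

#' Per-round mean density of a set of game logs
#'
#' Measures the post-rewiring edge density for every round, averaged across
#' logs — the schedule a [planner_neutral()] needs in order to mimic another
#' planner's connectivity dynamics.
#'
#' @param logs A `coop_log` or list of them.
#' @return Numeric vector of mean densities, one per round.
#' @export
density_schedule_from_logs <- function(logs) {
  if (inherits(logs, "coop_log")) logs <- list(logs)
  n <- logs[[1]]$config$n_players
  npairs <- choose(n, 2)
  dens <- sapply(logs, function(lg)
    vapply(lg$records, function(r) nrow(r$edges_after) / npairs, numeric(1)))
  rowMeans(as.matrix(dens))
}

#' Maximum-density planner
#'
#' Recommends adding every currently absent edge, and never recommends a
#' deletion; under accepting players the network density is non-decreasing.
#'
#' @return A planner object.
#' @export
planner_max_density <- function() {
  new_planner("max_density", subclass = "planner_max_density")
}

#' @export
recommend.planner_max_density <- function(planner, state, ...) {
  sp <- state_pairs(state)
  sel <- which(!sp$exists)
  recommendations(sp$pairs[sel, 1], sp$pairs[sel, 2], rep("add", length(sel)))
}
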