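# Analysis suite: cooperation trajectories, recommendation breakdowns,
# choice assortativity, degree bias, core-periphery structure, inequality.

#' Cooperation rate in a logged round
#'
#' @param log A `coop_log`.
#' @param round Round index; if `NULL`, returns the full per-round
#'   trajectory.
#' @return Fraction of players cooperating.
#' @export
cooperation_rate <- function(log, round = NULL) {
  tr <- vapply(log$records, function(r) mean(r$actions), numeric(1))
  if (is.null(round)) return(tr)
  assert_that(round >= 1 && round <= length(tr), "round not in log")
  tr[round]
}

# reconstruct per-round pre-rewiring adjacency and actions from a log
log_round_state <- function(log, t) {
  n <- log$config$n_players
  adj <- matrix(0L, n, n)
  e <- if (t == 1) log$initial_edges else log$records[[t - 1]]$edges_after
  if (length(e)) {
    e <- matrix(as.integer(e), ncol = 2)
    adj[e] <- 1L; adj[e[, 2:1, drop = FALSE]] <- 1L
  }
  game_state(adj, round_t = t, last_action = log$records[[t]]$actions,
             capital = log$records[[t]]$capital)
}

#' Recommendation breakdown by pair class, valence and round
#'
#' For every (pair class, valence, round) cell, counts the "chances" —
#' pair-rounds where a recommendation of that valence was applicable (the
#' pair linked, for a deletion; unlinked, for an addition) — and the
#' recommendations actually issued, and reports the emission probability
#' with a 95% credible interval from a uniform Beta(1, 1) prior.
#'
#' @param logs A `coop_log` or list of them.
#' @param by_round If `FALSE` (default) cells are aggregated over rounds.
#' @return Data frame with columns `pair_class`, `valence` (and `round` when
#'   `by_round = TRUE`), `chances`, `recs`, `prob`, `ci_lo`, `ci_hi`.
#'   Cells with zero chances have `prob = NA`.
#' @export
recommendation_breakdown <- function(logs, by_round = FALSE) {
  if (inherits(logs, "coop_log")) logs <- list(logs)
  rows <- list()
  for (lg in logs) {
    for (t in seq_along(lg$records)) {
      st <- log_round_state(lg, t)
      sp <- state_pairs(st)
      rec <- lg$records[[t]]$recs
      issued <- rep(FALSE, nrow(sp$pairs))
      if (nrow(rec)) {
        issued[pair_index(rec$i, rec$j, nrow(st$adjacency))] <- TRUE
      }
      rows[[length(rows) + 1]] <- data.frame(
        round = t, pair_class = sp$class, valence = sp$valence, issued = issued)
    }
  }
  d <- do.call(rbind, rows)
  keys <- if (by_round) c("pair_class", "valence", "round") else c("pair_class", "valence")
  agg <- stats::aggregate(cbind(chances = rep(1, nrow(d)), recs = d$issued),
                          by = d[keys], FUN = sum)
  full <- expand.grid(pair_class = c("CC", "CD", "DD"),
                      valence = c("add", "delete"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (by_round) {
    full <- merge(full, data.frame(round = seq_along(logs[[1]]$records)))
  }
  out <- merge(full, agg, by = keys, all.x = TRUE)
  out$chances[is.na(out$chances)] <- 0
  out$recs[is.na(out$recs)] <- 0
  out$prob <- ifelse(out$chances > 0, out$recs / out$chances, NA_real_)
  out$ci_lo <- ifelse(out$chances > 0,
                      stats::qbeta(0.025, out$recs + 1, out$chances - out$recs + 1),
                      NA_real_)
  out$ci_hi <- ifelse(out$chances > 0,
                      stats::qbeta(0.975, out$recs + 1, out$chances - out$recs + 1),
                      NA_real_)
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Choice assortativity of a labelled graph
#'
#' Attribute assortativity of the binary cooperate/defect label: the
#' correlation of endpoint labels across edges. +1 when cooperators link
#' only to cooperators and defectors to defectors; -1 for perfect
#' cooperator-defector bipartiteness. Undefined (returned as `NA`) when all
#' labels are identical or the graph has no edges.
#'
#' @param adjacency Simple symmetric 0/1 adjacency matrix.
#' @param last_actions Per-node 0/1 labels.
#' @return Assortativity coefficient in `[-1, 1]`, or `NA`.
#' @export
choice_assortativity <- function(adjacency, last_actions) {
  assert_that(sum(adjacency) > 0, "graph must have at least one edge")
  if (length(unique(last_actions)) < 2) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  r <- igraph::assortativity(g, values = as.numeric(last_actions))
  if (!is.finite(r)) NA_real_ else r
}

#' Mean degree bias towards cooperators
#'
#' Mean degree of cooperators minus mean degree of defectors; `NA` when
#' either class is empty.
#'
#' @inheritParams choice_assortativity
#' @return Signed degree difference, or `NA`.
#' @export
degree_bias <- function(adjacency, last_actions) {
  deg <- rowSums(adjacency)
  coop <- last_actions == 1
  if (!any(coop) || all(coop)) return(NA_real_)
  mean(deg[coop]) - mean(deg[!coop])
}

# correlation of the adjacency with the ideal core-periphery pattern for a
# given core, computed in closed form from (core size, periphery-internal
# edge count): pattern(i,j) = 1 iff i or j is in the core
cp_correlation <- function(n_pairs, n_edges, core_size, n, e_periph) {
  sy <- n_pairs - choose(n - core_size, 2)     # pattern ones
  sxy <- n_edges - e_periph                    # edges touching the core
  num <- n_pairs * sxy - n_edges * sy
  den <- sqrt(n_pairs * n_edges - n_edges^2) * sqrt(n_pairs * sy - sy^2)
  ifelse(den > 0, num / den, -Inf)
}

#' Discrete core-periphery structure of a graph
#'
#' Finds the core assignment maximizing the Pearson correlation between the
#' observed adjacency (over unordered pairs) and the ideal core-periphery
#' pattern in which a pair is linked iff at least one endpoint belongs to
#' the core. The search is exhaustive over all `2^n - 2` non-trivial
#' assignments for `n <= max_exact` (default 16); beyond that a greedy
#' single-swap ascent from degree-ranked seeds is used. Score ties break to
#' the smallest core, then to the smallest binary encoding of the
#' membership vector, so the output is deterministic. On graphs where the
#' correlation is undefined for every assignment (e.g. the complete graph)
#' the score is `NA` and the tie-break alone picks the core.
#'
#' @param adjacency Simple symmetric 0/1 adjacency matrix, `n >= 3`.
#' @param last_actions Optional 0/1 labels; when given, the cooperator share
#'   of the core and of the periphery are reported.
#' @param max_exact Largest `n` for which the exact search is used.
#' @return Object of class `core_periphery`: list with `core` (sorted node
#'   indices), `score`, and (if labelled) `core_coop_share`,
#'   `periphery_coop_share`.
#' @export
core_periphery <- function(adjacency, last_actions = NULL, max_exact = 16L) {
  n <- nrow(adjacency)
  if (n < 3) stop("core_periphery requires at least 3 nodes")
  npairs <- choose(n, 2)
  pp <- player_pairs(n)
  edge_rows <- which(adjacency[pp] == 1L)
  n_edges <- length(edge_rows)
  assert_that(n_edges > 0, "graph must have at least one edge")

  if (n <= max_exact) {
    n_masks <- 2^n - 2
    ids <- seq_len(n_masks)                      # masks 1 .. 2^n-2 (proper, non-empty)
    member <- matrix(FALSE, n_masks, n)
    for (b in seq_len(n)) member[, b] <- bitwAnd(ids, bitwShiftL(1L, b - 1L)) > 0
    csize <- rowSums(member)
    e_per <- integer(n_masks)
    for (r in edge_rows) {                       # edge inside periphery?
      e_per <- e_per + (!member[, pp[r, 1]] & !member[, pp[r, 2]])
    }
    sc <- cp_correlation(npairs, n_edges, csize, n, e_per)
    best <- max(sc)
    if (!is.finite(best)) {
      # saturated pattern (e.g. complete graph): every assignment ties and the
      # correlation is undefined; fall back to the tie-break alone
      core <- 1L; score <- NA_real_
    } else {
      cand <- which(sc >= best - 1e-12)
      cand <- cand[order(csize[cand], cand)]     # smallest core, then encoding order
      core <- which(member[cand[1], ])
      score <- sc[cand[1]]
    }
  } else {
    res <- cp_greedy(adjacency, pp, edge_rows, npairs, n_edges)
    core <- res$core; score <- res$score
  }
  out <- list(core = sort(core), score = score, n = n)
  if (!is.null(last_actions)) {
    periph <- setdiff(seq_len(n), out$core)
    out$core_coop_share <- mean(last_actions[out$core] == 1)
    out$periphery_coop_share <- mean(last_actions[periph] == 1)
  }
  structure(out, class = "core_periphery")
}

# greedy ascent used for n > max_exact: start from top-k degree cores for
# every k, repeatedly apply the best single add/remove move
cp_greedy <- function(adjacency, pp, edge_rows, npairs, n_edges) {
  n <- nrow(adjacency)
  score_of <- function(core_mask) {
    e_per <- sum(!core_mask[pp[edge_rows, 1]] & !core_mask[pp[edge_rows, 2]])
    cp_correlation(npairs, n_edges, sum(core_mask), n, e_per)
  }
  ord <- order(-rowSums(adjacency), seq_len(n))
  best_core <- NULL; best_score <- -Inf
  for (k in seq_len(n - 1)) {
    mask <- rep(FALSE, n); mask[ord[seq_len(k)]] <- TRUE
    repeat {
      s0 <- score_of(mask); improved <- FALSE
      for (v in seq_len(n)) {
        m2 <- mask; m2[v] <- !m2[v]
        if (any(m2) && !all(m2) && score_of(m2) > s0 + 1e-12) {
          mask <- m2; improved <- TRUE; break
        }
      }
      if (!improved) break
    }
    s <- score_of(mask)
    if (s > best_score + 1e-12 ||
        (s > best_score - 1e-12 && sum(mask) < length(best_core))) {
      best_score <- s; best_core <- which(mask)
    }
  }
  list(core = best_core, score = best_score)
}

#' @export
print.core_periphery <- function(x, ...) {
  cat(sprintf("Core-periphery fit: score %.3f, core of %d/%d nodes {%s}\n",
              x$score, length(x$core), x$n, paste(x$core, collapse = ", ")))
  if (!is.null(x$core_coop_share)) {
    cat(sprintf("  cooperator share: core %.1f%%, periphery %.1f%%\n",
                100 * x$core_coop_share, 100 * x$periphery_coop_share))
  }
  invisible(x)
}

#' Permutation test of core composition
#'
#' Tests whether the cooperator share of the core is larger than expected
#' when labels are assigned to nodes at random: permutes the labels
#' `n_perm` times and reports `p = (1 + #{share >= observed}) / (1 +
#' n_perm)` (add-one correction).
#'
#' @param core Node indices of the core (from [core_periphery()]).
#' @param last_actions Per-node 0/1 labels.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
core_composition_test <- function(core, last_actions, n_perm = 10000L, seed = 1L) {
  obs <- mean(last_actions[core] == 1)
  s <- rng_streams(seed, 1L)
  with_stream(s[[1]], {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(last_actions)
      if (mean(perm[core] == 1) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
}

#' Gini coefficient and Lorenz curve of end-of-game capital
#'
#' Gini is the mean absolute pairwise difference scaled by twice the mean:
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`. Capital can go negative in the
#' game; since the Gini coefficient is only well-defined for positive-mean,
#' non-negative data, negative inputs are shifted so the minimum is zero
#' (the shift is recorded in the result) unless `shift = "none"`.
#'
#' @param capital Numeric vector of per-player capital.
#' @param shift `"auto"` (default; shift so min is 0 when negatives occur)
#'   or `"none"` (error on negative values).
#' @return List with `gini`, `lorenz` (data frame `p`, `share` including the
#'   origin), and `shift` applied.
#' @export
gini_and_lorenz <- function(capital, shift = c("auto", "none")) {
  shift <- match.arg(shift)
  applied <- 0
  if (any(capital < 0)) {
    if (shift == "none") {
      stop("negative capital: Gini undefined; use shift = \"auto\" to shift the minimum to 0")
    }
    applied <- -min(capital)
    capital <- capital + applied
  }
  m <- mean(capital)
  if (m <= 0) stop("mean capital must be positive after shifting")
  n <- length(capital)
  g <- sum(abs(outer(capital, capital, "-"))) / (2 * n^2 * m)
  x <- sort(capital)
  lorenz <- data.frame(p = seq(0, 1, length.out = n + 1),
                       share = c(0, cumsum(x) / sum(x)))
  list(gini = g, lorenz = lorenz, shift = applied)
}

#' Tidy per-round summary statistics for a set of game logs
#'
#' One row per group, round and statistic: cooperation rate, density,
#' choice assortativity and degree bias — the table the condition-level
#' plots are drawn from.
#'
#' @param logs List of `coop_log` objects.
#' @return Data frame with columns `group`, `round`, `statistic`, `value`.
#' @export
summarize_logs <- function(logs) {
  if (inherits(logs, "coop_log")) logs <- list(logs)
  rows <- list()
  for (g in seq_along(logs)) {
    lg <- logs[[g]]
    n <- lg$config$n_players
    for (t in seq_along(lg$records)) {
      r <- lg$records[[t]]
      adj <- matrix(0L, n, n)
      e <- r$edges_after
      if (length(e)) {
        e <- matrix(as.integer(e), ncol = 2)
        adj[e] <- 1L; adj[e[, 2:1, drop = FALSE]] <- 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = g, round = t,
        statistic = c("cooperation", "density", "assortativity", "degree_bias"),
        value = c(mean(r$actions), sum(adj) / (n * (n - 1)),
                  if (sum(adj) > 0) choice_assortativity(adj, r$actions) else NA_real_,
                  degree_bias(adj, r$actions)))
    }
  }
  do.call(rbind, rows)
}
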