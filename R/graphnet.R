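# Graph-network planner: encoding, forward pass, and manual backpropagation.
#
# The network follows the standard graph-network block: per-pair ("edge")
# features are updated from the pair, its two endpoints and the global
# feature; per-pair latents are summed onto nodes, which are then updated;
# all latents are summed into a global update. Two such message-passing
# blocks are applied (non-recurrent), then a scalar policy logit is read
# out per candidate pair and a scalar value from the global latent.
# Candidate pairs are ALL unordered player pairs, so a logit exists for
# every possible edge; the edge-existence indicator is a feature.
#
# All MLPs are single-hidden-layer tanh networks written in base R with
# hand-derived gradients, which keeps the whole training loop dependency-
# free and exactly reproducible.

DE0 <- 4L  # exists, both-cooperate, mixed, both-defect
DV0 <- 3L  # cooperated, defected, normalized degree
DU0 <- 1L  # normalized round index t/T

#' Encode a game state for the graph network
#'
#' @param state A `coop_state` with defined `last_action`.
#' @param n_rounds Total rounds `T`, used to normalize the round index.
#' @return A `graph_obs`: list with `u` (1 x 1), `V` (n x 3), `E`
#'   (`choose(n,2)` x 4, canonical pair order), `pairs`, and `n`.
#' @export
encode_observation <- function(state, n_rounds) {
  n <- nrow(state$adjacency)
  assert_that(!anyNA(state$last_action), "last actions must be defined")
  pp <- player_pairs(n)
  a <- as.integer(state$last_action == 1L)
  V <- cbind(coop = a, defect = 1L - a,
             deg = rowSums(state$adjacency) / (n - 1))
  exists <- state$adjacency[pp]
  s <- a[pp[, 1]] + a[pp[, 2]]
  E <- cbind(exists = exists, both_coop = as.integer(s == 2L),
             mixed = as.integer(s == 1L), both_def = as.integer(s == 0L))
  structure(list(u = matrix(state$round_t / n_rounds, 1, 1),
                 V = V, E = E, pairs = pp, n = n),
            class = "graph_obs")
}

new_mlp <- function(d_in, d_hidden, d_out) {
  list(W1 = matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(1 / d_in)), d_in),
       b1 = rep(0, d_hidden),
       W2 = matrix(stats::rnorm(d_hidden * d_out, sd = sqrt(1 / d_hidden)), d_hidden),
       b2 = rep(0, d_out))
}

mlp_fwd <- function(m, X) {
  nr <- nrow(X)
  H <- tanh(X %*% m$W1 + rep(m$b1, each = nr))
  list(out = H %*% m$W2 + rep(m$b2, each = nr), X = X, H = H)
}

mlp_bwd <- function(m, cache, dOut) {
  dW2 <- crossprod(cache$H, dOut)
  db2 <- colSums(dOut)
  dH <- (dOut %*% t(m$W2)) * (1 - cache$H^2)
  dW1 <- crossprod(cache$X, dH)
  db1 <- colSums(dH)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dX = dH %*% t(m$W1))
}

#' Initialize graph-network parameters
#'
#' @param width Latent dimension of edge/node/global updates.
#' @param hidden Hidden-layer width of each MLP.
#' @param seed Integer seed for the weight initialization.
#' @param logit_bias Initial bias of the policy readout. The default (-2)
#'   starts the policy recommending each pair with probability ~0.12 — a
#'   sparse-recommendation prior that keeps the factorized policy out of
#'   the saturated everything-at-once regime where per-pair credit
#'   assignment has almost no gradient.
#' @return Object of class `graphnet_params`.
#' @export
init_graphnet <- function(width = 16L, hidden = 16L, seed = 1L,
                          logit_bias = -2) {
  s <- rng_streams(seed, 1L)
  d <- as.integer(width); h <- as.integer(hidden)
  params <- with_stream(s[[1]], list(
    b1_edge = new_mlp(DE0 + 2L * DV0 + DU0, h, d),
    b1_node = new_mlp(DV0 + d + DU0, h, d),
    b1_glob = new_mlp(DU0 + 2L * d, h, d),
    b2_edge = new_mlp(4L * d, h, d),
    b2_node = new_mlp(3L * d, h, d),
    b2_glob = new_mlp(3L * d, h, d),
    edge_out = list(W = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1),
                    b = logit_bias),
    glob_out = list(W = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1), b = 0)
  ))
  structure(c(params, list(width = d, hidden = h)), class = "graphnet_params")
}

#' @export
print.graphnet_params <- function(x, ...) {
  cat(sprintf("GraphNet: 2 message-passing blocks, latent width %d, hidden %d (%d weights)\n",
              x$width, x$hidden, length(flatten_params(x))))
  invisible(x)
}

# parameter names carrying gradients (excludes width/hidden metadata)
GN_PARTS <- c("b1_edge", "b1_node", "b1_glob", "b2_edge", "b2_node", "b2_glob",
              "edge_out", "glob_out")

flatten_params <- function(params) unlist(params[GN_PARTS], use.names = FALSE)

unflatten_params <- function(params, vec) {
  skel <- params[GN_PARTS]
  out <- utils::relist(vec, skel)
  for (nm in GN_PARTS) params[[nm]] <- out[[nm]]
  params
}

# cached batched index structures for a stack of R observations on n nodes
gn_batch_index <- function(n, R) {
  key <- paste0(n, "_", R)
  hit <- .coopnet_cache$gn[[key]]
  if (!is.null(hit)) return(hit)
  P <- choose(n, 2)
  pp <- player_pairs(n)
  roff <- rep((seq_len(R) - 1L), each = P)
  pi_idx <- roff * n + rep(pp[, 1], R)
  pj_idx <- roff * n + rep(pp[, 2], R)
  pr_idx <- rep(seq_len(R), each = P)
  vr_idx <- rep(seq_len(R), each = n)
  S <- Matrix::sparseMatrix(
    i = c(pi_idx, pj_idx),
    j = rep(seq_len(R * P), 2),
    x = 1, dims = c(R * n, R * P))
  out <- list(n = n, P = P, R = R, pi = pi_idx, pj = pj_idx, pr = pr_idx,
              vr = vr_idx, S = S)
  .coopnet_cache$gn[[key]] <- out
  out
}

gn_block_fwd <- function(edge, node, glob, Ein, Vin, Uin, ix) {
  # endpoint features enter through their sum and elementwise product, so the
  # edge update is symmetric under endpoint exchange (the pair is unordered)
  Vi <- Vin[ix$pi, , drop = FALSE]
  Vj <- Vin[ix$pj, , drop = FALSE]
  Xe <- cbind(Ein, Vi + Vj, Vi * Vj, Uin[ix$pr, , drop = FALSE])
  fe <- mlp_fwd(edge, Xe)
  fe$Vi <- Vi; fe$Vj <- Vj
  aggEn <- as.matrix(ix$S %*% fe$out)
  Xv <- cbind(Vin, aggEn, Uin[ix$vr, , drop = FALSE])
  fv <- mlp_fwd(node, Xv)
  aggEg <- rowsum(fe$out, ix$pr)
  aggVg <- rowsum(fv$out, ix$vr)
  Xu <- cbind(Uin, aggEg, aggVg)
  fu <- mlp_fwd(glob, Xu)
  list(E = fe$out, V = fv$out, U = fu$out, fe = fe, fv = fv, fu = fu,
       d_in = list(E = ncol(Ein), V = ncol(Vin), U = ncol(Uin)))
}

# backward through one block; dE, dV, dU are gradients w.r.t. the block's
# outputs (dV/dU may be zero matrices). Returns gradients for the three MLPs
# and for the block inputs.
gn_block_bwd <- function(edge, node, glob, blk, dE, dV, dU, ix) {
  d <- ncol(blk$E)
  din <- blk$d_in
  bu <- mlp_bwd(glob, blk$fu, dU)
  dUin <- bu$dX[, seq_len(din$U), drop = FALSE]
  dAggEg <- bu$dX[, din$U + seq_len(d), drop = FALSE]
  dAggVg <- bu$dX[, din$U + d + seq_len(d), drop = FALSE]
  dV <- dV + dAggVg[ix$vr, , drop = FALSE]
  dEacc <- dE + dAggEg[ix$pr, , drop = FALSE]

  bv <- mlp_bwd(node, blk$fv, dV)
  dVin <- bv$dX[, seq_len(din$V), drop = FALSE]
  dAggEn <- bv$dX[, din$V + seq_len(d), drop = FALSE]
  dUin <- dUin + rowsum(bv$dX[, din$V + d + seq_len(din$U), drop = FALSE], ix$vr)
  dEacc <- dEacc + as.matrix(Matrix::crossprod(ix$S, dAggEn))

  be <- mlp_bwd(edge, blk$fe, dEacc)
  dEin <- be$dX[, seq_len(din$E), drop = FALSE]
  dSum <- be$dX[, din$E + seq_len(din$V), drop = FALSE]
  dProd <- be$dX[, din$E + din$V + seq_len(din$V), drop = FALSE]
  dVi <- dSum + dProd * blk$fe$Vj
  dVj <- dSum + dProd * blk$fe$Vi
  # every node appears in n-1 pairs across the two endpoint slots, so the
  # combined grouping covers all rows
  dVin <- dVin + rowsum(rbind(dVi, dVj), c(ix$pi, ix$pj))
  dUin <- dUin + rowsum(be$dX[, din$E + 2 * din$V + seq_len(din$U), drop = FALSE],
                        ix$pr)
  list(edge = be$grads, node = bv$grads, glob = bu$grads,
       dEin = dEin, dVin = dVin, dUin = dUin)
}

#' Graph-network forward pass
#'
#' Computes per-pair policy logits and a state-value estimate for one
#' observation or a stacked batch of observations on the same player count.
#'
#' @param params A `graphnet_params` object.
#' @param obs A `graph_obs`, or a list of them (stacked into one batch).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return List with `logits` (`R x choose(n,2)` matrix), `value` (length
#'   `R`), and (if requested) the backward cache.
#' @export
graphnet_forward <- function(params, obs, keep_cache = FALSE) {
  if (inherits(obs, "graph_obs")) obs <- list(obs)
  R <- length(obs); n <- obs[[1]]$n
  ix <- gn_batch_index(n, R)
  E0 <- do.call(rbind, lapply(obs, `[[`, "E"))
  V0 <- do.call(rbind, lapply(obs, `[[`, "V"))
  U0 <- do.call(rbind, lapply(obs, `[[`, "u"))
  blk1 <- gn_block_fwd(params$b1_edge, params$b1_node, params$b1_glob,
                       E0, V0, U0, ix)
  blk2 <- gn_block_fwd(params$b2_edge, params$b2_node, params$b2_glob,
                       blk1$E, blk1$V, blk1$U, ix)
  logits <- as.numeric(blk2$E %*% params$edge_out$W + params$edge_out$b)
  value <- as.numeric(blk2$U %*% params$glob_out$W + params$glob_out$b)
  if (any(!is.finite(logits)) || any(!is.finite(value))) {
    stop("non-finite activations in graph-network forward pass")
  }
  out <- list(logits = matrix(logits, R, ix$P, byrow = TRUE), value = value)
  if (keep_cache) out$cache <- list(ix = ix, blk1 = blk1, blk2 = blk2,
                                    logit_vec = logits)
  out
}

# gradients of a scalar loss w.r.t. all parameters, given d(loss)/d(logit)
# (R*P vector, batch pair order) and d(loss)/d(value) (length R)
graphnet_backward <- function(params, cache, dlogits, dvalue) {
  ix <- cache$ix; blk1 <- cache$blk1; blk2 <- cache$blk2
  d <- params$width
  dlog <- matrix(dlogits, ncol = 1)
  dval <- matrix(dvalue, ncol = 1)
  g_edge_out <- list(W = crossprod(blk2$E, dlog), b = sum(dlog))
  g_glob_out <- list(W = crossprod(blk2$U, dval), b = sum(dval))
  dE2 <- dlog %*% t(params$edge_out$W)
  dU2 <- dval %*% t(params$glob_out$W)
  dV2 <- matrix(0, nrow(blk2$V), d)
  b2 <- gn_block_bwd(params$b2_edge, params$b2_node, params$b2_glob,
                     blk2, dE2, dV2, dU2, ix)
  b1 <- gn_block_bwd(params$b1_edge, params$b1_node, params$b1_glob,
                     blk1, b2$dEin, b2$dVin, b2$dUin, ix)
  list(b1_edge = b1$edge, b1_node = b1$node, b1_glob = b1$glob,
       b2_edge = b2$edge, b2_node = b2$node, b2_glob = b2$glob,
       edge_out = g_edge_out, glob_out = g_glob_out)
}

#' Sample a recommendation set from policy logits
#'
#' The policy is factorized: each candidate pair is recommended
#' independently with probability `sigmoid(logit)`; the valence follows the
#' current edge state (add if absent, delete if present). Uses the current
#' RNG stream.
#'
#' @param logits Numeric vector, one logit per canonical pair.
#' @param state The current `coop_state`.
#' @return List with `recs` (recommendation data frame) and `mask` (the 0/1
#'   per-pair emission vector actually sampled).
#' @export
sample_action <- function(logits, state) {
  sp <- state_pairs(state)
  assert_that(length(logits) == nrow(sp$pairs), "one logit per candidate pair")
  p <- logistic(logits)
  mask <- as.integer(stats::runif(length(p)) < p)
  sel <- which(mask == 1L)
  list(recs = recommendations(sp$pairs[sel, 1], sp$pairs[sel, 2],
                              sp$valence[sel]),
       mask = mask)
}

#' GraphNet planner
#'
#' Wraps trained (or freshly initialized) graph-network parameters as a
#' planner implementing [recommend()].
#'
#' @param params A `graphnet_params` object.
#' @param n_rounds Total rounds of the games it will be used in (for the
#'   round-index feature).
#' @return A planner object.
#' @export
planner_graphnet <- function(params, n_rounds = 15L) {
  assert_that(inherits(params, "graphnet_params"), "params must be graphnet_params")
  new_planner("graphnet", params = params, n_rounds = as.integer(n_rounds),
              subclass = "planner_graphnet")
}

#' @export
recommend.planner_graphnet <- function(planner, state, ...) {
  obs <- encode_observation(state, planner$n_rounds)
  fwd <- graphnet_forward(planner$params, obs)
  sample_action(fwd$logits[1, ], state)$recs
}

#' Save / load graph-network weights
#'
#' Weights are stored as plain JSON together with the architecture fields
#' and a simple content checksum, so checkpoints are portable text files.
#'
#' @param params A `graphnet_params`.
#' @param path File path.
#' @return `load_graphnet` returns a `graphnet_params`.
#' @export
save_graphnet <- function(params, path) {
  vec <- flatten_params(params)
  obj <- list(width = params$width, hidden = params$hidden,
              checksum = sum(vec^2), weights = vec)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_graphnet
#' @export
load_graphnet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- init_graphnet(width = obj$width, hidden = obj$hidden, seed = 0L)
  params <- unflatten_params(params, as.numeric(obj$weights))
  assert_that(abs(sum(obj$weights^2) - obj$checksum) < 1e-6,
              "checkpoint checksum mismatch")
  params
}
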