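# Internal helpers: pair bookkeeping, seeded RNG substreams, small checks.

logistic <- function(x) 1 / (1 + exp(-x))

#' Enumerate the unordered player pairs of an n-player game
#'
#' Pairs are listed in canonical column-major upper-triangle order:
#' (1,2), (1,3), (2,3), (1,4), ... This ordering is used everywhere a
#' per-pair vector (logits, action masks, recommendation probabilities)
#' is laid out.
#'
#' @param n Number of players (>= 2).
#' @return Integer matrix with columns `i`, `j` (i < j) and `choose(n, 2)` rows.
#' @export
player_pairs <- function(n) {
  if (n < 2) stop("need at least 2 players")
  key <- as.character(n)
  hit <- .coopnet_cache$pairs[[key]]
  if (!is.null(hit)) return(hit)
  m <- matrix(0L, n, n)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx <- idx[, c("i", "j"), drop = FALSE]
  .coopnet_cache$pairs[[key]] <- idx
  idx
}

# package-local memo store for index structures rebuilt in hot loops
.coopnet_cache <- new.env(parent = emptyenv())
.coopnet_cache$pairs <- list()
.coopnet_cache$gn <- list()

# index of unordered pair (i,j) in the canonical player_pairs(n) order
pair_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  # column-major upper triangle: pairs with larger index hi come after
  # all choose(hi - 1, 2) pairs contained in 1..(hi-1)
  choose(hi - 1, 2) + lo
}

# --- seeded RNG substreams -------------------------------------------------
#
# Every stochastic actor (each bot, each planner, the engine itself) owns an
# independent L'Ecuyer-CMRG substream so that, e.g., a planner consuming more
# or fewer random numbers never perturbs the bots' decisions. A "stream" is an
# environment holding a .Random.seed vector; draws temporarily install it.

rng_streams <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, k >= 1)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  old_kind <- RNGkind()
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", k)
  for (g in seq_len(k)) {
    streams[[g]] <- new.env(parent = emptyenv())
    streams[[g]]$seed <- s
    s <- parallel::nextRNGStream(s)
  }
  RNGkind(old_kind[1], old_kind[2], old_kind[3])
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  }
  streams
}

# evaluate expr with the stream's RNG state installed; persist advanced state
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  assign(".Random.seed", stream$seed, globalenv())
  on.exit({
    stream$seed <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
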