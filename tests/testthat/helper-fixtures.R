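# Shared fixtures: small graphs and scripted populations built in code.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
    a[e] <- 1L; a[e[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# path graph 1-2-3-4
adj_path4 <- function() adj_from_edges(4, c(1, 2, 2, 3, 3, 4))

# star with hub 1
adj_star <- function(n) adj_from_edges(n, rbind(1, 2:n))

# all-cooperate / all-defect scripted populations
fixture_all <- function(n, rounds, action = 1L, accept = "all") {
  make_fixture(matrix(action, n, rounds), accept = accept)
}

# deterministic Bernoulli graph for sweeps
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(choose(n, 2)) < p)
  a + t(a)
}

# brute-force edge-wise label correlation (doubled edge list), the
# independent oracle for choice_assortativity
assortativity_oracle <- function(adj, labels) {
  pp <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  x <- c(labels[pp[, 1]], labels[pp[, 2]])
  y <- c(labels[pp[, 2]], labels[pp[, 1]])
  suppressWarnings(stats::cor(x, y))
}

# exhaustive core-periphery oracle: enumerates every non-trivial core
# assignment, builds its explicit ideal-pattern vector (pair linked iff an
# endpoint is in the core) and takes the textbook Pearson correlation with
# the adjacency vector. The per-n pattern matrix is precomputed once; the
# correlation is evaluated from its sums, which is algebraically identical
# to cor() but lets one graph be scored against all assignments at once.
.cp_oracle_env <- new.env()

cp_oracle_patterns <- function(n) {
  key <- as.character(n)
  if (!is.null(.cp_oracle_env[[key]])) return(.cp_oracle_env[[key]])
  pp <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ids <- seq_len(2^n - 2)
  P <- sapply(ids, function(id) {
    core <- which(bitwAnd(id, bitwShiftL(1L, 0:(n - 1))) > 0)
    as.integer(pp[, 1] %in% core | pp[, 2] %in% core)
  })
  out <- list(pp = pp, P = P,
              core_size = sapply(ids, function(id)
                sum(bitwAnd(id, bitwShiftL(1L, 0:(n - 1))) > 0)))
  .cp_oracle_env[[key]] <- out
  out
}

core_periphery_oracle <- function(adj) {
  n <- nrow(adj)
  o <- cp_oracle_patterns(n)
  a <- adj[o$pp]
  m <- length(a)
  sa <- sum(a); sp <- colSums(o$P)
  sap <- as.numeric(crossprod(o$P, a))
  num <- m * sap - sa * sp
  den <- sqrt(m * sa - sa^2) * sqrt(m * sp - sp^2)
  r <- ifelse(den > 0, num / den, NA_real_)
  if (all(is.na(r))) return(list(score = -Inf, core = NULL))
  best <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & r >= best - 1e-12)
  k <- cand[which.min(o$core_size[cand])]
  list(score = r[k],
       core = which(bitwAnd(k, bitwShiftL(1L, 0:(n - 1))) > 0))
}
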