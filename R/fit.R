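# Maximum-likelihood fitting of the bot model from game logs.
#
# The cooperation model is a logistic discrete-choice model with a
# per-player Gaussian disposition theta_i shared across both branches:
# round 1 uses logit p = beta0p + beta1p * theta_i, later rounds
# logit p = beta0 + beta1*x_s + beta2*x_n + beta3*x_r + theta_i.
# The marginal likelihood integrates theta_i out by Gauss-Hermite
# quadrature; the acceptance table phi is estimated cell-wise from the
# logged accept/reject events with binomial standard errors.
#
# mu_theta is not separately identified (it shifts both branches only
# through theta and is absorbed by the intercepts), so it is fixed at 0 and
# the fitted intercepts should be read as beta0p + beta1p*mu and beta0 + mu.

# physicists' Gauss-Hermite rule via the Golub-Welsch eigendecomposition
gauss_hermite <- function(k) {
  if (k == 1) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2 * sqrt(pi))[ord])
}

# flatten the cooperation choices of one or more logs into a model frame
choice_data_from_logs <- function(logs) {
  if (inherits(logs, "coop_log")) logs <- list(logs)
  rows <- list()
  pid0 <- 0L
  for (lg in logs) {
    n <- lg$config$n_players
    for (t in seq_along(lg$records)) {
      r <- lg$records[[t]]
      if (t == 1) {
        xs <- xn <- xr <- rep(0, n)
      } else {
        # neighbourhood covariates: graph after round t-1 rewiring, decisions
        # from round t-1
        n_adj <- matrix(0L, n, n)
        e <- lg$records[[t - 1]]$edges_after
        if (length(e)) {
          e <- matrix(as.integer(e), ncol = 2)
          n_adj[e] <- 1L; n_adj[e[, 2:1, drop = FALSE]] <- 1L
        }
        prev <- lg$records[[t - 1]]$actions
        xs <- rowSums(n_adj)
        xn <- as.numeric(n_adj %*% prev)
        xr <- ifelse(xs > 0, xn / xs, 0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        player = pid0 + seq_len(n), round = t, action = r$actions,
        x_s = xs, x_n = xn, x_r = xr)
    }
    pid0 <- pid0 + n
  }
  do.call(rbind, rows)
}

# flatten the per-endpoint accept/reject events of one or more logs
accept_data_from_logs <- function(logs) {
  if (inherits(logs, "coop_log")) logs <- list(logs)
  rows <- list()
  for (lg in logs) {
    for (t in seq_along(lg$records)) {
      r <- lg$records[[t]]
      if (nrow(r$recs) == 0) next
      acts <- r$actions
      rows[[length(rows) + 1]] <- data.frame(
        valence = rep(r$recs$valence, 2),
        referent = c(acts[r$recs$j], acts[r$recs$i]),
        accepted = c(r$recs$accept_i, r$recs$accept_j))
    }
  }
  if (!length(rows)) {
    return(data.frame(valence = character(), referent = integer(),
                      accepted = logical()))
  }
  do.call(rbind, rows)
}

#' Fit the bot model to game logs
#'
#' Estimates the logistic cooperation coefficients (both branches) and the
#' disposition s.d. by maximizing the marginal likelihood with the
#' per-player disposition integrated out by Gauss-Hermite quadrature, and
#' the acceptance table phi as cell-wise frequencies of the logged
#' accept/reject events.
#'
#' @param logs A `coop_log` or list of them.
#' @param gh_points Number of quadrature nodes.
#' @param start Optional named start vector.
#' @return Object of class `bot_fit` with `print`, `summary`, `coef`,
#'   `vcov` and `logLik` methods. `coef()` returns the beta coefficients
#'   and `sigma_theta`; `$phi` holds the acceptance-table estimates (cells
#'   with no events are `NA`).
#' @export
fit_bot_params <- function(logs, gh_points = 25L, start = NULL) {
  d <- choice_data_from_logs(logs)
  if (length(unique(d$action)) < 2) {
    stop("complete separation: all logged actions are identical; ",
         "the likelihood is unbounded")
  }
  gh <- gauss_hermite(gh_points)
  wn <- gh$w / sqrt(pi)
  players <- sort(unique(d$player))
  pidx <- match(d$player, players)
  first <- d$round == 1
  X_l <- cbind(1, d$x_s, d$x_n, d$x_r)[!first, , drop = FALSE]
  a_l <- d$action[!first]; p_l <- pidx[!first]
  a_f <- d$action[first];  p_f <- pidx[first]
  nP <- length(players)

  nll <- function(par) {
    b0p <- par[1]; b1p <- par[2]; beta <- par[3:6]; sigma <- exp(par[7])
    theta <- sqrt(2) * sigma * gh$x
    eta_l0 <- as.numeric(X_l %*% beta)
    M <- matrix(0, nP, length(theta))
    for (k in seq_along(theta)) {
      ll_f <- stats::plogis((2 * a_f - 1) * (b0p + b1p * theta[k]), log.p = TRUE)
      ll_l <- stats::plogis((2 * a_l - 1) * (eta_l0 + theta[k]), log.p = TRUE)
      M[, k] <- rowsum(c(ll_f, ll_l), c(p_f, p_l))[, 1]
    }
    mx <- apply(M, 1, max)
    val <- -sum(mx + log(as.numeric(exp(M - mx) %*% wn)))
    if (!is.finite(val)) 1e10 else val
  }

  if (is.null(start)) {
    warm <- stats::glm.fit(X_l, a_l, family = stats::binomial())$coefficients
    p1 <- mean(a_f)
    start <- c(stats::qlogis(min(max(p1, 0.05), 0.95)), 1, warm, 0)
  }
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-10))
  est <- opt$par
  nm <- c("beta0p", "beta1p", "beta0", "beta1", "beta2", "beta3", "log_sigma_theta")
  names(est) <- nm
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 7, 7))
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))

  # acceptance table: cell-wise binomial estimates
  acc <- accept_data_from_logs(logs)
  cells <- data.frame(phi = paste0("phi", 0:3),
                      valence = c("delete", "delete", "add", "add"),
                      referent = c(0L, 1L, 0L, 1L))
  cells$n <- cells$k <- integer(4)
  for (r in seq_len(4)) {
    ev <- acc$valence == cells$valence[r] & acc$referent == cells$referent[r]
    cells$n[r] <- sum(ev)
    cells$k[r] <- sum(acc$accepted[ev])
  }
  cells$estimate <- ifelse(cells$n > 0, cells$k / cells$n, NA_real_)
  cells$se <- ifelse(cells$n > 0,
                     sqrt(cells$estimate * (1 - cells$estimate) / cells$n),
                     NA_real_)

  coefs <- c(est[1:6], sigma_theta = unname(exp(est[7])))
  structure(list(coefficients = coefs, par = est, se = se, vcov = vc,
                 phi = cells[c("phi", "valence", "referent", "n", "k",
                               "estimate", "se")],
                 logLik = -opt$value, n_players = nP, n_obs = nrow(d),
                 n_accept_events = nrow(acc), convergence = opt$convergence,
                 gh_points = gh_points),
            class = "bot_fit")
}

#' @export
coef.bot_fit <- function(object, ...) object$coefficients

#' @export
vcov.bot_fit <- function(object, ...) object$vcov

#' @export
logLik.bot_fit <- function(object, ...) {
  structure(object$logLik, df = 7, nobs = object$n_obs, class = "logLik")
}

#' @export
print.bot_fit <- function(x, ...) {
  cat(sprintf("Bot model fit: %d players, %d choice observations, %d acceptance events\n",
              x$n_players, x$n_obs, x$n_accept_events))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.bot_fit <- function(object, ...) {
  # delta method for sigma_theta = exp(log_sigma)
  se <- object$se
  se_sigma <- se[7] * exp(object$par[7])
  tab <- data.frame(estimate = object$coefficients,
                    std_error = c(se[1:6], se_sigma))
  cat("Cooperation model (marginal ML, Gauss-Hermite ", object$gh_points,
      " nodes):\n", sep = "")
  print(round(tab, 4))
  cat("\nAcceptance table:\n")
  print(object$phi, row.names = FALSE)
  cat(sprintf("\nlog-likelihood %.2f, optim convergence code %d\n",
              object$logLik, object$convergence))
  invisible(list(coefficients = tab, phi = object$phi))
}

#' Convert a fit back to simulation parameters
#'
#' @param fit A `bot_fit`.
#' @param phi_fallback Values used for acceptance cells with no events.
#' @return A [bot_params()] object with the fitted values (mu_theta = 0 by
#'   the identification convention).
#' @export
as_bot_params <- function(fit, phi_fallback = c(0.5, 0.5, 0.5, 0.5)) {
  cf <- coef(fit)
  phi <- fit$phi$estimate
  phi[is.na(phi)] <- phi_fallback[is.na(phi)]
  bot_params(mu_theta = 0, sigma_theta = cf[["sigma_theta"]],
             beta0p = cf[["beta0p"]], beta1p = cf[["beta1p"]],
             beta0 = cf[["beta0"]], beta1 = cf[["beta1"]],
             beta2 = cf[["beta2"]], beta3 = cf[["beta3"]], phi = phi)
}
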