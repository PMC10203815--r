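# Variational Bayesian multiple linear regression with free-energy model
# evidence, tau-grid optimization and the evidence-inflation penalty.
#
# Model: y | w, lambda ~ N(Xw, lambda^-1 I); w | alpha ~ N(0, alpha^-1 I);
# alpha ~ Gamma(a0, b0); lambda ~ Gamma(c0, d0). Mean-field factorization
# q(w) q(alpha) q(lambda), coordinate-ascent updates, free energy F as the
# evidence lower bound in nats.

VB_PRIORS <- list(a0 = 1e-2, b0 = 1e-4, c0 = 1e-2, d0 = 1e-4)

#' Variational Bayesian linear regression
#'
#' Mean-field VB for Gaussian linear regression with conjugate Gamma
#' hyperpriors on the (shared) weight precision and the noise precision.
#' The free energy is non-decreasing across iterations and approximates the
#' log model evidence.
#'
#' @param y response vector (n trials).
#' @param X design matrix including the offset column; non-offset columns
#'   are expected z-scored.
#' @param priors list with `a0`, `b0` (weight precision shape/rate) and
#'   `c0`, `d0` (noise precision shape/rate).
#' @param tol convergence tolerance on the free-energy change (default 1e-4).
#' @param max_iter maximum iterations (default 200).
#' @return list with `w_mean`, `w_cov`, `noise_precision` (posterior mean),
#'   `F` (final free energy), `F_trace`, `converged`, `iterations`.
#' @export
vb_linear_regression <- function(y, X, priors = VB_PRIORS, tol = 1e-4,
                                 max_iter = 200) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more trials than regressors")
  fit <- vb_fit_batch(crossprod(X), crossprod(X, y), sum(y^2), n,
                      priors = priors, tol = tol, max_iter = max_iter,
                      keep_trace = TRUE)
  ed <- attr(fit, "eigen")
  m <- ed$vectors %*% fit$mu[, 1]
  S <- ed$vectors %*% diag(fit$s[, 1], p, p) %*% t(ed$vectors)
  list(w_mean = drop(m), w_cov = S,
       noise_precision = fit$Elambda[1],
       weight_precision = fit$Ealpha[1],
       F = fit$F[1], F_trace = fit$F_trace[[1]],
       converged = fit$converged[1], iterations = fit$iterations)
}

# Batched VB fits sharing one design. XtY is p x J (one column per fit),
# yty length J. Works in the eigenbasis of XtX so each iteration is O(pJ).
vb_fit_batch <- function(XtX, XtY, yty, n, priors = VB_PRIORS, tol = 1e-4,
                         max_iter = 200, keep_trace = FALSE) {
  XtY <- as.matrix(XtY)
  p <- nrow(XtY)
  J <- ncol(XtY)
  stopifnot(length(yty) == J)
  ed <- eigen(XtX, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  Z <- crossprod(ed$vectors, XtY)            # p x J
  a0 <- priors$a0; b0 <- priors$b0; c0 <- priors$c0; d0 <- priors$d0
  Ealpha <- rep(1, J)
  Elambda <- n / pmax(yty, .Machine$double.eps)  # ~ 1/var(y) init
  aN <- a0 + p / 2
  cN <- c0 + n / 2
  F_old <- rep(-Inf, J)
  F_trace <- if (keep_trace) vector("list", J) else NULL
  converged <- rep(FALSE, J)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- outer(lam, Elambda) + rep(Ealpha, each = p)   # p x J
    Mu <- Z * rep(Elambda, each = p) / D               # posterior mean, eigen coords
    s <- 1 / D                                         # posterior var, eigen coords
    mm <- colSums(Mu^2)
    trS <- colSums(s)
    tr_SXtX <- colSums(s * lam)
    mXty <- colSums(Mu * Z)
    mXtXm <- colSums(Mu^2 * lam)
    R <- yty - 2 * mXty + mXtXm + tr_SXtX
    Ew2 <- mm + trS
    bN <- b0 + Ew2 / 2
    dN <- d0 + pmax(R, 0) / 2
    Ealpha <- aN / bN
    Elambda <- cN / dN
    Elog_alpha <- digamma(aN) - log(bN)
    Elog_lambda <- digamma(cN) - log(dN)
    logdetS <- -colSums(log(D))
    Fnew <-
      (n / 2) * (Elog_lambda - log(2 * pi)) - (Elambda / 2) * R +
      (p / 2) * (Elog_alpha - log(2 * pi)) - (Ealpha / 2) * Ew2 +
      a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elog_alpha - b0 * Ealpha +
      c0 * log(d0) - lgamma(c0) + (c0 - 1) * Elog_lambda - d0 * Elambda +
      (p / 2) * (1 + log(2 * pi)) + logdetS / 2 +
      gamma_entropy(aN, bN) + gamma_entropy(cN, dN)
    if (keep_trace) {
      for (j in seq_len(J)) F_trace[[j]] <- c(F_trace[[j]], Fnew[j])
    }
    dF <- Fnew - F_old
    converged <- abs(dF) < tol
    F_old <- Fnew
    if (all(converged) || iter >= max_iter) break
  }
  out <- list(F = F_old, mu = Mu, s = s, Ealpha = Ealpha, Elambda = Elambda,
              converged = converged, iterations = iter, F_trace = F_trace)
  attr(out, "eigen") <- ed
  out
}

gamma_entropy <- function(a, b) {
  a - log(b) + lgamma(a) + (1 - a) * digamma(a)
}

#' Integration half-life of a forgetting rate
#'
#' Number of stimuli after which an observation's weight has decayed to 0.5:
#' `floor(ln 2 / tau)`, capped at the run length of 600 stimuli (`tau = 0`
#' never forgets and maps to the cap).
#'
#' @param tau forgetting rate(s) >= 0.
#' @param cap maximum window (default 600, one run).
#' @return integer vector of half-lives in stimuli.
#' @export
half_life <- function(tau, cap = 600) {
  if (any(tau < 0)) stop("tau must be >= 0")
  hl <- ifelse(tau == 0, Inf, floor(log(2) / tau))
  as.integer(pmin(hl, cap))
}

#' The canonical 11-point tau grid
#' @return numeric vector of forgetting rates.
#' @export
tau_grid_default <- function() {
  c(0, 0.001, 0.0015, 0.002, 0.003, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
}

#' Optimize the forgetting rate over a grid
#'
#' Selects, for each subject and peri-stimulus time bin, the tau with the
#' highest free energy summed over channels. Ties break toward the smallest
#' tau (the grid must be ascending).
#'
#' @param F_grid array `[subject, channel, time, tau]` of free energies for
#'   one model.
#' @param tau_grid ascending grid of tau values, length = last dim of
#'   `F_grid`.
#' @return list with `tau_index` and `tau` (`subject x time` matrices) and
#'   `F_opt` (`[subject, channel, time]` at the selected tau).
#' @export
optimize_tau <- function(F_grid, tau_grid = tau_grid_default()) {
  stopifnot(length(dim(F_grid)) == 4, dim(F_grid)[4] == length(tau_grid),
            !is.unsorted(tau_grid))
  ns <- dim(F_grid)[1]; nc <- dim(F_grid)[2]; nt <- dim(F_grid)[3]
  Fsum <- apply(F_grid, c(1, 3, 4), sum)        # subject x time x tau
  tau_index <- apply(Fsum, c(1, 2), which.max)  # first max = smallest tau
  F_opt <- array(NA_real_, dim = c(ns, nc, nt))
  for (s in seq_len(ns)) for (t in seq_len(nt)) {
    F_opt[s, , t] <- F_grid[s, , t, tau_index[s, t]]
  }
  list(tau_index = tau_index,
       tau = matrix(tau_grid[tau_index], ns, nt),
       F_opt = F_opt)
}

#' Evidence-inflation penalty for tau optimization
#'
#' The average degree to which picking the best grid point inflates model
#' evidence: the mean over subjects, channels and post-stimulus time bins of
#' `F(optimized tau) - mean over the grid of F(tau)`, subtracted from the
#' optimized evidence. Applied to the Bayesian-learner models only; the TLCD
#' and null models have no tau and enter model comparison unpenalized.
#'
#' @param F_grid array `[subject, channel, time, tau]`.
#' @param F_opt array `[subject, channel, time]` at the selected tau
#'   (computed by [optimize_tau()] if missing).
#' @param tau_grid grid used (only needed when `F_opt` is missing).
#' @return list with `F_penalized`, `penalty` (scalar >= 0).
#' @export
tau_penalty <- function(F_grid, F_opt = NULL, tau_grid = tau_grid_default()) {
  if (is.null(F_opt)) F_opt <- optimize_tau(F_grid, tau_grid)$F_opt
  penalty <- mean(F_opt - apply(F_grid, c(1, 2, 3), mean))
  list(F_penalized = F_opt - penalty, penalty = penalty)
}
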