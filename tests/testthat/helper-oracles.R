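# Shared fixtures and independent oracles used across test files.

# small multi-run experiment reused by several tests
small_experiment <- function(seed = 101, n_trials = 200, n_catch = 2,
                             schedule = c("congruent_unlikely",
                                          "incongruent_unlikely", "neutral")) {
  generate_experiment(schedule, seed = seed, n_trials = n_trials,
                      n_catch = n_catch)
}

full_experiment <- function(seed = 202) {
  generate_experiment(rep(c("congruent_unlikely", "incongruent_unlikely",
                            "neutral"), 2), seed = seed)
}

# quadrature oracle for KL(Dir(a) || Dir(b)), K = 2 or 3, via direct
# integration of the KL integrand over the simplex
kl_dirichlet_quadrature <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) %in% c(2, 3))
  ldir <- function(x, al) {
    lgamma(sum(al)) - sum(lgamma(al)) + sum((al - 1) * log(x))
  }
  if (length(a) == 2) {
    f <- function(x) {
      vapply(x, function(xi) {
        p <- c(xi, 1 - xi)
        exp(ldir(p, a)) * (ldir(p, a) - ldir(p, b))
      }, numeric(1))
    }
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  } else {
    inner <- function(x1) {
      vapply(x1, function(u) {
        stats::integrate(function(x2) {
          vapply(x2, function(v) {
            p <- c(u, v, 1 - u - v)
            if (min(p) <= 0) return(0)
            exp(ldir(p, a)) * (ldir(p, a) - ldir(p, b))
          }, numeric(1))
        }, 0, 1 - u, rel.tol = 1e-9)$value
      }, numeric(1))
    }
    stats::integrate(inner, 0, 1, rel.tol = 1e-8)$value
  }
}

# step-by-step observer oracle using the public single-step API
observer_trace_oracle <- function(ctx, out, n_ctx, n_out, tau, alpha0) {
  belief <- dircat_belief(as.character(seq_len(n_ctx)), n_out,
                          alpha0 = alpha0, tau = tau)
  res <- data.frame(PS = numeric(0), BS = numeric(0), CS = numeric(0))
  for (t in seq_along(ctx)) {
    cx <- as.character(ctx[t])
    prior <- decay_belief(belief)          # decay, read out, increment
    ps <- surprise_ps(prior, cx, out[t])
    cs <- surprise_cs(prior, cx, out[t])
    post <- update_belief(prior, cx, out[t], decay = FALSE)
    bs <- surprise_bs(prior, post, cx)
    res <- rbind(res, data.frame(PS = ps, BS = bs, CS = cs))
    belief <- post
  }
  res
}

# brute-force annotation rescan: deviant flags and train lengths from a raw
# per-modality sequence by explicit counting
annotate_oracle_modality <- function(x) {
  n <- length(x)
  dev <- rep(NA, n)
  train <- rep(NA_integer_, n)
  for (t in 2:n) {
    dev[t] <- x[t] != x[t - 1]
    k <- 0
    while (t - 1 - k >= 1 && x[t - 1 - k] == x[t - 1]) k <- k + 1
    train[t] <- k
  }
  list(dev = dev, train = train)
}

# direct (non-eigen) VB implementation used as an oracle for the batched
# fitter: plain coordinate ascent with explicit matrix solves
vb_oracle <- function(y, X, priors = list(a0 = 1e-2, b0 = 1e-4,
                                          c0 = 1e-2, d0 = 1e-4),
                      n_iter = 300) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  Ea <- 1; El <- n / yty
  aN <- priors$a0 + p / 2; cN <- priors$c0 + n / 2
  Fh <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    S <- solve(Ea * diag(p) + El * XtX)
    m <- El * S %*% Xty
    Ew2 <- sum(m^2) + sum(diag(S))
    R <- yty - 2 * sum(m * Xty) + sum((m %*% t(m) + S) * XtX)
    bN <- priors$b0 + Ew2 / 2
    dN <- priors$d0 + R / 2
    Ea <- aN / bN; El <- cN / dN
    Ela <- digamma(aN) - log(bN); Ell <- digamma(cN) - log(dN)
    gent <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)
    Fh[i] <- (n / 2) * (Ell - log(2 * pi)) - (El / 2) * R +
      (p / 2) * (Ela - log(2 * pi)) - (Ea / 2) * Ew2 +
      priors$a0 * log(priors$b0) - lgamma(priors$a0) +
      (priors$a0 - 1) * Ela - priors$b0 * Ea +
      priors$c0 * log(priors$d0) - lgamma(priors$c0) +
      (priors$c0 - 1) * Ell - priors$d0 * El +
      (p / 2) * (1 + log(2 * pi)) + 0.5 * determinant(S)$modulus +
      gent(aN, bN) + gent(cN, dN)
  }
  list(F = Fh[n_iter], m = drop(m), F_trace = Fh)
}

# aov()-based oracle for the balanced two-way repeated-measures ANOVA
rm_anova2_cell_oracle <- function(y) {
  n <- dim(y)[1]
  d <- expand.grid(s = factor(seq_len(n)), a = factor(1:3), b = factor(1:3))
  d$y <- as.vector(y)
  fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = d)
  sm <- summary(fit)
  getF <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  fa <- getF("Error: s:a", "^a$")
  fb <- getF("Error: s:b", "^b$")
  fab <- getF("Error: s:a:b", "^a:b$")
  list(F = c(fa["F"], fb["F"], fab["F"]), p = c(fa["p"], fb["p"], fab["p"]))
}
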