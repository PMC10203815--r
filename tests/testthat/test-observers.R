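# Dirichlet-Categorical observers, surprise read-outs, TLCD baseline,
# regressor construction

test_that("belief updates implement decay-then-increment", {
  b <- dircat_belief(c("c0", "c1"), 2)
  b1 <- update_belief(b, "c0", 2)
  expect_equal(unname(b1$counts["c0", ]), c(0, 1))
  expect_equal(unname(b1$counts["c1", ]), c(0, 0))
  expect_equal(unname(b$counts["c0", ]), c(0, 0))  # input unchanged
  # tau = ln 2: a count of 1 decays to 0.5 after one subsequent observation
  bh <- dircat_belief("c", 2, tau = log(2))
  bh <- update_belief(bh, "c", 1)
  bh <- update_belief(bh, "c", 2)
  expect_equal(unname(bh$counts["c", ]), c(0.5, 1))
  # large tau: by the next read-out (decay first), prediction is flat
  bt <- dircat_belief("c", 2, tau = 50)
  for (i in 1:20) bt <- update_belief(bt, "c", 1)
  expect_equal(unname(predictive_prob(decay_belief(bt), "c")), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_error(update_belief(b, "nope", 1))
  expect_error(update_belief(b, "c0", 3))
})

test_that("predictive probabilities follow the Laplace rule", {
  b <- dircat_belief("c", 2)
  expect_equal(unname(predictive_prob(b, "c")), c(0.5, 0.5))
  b <- update_belief(b, "c", 1)
  expect_equal(unname(predictive_prob(b, "c")), c(2 / 3, 1 / 3))
  b4 <- dircat_belief("c", 4)
  expect_equal(sum(predictive_prob(b4, "c")), 1)
})

test_that("kl_dirichlet matches the simplex-quadrature oracle on a 10-case panel", {
  panel <- list(
    list(a = c(1, 1), b = c(2, 1)), list(a = c(2, 1), b = c(1, 1)),
    list(a = c(1, 1), b = c(5, 1)), list(a = c(3, 4), b = c(4, 3)),
    list(a = c(0.5, 2), b = c(2, 0.5)), list(a = c(10, 2), b = c(2, 10)),
    list(a = c(1, 1, 1), b = c(2, 1, 1)), list(a = c(2, 3, 4), b = c(4, 3, 2)),
    list(a = c(1, 1, 1), b = c(1, 1, 5)), list(a = c(5, 1, 2), b = c(1, 2, 5)))
  for (case in panel) {
    expect_equal(kl_dirichlet(case$a, case$b),
                 kl_dirichlet_quadrature(case$a, case$b), tolerance = 1e-5)
  }
  expect_equal(kl_dirichlet(c(2, 3), c(2, 3)), 0)
  expect_true(kl_dirichlet(c(1, 1), c(5, 1)) != kl_dirichlet(c(5, 1), c(1, 1)))
  expect_error(kl_dirichlet(c(1, -1), c(1, 1)))
})

test_that("surprise read-outs satisfy their closed-form examples", {
  b <- dircat_belief("c", 2)
  expect_equal(surprise_ps(b, "c", 1), log(2))
  expect_equal(surprise_ps(dircat_belief("c", 4), "c", 2), log(4))
  # first observation: BS equals the quadrature value for Dir(1,1)->Dir(2,1)
  post <- update_belief(b, "c", 1)
  expect_equal(surprise_bs(b, post, "c"),
               kl_dirichlet_quadrature(c(1, 1), c(2, 1)), tolerance = 1e-5)
  expect_equal(surprise_bs(b, b, "c"), 0)  # no update
  # flat prior: CS equals BS exactly
  expect_equal(surprise_cs(b, "c", 1), surprise_bs(b, post, "c"),
               tolerance = 1e-12)
  # committed wrong prior is more surprising than a flat one
  b_wrong <- b
  b_wrong$counts["c", ] <- c(50, 0)
  expect_gt(surprise_cs(b_wrong, "c", 2), surprise_cs(b, "c", 2))
  expect_gte(surprise_cs(b_wrong, "c", 2), 0)
})

test_that("vectorized observers agree with the step-by-step oracle", {
  set.seed(14)
  x <- rbinom(40, 1, 0.4)
  for (tau in c(0, 0.1)) {
    tr <- run_unimodal_observer(x, tau = tau)
    oracle <- observer_trace_oracle(x[-length(x)] + 1L, x[-1] + 1L, 2, 2,
                                    tau, 1)
    expect_equal(tr$PS, oracle$PS, tolerance = 1e-12)
    expect_equal(tr$BS, oracle$BS, tolerance = 1e-12)
    expect_equal(tr$CS, oracle$CS, tolerance = 1e-12)
  }
  cong <- as.logical(rbinom(39, 1, 0.5))
  d <- as.integer(x[-1] != x[-length(x)])
  tr <- run_crossmodal_observer(x, cong, tau = 0.05)
  oracle <- observer_trace_oracle(ifelse(cong, 1L, 2L), d + 1L, 2, 2, 0.05, 1)
  expect_equal(tr$PS, oracle$PS, tolerance = 1e-12)
  expect_equal(tr$BS, oracle$BS, tolerance = 1e-12)
  expect_equal(tr$CS, oracle$CS, tolerance = 1e-12)
})

test_that("unimodal observer learns: constant, alternating and first-trial behavior", {
  tr <- run_unimodal_observer(rep(1, 30))
  expect_equal(tr$PS[1], log(2))  # flat first prediction from the context
  expect_true(all(diff(tr$PS) < 0))  # strictly decreasing at tau = 0
  alt <- run_unimodal_observer(rep(c(0, 1), 30))
  nT <- nrow(alt)
  expect_true(all(alt$PS[(nT - 10):nT] < log(2)))  # alternation learned
  expect_error(run_unimodal_observer(c(1)))
})

test_that("cross-modal observer is consistent for generated sequences", {
  tab <- generate_run(build_transition_matrix("congruent_unlikely"),
                      20000, 0, seed = 77)
  obs <- as.matrix(tab[, c("obs_A", "obs_S", "obs_V")])
  n <- nrow(obs)
  cong <- obs[-n, 2] == obs[-n, 3]
  tr <- run_crossmodal_observer(obs[, 1], cong, tau = 0)
  # learned P(alternate | congruent) from final counts ~ 0.025
  last_cong <- max(which(tr$context == 1))
  p_alt <- 1 - tr$p_pred[last_cong]
  p_alt <- if (tr$outcome[last_cong] == 2) tr$p_pred[last_cong] else p_alt
  n_cong <- sum(tr$context == 1)
  expect_lt(abs(p_alt - 0.025), 3 * sqrt(0.025 * 0.975 / n_cong) + 2 / n_cong)
  # all-congruent context reduces to a single-context repetition learner
  tr1 <- run_crossmodal_observer(obs[1:500, 1], rep(TRUE, 499), tau = 0)
  b <- dircat_belief("all", 2)
  d <- as.integer(obs[2:500, 1] != obs[1:499, 1])
  ps <- numeric(499)
  for (t in seq_along(d)) {
    ps[t] <- surprise_ps(b, "all", d[t] + 1L)
    b <- update_belief(b, "all", d[t] + 1L)
  }
  expect_equal(tr1$PS, ps, tolerance = 1e-12)
})

test_that("after learning, a mispredicted change is more surprising than a predicted one", {
  tab <- generate_run(build_transition_matrix("congruent_unlikely"),
                      5000, 0, seed = 99)
  ann <- annotate(tab)
  obs <- as.matrix(tab[, c("obs_A", "obs_S", "obs_V")])
  n <- nrow(obs)
  cong <- obs[-n, 2] == obs[-n, 3]
  tr <- run_crossmodal_observer(obs[, 1], cong, tau = 0)
  pr <- ann$pred_A[-1]
  dv <- ann$dev_A[-1]
  late <- seq_len(nrow(tr)) > 1000
  mis <- mean(tr$PS[late & dv & pr == "mispredicted"])
  prd <- mean(tr$PS[late & dv & pr == "predicted"])
  expect_gt(mis, prd)
})

test_that("TLCD recursion matches its printed definition", {
  tr <- run_tlcd(c(0, 0, 0, 1))
  expect_equal(tr$output, c(-1, -2, 2))
  expect_equal(tr$d, c(1, 1, 0))
  expect_equal(tr$c, c(1, 2, 0))
  # all-repeat: output at t = n is -(n-1)
  n <- 12
  tr2 <- run_tlcd(rep(1, n))
  expect_equal(tr2$output[n - 1], -(n - 1))
  # alternating: deviant outputs all 0
  tr3 <- run_tlcd(rep(c(0, 1), 10))
  expect_true(all(tr3$output == 0))
  # invariant c_t = d_t (c_{t-1} + d_t)
  set.seed(3)
  x <- rbinom(100, 1, 0.5)
  tr4 <- run_tlcd(x)
  c_prev <- c(0, tr4$c[-nrow(tr4)])
  expect_equal(tr4$c, tr4$d * (c_prev + tr4$d))
  expect_equal(tr4$output, ifelse(tr4$d == 1, -tr4$c, c_prev))
})

test_that("surprise values are nonnegative across a whole experiment", {
  exper <- small_experiment(seed = 123)
  for (fam in c("um-ps", "um-bs", "um-cs")) {
    X <- build_regressors(exper, fam, tau = 0.05, z_score = FALSE)
    expect_true(all(X >= 0))
  }
  X <- build_regressors(exper, "ucm-cs", tau = 0, z_score = FALSE)
  expect_true(all(X >= 0))
})

test_that("tau = 0 recovers exact conjugate counting", {
  set.seed(8)
  x <- rbinom(200, 1, 0.5)
  tr <- run_unimodal_observer(x, tau = 0)
  # brute-force transition counts before the final trial
  n <- length(x)
  ctx <- x[n - 1]
  trans <- cbind(x[-n], x[-1])[seq_len(n - 2), , drop = FALSE]
  counts <- table(factor(trans[trans[, 1] == ctx, 2], levels = 0:1))
  p_expected <- (1 + counts[as.character(x[n])]) / (2 + sum(counts))
  expect_equal(tr$p_pred[n - 1], unname(p_expected), tolerance = 1e-12)
})

test_that("build_regressors: shapes, z-scoring, shared unimodal columns", {
  exper <- small_experiment(seed = 31)
  Xum <- build_regressors(exper, "um-bs", tau = 0.05)
  Xucm <- build_regressors(exper, "ucm-bs", tau = 0.05)
  expect_equal(ncol(Xum), 3)
  expect_equal(ncol(Xucm), 6)
  expect_equal(colnames(Xucm), c("um_A", "um_S", "um_V", "cm_A", "cm_S", "cm_V"))
  expect_equal(unname(Xucm[, 1:3]), unname(Xum), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(Xucm)) < 1e-10))
  expect_true(all(abs(apply(Xucm, 2, sd) - 1) < 1e-10))
  # included trials = non-catch minus one per run
  n_expected <- sum(!exper$is_catch) - length(unique(exper$run))
  expect_equal(nrow(Xucm), n_expected)
  Xt <- build_regressors(exper, "tlcd")
  expect_equal(ncol(Xt), 3)
  # zero-variance regressor errors: an alternating sequence makes TLCD flat
  tab <- data.frame(run = 1L, trial = 1:20, setting = "neutral",
                    obs_A = rep(c(0, 1), 10), obs_S = rep(c(0, 1), 10),
                    obs_V = rep(c(0, 1), 10), is_catch = FALSE,
                    catch_target = "none")
  class(tab) <- c("trial_table", "data.frame")
  expect_error(build_regressors(tab, "tlcd"), "zero-variance")
})
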