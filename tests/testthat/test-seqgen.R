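# sequence generator: transition matrices, stationary checks, runs,
# annotation, empirical change probabilities

test_that("transition matrices reproduce the printed conditional probabilities", {
  P <- build_transition_matrix("congruent_unlikely")$matrix
  expect_equal(P["000", "100"], 0.025)  # S,V congruent -> change unlikely
  expect_equal(P["100", "000"], 0.025)
  expect_equal(P["011", "111"], 0.025)
  expect_equal(P["010", "110"], 0.15)   # S,V incongruent -> change likely
  expect_equal(P["001", "101"], 0.15)
  Q <- build_transition_matrix("incongruent_unlikely")$matrix
  expect_equal(Q["010", "110"], 0.025)
  expect_equal(Q["000", "100"], 0.15)
  N <- build_transition_matrix("neutral")$matrix
  single <- which(N > 0 & row(N) != col(N))
  expect_true(all(N[single] == 0.0875))
  expect_equal(N["000", "000"], 1 - 3 * 0.0875)
})

test_that("rows are stochastic and multimodal changes have probability zero", {
  ham <- outer(0:7, 0:7, function(a, b) {
    x <- state_to_obs(a); y <- state_to_obs(b)
    rowSums(abs(matrix(x, length(a), 3) - matrix(y, length(b), 3)))
  })
  for (s in c("congruent_unlikely", "incongruent_unlikely", "neutral")) {
    P <- build_transition_matrix(s)$matrix
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(P[ham >= 2] == 0))
    expect_true(all(diag(P) > 0))
  }
})

test_that("invalid settings and probabilities error", {
  expect_error(build_transition_matrix("bogus"))
  expect_error(build_transition_matrix("neutral", p_neutral = 0.4))
  expect_error(build_transition_matrix("neutral", p_neutral = 0))
})

test_that("stationary distribution matches a brute-force power oracle", {
  for (s in c("congruent_unlikely", "incongruent_unlikely", "neutral")) {
    model <- build_transition_matrix(s)
    pi_hat <- stationary_distribution(model)
    # oracle: many-step transition from an arbitrary start
    Pk <- diag(8)
    for (i in 1:400) Pk <- Pk %*% model$matrix
    expect_equal(unname(pi_hat), unname(Pk[3, ]), tolerance = 1e-10)
    expect_equal(sum(pi_hat), 1)
    expect_true(all(pi_hat >= 0))
  }
  # symmetric settings: uniform; mass split of the derived example
  pi_cu <- stationary_distribution(build_transition_matrix("congruent_unlikely"))
  expect_equal(pi_cu[["000"]] + pi_cu[["111"]], 0.25, tolerance = 1e-10)
  expect_equal(sum(pi_cu[c("001", "010", "011", "100", "101", "110")]), 0.75,
               tolerance = 1e-10)
  pi_n <- stationary_distribution(build_transition_matrix("neutral"))
  expect_equal(unname(pi_n), rep(1 / 8, 8), tolerance = 1e-10)
})

test_that("generate_run bookkeeping: rows, catch trials, reproducibility", {
  model <- build_transition_matrix("neutral")
  tab <- generate_run(model, 600, 6, seed = 11)
  expect_s3_class(tab, "trial_table")
  expect_equal(nrow(tab), 606)
  expect_equal(sum(tab$is_catch), 6)
  expect_false(tab$is_catch[1])
  expect_true(all(is.na(tab$obs_A[tab$is_catch])))
  expect_true(all(tab$catch_target[tab$is_catch] %in% c("A", "T", "V")))
  expect_identical(tab, generate_run(model, 600, 6, seed = 11))
  expect_false(identical(tab, generate_run(model, 600, 6, seed = 12)))
  expect_error(generate_run(model, 600, 6))
})

test_that("consecutive non-catch trials never differ in more than one modality", {
  for (s in c("congruent_unlikely", "neutral")) {
    tab <- generate_run(build_transition_matrix(s), 400, 4, seed = 5)
    obs <- as.matrix(tab[!tab$is_catch, c("obs_A", "obs_S", "obs_V")])
    dif <- rowSums(abs(obs[-1, ] - obs[-nrow(obs), ]))
    expect_true(all(dif <= 1))
  }
})

test_that("generator ergodicity: state frequencies match the stationary law", {
  model <- build_transition_matrix("congruent_unlikely")
  tabs <- lapply(1:20, function(i) generate_run(model, 600, 0, seed = 300 + i))
  obs <- do.call(rbind, lapply(tabs, function(t) {
    as.matrix(t[, c("obs_A", "obs_S", "obs_V")])
  }))
  states <- obs_to_state(obs)
  freq <- tabulate(states + 1, 8) / length(states)
  pi_hat <- stationary_distribution(model)
  se <- sqrt(pi_hat * (1 - pi_hat) / length(states))
  expect_true(all(abs(freq - pi_hat) <= 3 * se))
})

test_that("empirical conditional change frequencies converge to the nominal parameters", {
  model <- build_transition_matrix("congruent_unlikely")
  tabs <- lapply(1:30, function(i) generate_run(model, 600, 0, seed = 700 + i))
  tab <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]; t$run <- i; t
  }))
  class(tab) <- c("trial_table", "data.frame")
  probs <- empirical_change_probs(tab)
  pc <- probs[probs$context == "congruent", ]
  pi <- probs[probs$context == "incongruent", ]
  expect_lt(abs(pc$p_change - 0.025), 3 * sqrt(0.025 * 0.975 / pc$n))
  expect_lt(abs(pi$p_change - 0.15), 3 * sqrt(0.15 * 0.85 / pi$n))
  # marginal change probability under the stationary law is 0.0875
  pa <- probs[probs$context == "any", ]
  expect_lt(abs(pa$p_change - 0.0875), 3 * sqrt(0.0875 * 0.9125 / pa$n))
})

test_that("generate_experiment builds six independent runs deterministically", {
  tab <- full_experiment(seed = 9)
  expect_equal(sum(!tab$is_catch), 3600)
  expect_equal(length(unique(tab$run)), 6)
  sched <- attr(tab, "schedule")
  expect_equal(sort(table(sched)), sort(table(rep(SETTINGS <- c(
    "congruent_unlikely", "incongruent_unlikely", "neutral"), 2))),
    ignore_attr = TRUE)
  # per-run setting label matches the schedule
  lab <- tapply(tab$setting, tab$run, function(x) unique(x))
  expect_equal(as.vector(unlist(lab)), sched)
  expect_identical(tab, full_experiment(seed = 9))
  expect_error(generate_experiment(c("neutral", "bogus"), seed = 1))
})

test_that("annotate reproduces the worked example and the brute-force rescan", {
  # hand example in one modality: 0,0,0,1,1
  tab <- data.frame(run = 1L, trial = 1:5, setting = "neutral",
                    obs_A = c(0, 0, 0, 1, 1), obs_S = 0, obs_V = 0,
                    is_catch = FALSE, catch_target = "none")
  class(tab) <- c("trial_table", "data.frame")
  ann <- annotate(tab)
  expect_equal(ann$dev_A, c(NA, FALSE, FALSE, TRUE, FALSE))
  expect_equal(ann$train_A, c(NA, 1L, 2L, 3L, 1L))
  expect_equal(ann$global_status,
               c(NA, "global_standard", "global_standard", "global_deviant",
                 "global_standard"))
  # train bins
  expect_equal(train_bin(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 20)),
               c("1", "2", "3", "4-5", "4-5", "6-8", "6-8", "6-8", ">8", ">8"))
  # brute-force rescan on generated data
  run <- generate_run(build_transition_matrix("congruent_unlikely"), 300, 3,
                      seed = 21)
  ann <- annotate(run)
  obs <- run[!run$is_catch, c("obs_A", "obs_S", "obs_V")]
  for (m in c("A", "S", "V")) {
    oracle <- annotate_oracle_modality(obs[[paste0("obs_", m)]])
    expect_equal(ann[[paste0("dev_", m)]], oracle$dev)
    expect_equal(ann[[paste0("train_", m)]], oracle$train)
  }
  # deterministic / idempotent
  expect_identical(ann, annotate(run))
  expect_error(annotate(tab[1, ]))
})

test_that("deviant train length equals the length of the preceding standard run", {
  run <- generate_run(build_transition_matrix("neutral"), 400, 0, seed = 33)
  ann <- annotate(run)
  for (m in c("A", "S", "V")) {
    dv <- ann[[paste0("dev_", m)]]
    tr <- ann[[paste0("train_", m)]]
    devs <- which(dv %in% TRUE)
    for (t in devs[devs > 2]) {
      # preceding standard run: trail back over non-deviant trials
      k <- t - 1
      len <- 1
      while (k > 1 && isFALSE(dv[k])) {
        len <- len + 1
        k <- k - 1
      }
      if (k == 1) next  # run-start truncation: train counts observed trials
      expect_equal(tr[t], len)
    }
    # global deviant iff any modality deviant
  }
  gd <- ann$global_status == "global_deviant"
  any_dev <- ann$dev_A | ann$dev_S | ann$dev_V
  expect_equal(gd[-1], any_dev[-1])
})

test_that("predictability labels follow setting, congruency and event type", {
  exper <- small_experiment(seed = 55)
  ann <- annotate(exper)
  for (m in c("A", "S", "V")) {
    pr <- ann[[paste0("pred_", m)]]
    cg <- ann[[paste0("congr_", m)]]
    dv <- ann[[paste0("dev_", m)]]
    neutral <- ann$setting == "neutral"
    ok <- !is.na(pr)
    expect_true(all(pr[neutral & ok] == "unpredictable"))
    expect_false(any(pr[!neutral & ok] == "unpredictable"))
    # congruent_unlikely: a change while others are congruent is mispredicted
    sel <- ann$setting == "congruent_unlikely" & ok & dv & cg
    expect_true(all(pr[sel] == "mispredicted"))
    # ... and a repetition in the same context is predicted
    sel2 <- ann$setting == "congruent_unlikely" & ok & !dv & cg
    expect_true(all(pr[sel2] == "predicted"))
    # incongruent_unlikely: change while others congruent is the likely event
    sel3 <- ann$setting == "incongruent_unlikely" & ok & dv & cg
    expect_true(all(pr[sel3] == "predicted"))
  }
})

test_that("empirical_change_probs handles degenerate tables", {
  tab <- data.frame(run = 1L, trial = 1:10, setting = "neutral",
                    obs_A = 1, obs_S = 0, obs_V = 1,
                    is_catch = FALSE, catch_target = "none")
  class(tab) <- c("trial_table", "data.frame")
  probs <- empirical_change_probs(tab)
  expect_equal(probs$p_change[probs$context == "any"], 0)
  # for modality A the others (S=0, V=1) are always incongruent, so the
  # congruent cell is empty and flagged NA
  by_mod <- empirical_change_probs(tab, pooled = FALSE)
  cellA <- by_mod[by_mod$modality == "A" & by_mod$context == "congruent", ]
  expect_true(is.na(cellA$p_change))
  expect_equal(cellA$n, 0)
})
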