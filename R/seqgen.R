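#' @importFrom stats rnorm runif filter integrate pbeta pgamma dgamma qt pt pf
#' @importFrom utils head tail
NULL

MODALITIES <- c("A", "S", "V")
SETTINGS <- c("congruent_unlikely", "incongruent_unlikely", "neutral")
TRAIN_BINS <- c("1", "2", "3", "4-5", "6-8", ">8")
GLOBAL_BINS <- c("1", "2", "3", ">3")

#' Decode state index into binary observation triplet
#'
#' States 0..7 encode the (A, S, V) intensity combination as binary digits
#' with the auditory bit most significant.
#'
#' @param state integer vector of states in 0..7.
#' @return matrix with columns A, S, V of 0/1 values.
#' @export
state_to_obs <- function(state) {
  stopifnot(all(state >= 0 & state <= 7))
  cbind(A = (state %/% 4) %% 2, S = (state %/% 2) %% 2, V = state %% 2)
}

#' Encode observation triplet into state index
#'
#' @param obs matrix (or vector) of 0/1 values with columns A, S, V.
#' @return integer vector of states in 0..7.
#' @export
obs_to_state <- function(obs) {
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 3)
  as.integer(obs[, 1] * 4 + obs[, 2] * 2 + obs[, 3])
}

#' Build the 8-state transition matrix for a probability setting
#'
#' Each row corresponds to the previous tri-modal stimulus combination.
#' Within a row, exactly three off-diagonal entries are nonzero: the
#' single-modality changes. Each gets the conditional change probability
#' determined by the congruency of the other two modalities and the chosen
#' setting; simultaneous changes of two or three modalities have probability
#' zero and the diagonal carries the remainder (tri-modal repetition).
#'
#' @param setting one of `"congruent_unlikely"` (change is rare when the
#'   other two modalities are congruent), `"incongruent_unlikely"` (rare when
#'   incongruent) or `"neutral"` (no cross-modal dependence).
#' @param p_low,p_high,p_neutral conditional change probabilities; defaults
#'   0.025 / 0.15 / 0.0875.
#' @return object of class `transition_model`: list with `setting`, `matrix`
#'   (8x8 row-stochastic) and `change_probs`.
#' @export
build_transition_matrix <- function(setting, p_low = 0.025, p_high = 0.15,
                                    p_neutral = 0.0875) {
  setting <- match.arg(setting, SETTINGS)
  for (p in c(p_low, p_high, p_neutral)) {
    if (!is.finite(p) || p <= 0 || p > 1 / 3) {
      stop("change probabilities must lie in (0, 1/3] to keep rows valid")
    }
  }
  P <- matrix(0, 8, 8, dimnames = list(state_labels(), state_labels()))
  for (s in 0:7) {
    b <- drop(state_to_obs(s))
    for (m in 1:3) {
      others <- b[-m]
      cong <- others[1] == others[2]
      p <- switch(setting,
        congruent_unlikely   = if (cong) p_low else p_high,
        incongruent_unlikely = if (cong) p_high else p_low,
        neutral              = p_neutral
      )
      tgt <- b
      tgt[m] <- 1 - tgt[m]
      P[s + 1, obs_to_state(tgt) + 1] <- p
    }
    P[s + 1, s + 1] <- 1 - sum(P[s + 1, ])
  }
  if (any(diag(P) < 0)) stop("diagonal entries negative; probabilities too large")
  structure(
    list(setting = setting, matrix = P,
         change_probs = c(
           p_change_given_congruent = switch(setting,
             congruent_unlikely = p_low, incongruent_unlikely = p_high,
             neutral = p_neutral),
           p_change_given_incongruent = switch(setting,
             congruent_unlikely = p_high, incongruent_unlikely = p_low,
             neutral = p_neutral))),
    class = "transition_model")
}

state_labels <- function() {
  apply(state_to_obs(0:7), 1, paste, collapse = "")
}

#' Stationary distribution of a transition model
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one. Used as an internal validation oracle for the generator.
#'
#' @param model a `transition_model`.
#' @param tol eigenvalue tolerance.
#' @return numeric vector of length 8 summing to 1.
#' @export
stationary_distribution <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "transition_model"))
  e <- eigen(t(model$matrix))
  i <- which(abs(e$values - 1) < tol)
  if (length(i) != 1) stop("transition matrix is not ergodic")
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -tol)) stop("invalid stationary vector")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), state_labels())
}

#' Generate one run of a tri-modal roving sequence
#'
#' Draws the first combination uniformly from the 8 states, then follows the
#' Markov chain for `n_trials` stimulus presentations. `n_catch` catch trials
#' are inserted at distinct uniformly random positions (never the first row);
#' catch trials carry no stimulus and the stimulus chain continues across
#' them.
#'
#' @param model a `transition_model`.
#' @param n_trials number of stimulus trials (default 600).
#' @param n_catch number of catch trials (default 6, i.e. one percent).
#' @param seed integer seed; required for reproducibility.
#' @param run_id run identifier stored in the table.
#' @return a `trial_table` data.frame with columns `run`, `trial`, `setting`,
#'   `obs_A`, `obs_S`, `obs_V`, `is_catch`, `catch_target`. Stimulus columns
#'   are `NA` on catch rows.
#' @export
generate_run <- function(model, n_trials = 600, n_catch = 6, seed,
                         run_id = 1L) {
  stopifnot(inherits(model, "transition_model"), n_catch < n_trials)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  states <- integer(n_trials)
  states[1] <- sample.int(8, 1) - 1L
  P <- model$matrix
  for (t in 2:n_trials) {
    states[t] <- sample.int(8, 1, prob = P[states[t - 1] + 1, ]) - 1L
  }
  n_rows <- n_trials + n_catch
  catch_pos <- if (n_catch > 0) sort(sample(2:n_rows, n_catch)) else integer(0)
  is_catch <- rep(FALSE, n_rows)
  is_catch[catch_pos] <- TRUE
  obs <- matrix(NA_integer_, n_rows, 3)
  obs[!is_catch, ] <- state_to_obs(states)
  catch_target <- rep("none", n_rows)
  if (n_catch > 0) {
    catch_target[catch_pos] <- sample(c("A", "T", "V"), n_catch, replace = TRUE)
  }
  tab <- data.frame(
    run = run_id, trial = seq_len(n_rows), setting = model$setting,
    obs_A = obs[, 1], obs_S = obs[, 2], obs_V = obs[, 3],
    is_catch = is_catch, catch_target = catch_target,
    stringsAsFactors = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Generate a full experiment of six runs
#'
#' @param settings_schedule character vector of 6 setting labels containing
#'   each of the three settings exactly twice; `NULL` draws a random order.
#' @param seed master integer seed; per-run sub-seeds are derived from it.
#' @param n_trials,n_catch per-run sizes.
#' @param p_low,p_high,p_neutral nominal change probabilities.
#' @return concatenated `trial_table` with run ids 1..6.
#' @export
generate_experiment <- function(settings_schedule = NULL, seed,
                                n_trials = 600, n_catch = 6,
                                p_low = 0.025, p_high = 0.15,
                                p_neutral = 0.0875) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (is.null(settings_schedule)) {
    set.seed(seed)
    settings_schedule <- sample(rep(SETTINGS, 2))
  } else if (any(is.na(match(settings_schedule, SETTINGS)))) {
    stop("invalid setting label in schedule")
  }
  models <- lapply(SETTINGS, build_transition_matrix,
                   p_low = p_low, p_high = p_high, p_neutral = p_neutral)
  names(models) <- SETTINGS
  runs <- lapply(seq_along(settings_schedule), function(r) {
    generate_run(models[[settings_schedule[r]]], n_trials, n_catch,
                 seed = derive_seed(seed, r), run_id = r)
  })
  tab <- do.call(rbind, runs)
  rownames(tab) <- NULL
  class(tab) <- c("trial_table", "data.frame")
  attr(tab, "schedule") <- settings_schedule
  attr(tab, "probs") <- c(p_low = p_low, p_high = p_high, p_neutral = p_neutral)
  attr(tab, "seed") <- seed
  tab
}

#' Derive a deterministic 32-bit sub-seed from a master seed
#'
#' Linear-congruential mixing keeps every stage's stream reproducible from
#' one master seed while staying below 2^31.
#'
#' @param seed master integer seed.
#' @param k stream index.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Annotate a trial table
#'
#' Computes per trial x modality deviant flags, train lengths and bins,
#' other-modality congruency at t-1, predictability labels, and global
#' standard/deviant status with global train bins. Catch rows are dropped;
#' counters reset at run boundaries; the first stimulus trial of each run is
#' kept but carries `NA` annotations (excluded from regressions downstream).
#'
#' @param table a `trial_table` (single- or multi-run).
#' @return data.frame of class `trial_annotation`, one row per non-catch
#'   trial, with per-modality columns `dev_<m>`, `train_<m>`, `bin_<m>`,
#'   `congr_<m>`, `pred_<m>` and global columns `global_status`,
#'   `global_train`, `global_bin`, plus `included` flagging rows that enter
#'   regressions (all non-first trials).
#' @export
annotate <- function(table) {
  stopifnot(is.data.frame(table))
  tab <- table[!table$is_catch, , drop = FALSE]
  if (nrow(tab) < 2) stop("need at least 2 non-catch trials")
  out <- do.call(rbind, lapply(split(tab, tab$run), annotate_run))
  rownames(out) <- NULL
  class(out) <- c("trial_annotation", "data.frame")
  out
}

annotate_run <- function(tab) {
  n <- nrow(tab)
  obs <- as.matrix(tab[, c("obs_A", "obs_S", "obs_V")])
  ann <- data.frame(run = tab$run, trial = tab$trial, setting = tab$setting)
  dev <- matrix(NA, n, 3)
  train <- matrix(NA_integer_, n, 3)
  congr <- matrix(NA, n, 3)
  pred <- matrix(NA_character_, n, 3)
  for (m in 1:3) {
    x <- obs[, m]
    dv <- c(NA, x[-1] != x[-n])
    # run-length of the value ending at t-1 == trials since last change
    last_change <- cummax(ifelse(c(FALSE, dv[-1]), seq_len(n), 1L))
    tr <- seq_len(n) - c(NA, last_change[-n])
    others <- obs[, -m, drop = FALSE]
    cg <- c(NA, (others[-n, 1] == others[-n, 2]))
    st <- tab$setting
    p_change <- ifelse(st == "neutral", NA,
      ifelse((st == "congruent_unlikely") == cg, "low", "high"))
    pr <- ifelse(st == "neutral", "unpredictable",
      ifelse(dv, ifelse(p_change == "high", "predicted", "mispredicted"),
                 ifelse(p_change == "low", "predicted", "mispredicted")))
    pr[1] <- NA
    dev[, m] <- dv
    train[, m] <- tr
    congr[, m] <- cg
    pred[, m] <- pr
  }
  gdev <- rowSums(dev) > 0
  g_last <- cummax(ifelse(c(FALSE, gdev[-1]), seq_len(n), 1L))
  gtrain <- seq_len(n) - c(NA, g_last[-n])
  for (m in 1:3) {
    ann[[paste0("dev_", MODALITIES[m])]] <- dev[, m]
    ann[[paste0("train_", MODALITIES[m])]] <- train[, m]
    ann[[paste0("bin_", MODALITIES[m])]] <- train_bin(train[, m])
    ann[[paste0("congr_", MODALITIES[m])]] <- congr[, m]
    ann[[paste0("pred_", MODALITIES[m])]] <- pred[, m]
  }
  ann$global_status <- ifelse(gdev, "global_deviant", "global_standard")
  ann$global_status[1] <- NA
  ann$global_train <- gtrain
  ann$global_bin <- global_bin(gtrain)
  ann$included <- seq_len(n) > 1
  ann
}

#' Bin a train length into the six-level design bins
#' @param train integer train lengths.
#' @return character vector over `"1","2","3","4-5","6-8",">8"`.
#' @export
train_bin <- function(train) {
  cut(train, breaks = c(0, 1, 2, 3, 5, 8, Inf), labels = TRAIN_BINS,
      right = TRUE) |> as.character()
}

global_bin <- function(train) {
  cut(train, breaks = c(0, 1, 2, 3, Inf), labels = GLOBAL_BINS,
      right = TRUE) |> as.character()
}

#' Empirical conditional change probabilities
#'
#' Frequencies of a modality change between consecutive non-catch trials,
#' conditional on the congruency of the other two modalities on the earlier
#' trial, pooled within runs.
#'
#' @param table a `trial_table`.
#' @param pooled if `TRUE` (default) pool the three modalities (the model is
#'   symmetric across them); otherwise return per-modality rows.
#' @return data.frame with columns `modality`, `context`
#'   (congruent/incongruent/any), `p_change`, `n_change`, `n`; empty cells
#'   yield `NA` probabilities.
#' @export
empirical_change_probs <- function(table, pooled = TRUE) {
  ann <- annotate(table)
  res <- list()
  for (m in MODALITIES) {
    dv <- ann[[paste0("dev_", m)]]
    cg <- ann[[paste0("congr_", m)]]
    keep <- !is.na(dv)
    for (ctx in c("congruent", "incongruent", "any")) {
      sel <- keep & switch(ctx, congruent = cg %in% TRUE,
                           incongruent = cg %in% FALSE, any = TRUE)
      n <- sum(sel)
      res[[length(res) + 1]] <- data.frame(
        modality = m, context = ctx,
        p_change = if (n > 0) mean(dv[sel]) else NA_real_,
        n_change = sum(dv[sel]), n = n)
    }
  }
  res <- do.call(rbind, res)
  if (pooled) {
    res <- do.call(rbind, lapply(split(res, res$context), function(d) {
      data.frame(modality = "pooled", context = d$context[1],
                 p_change = sum(d$n_change) / sum(d$n),
                 n_change = sum(d$n_change), n = sum(d$n))
    }))
    rownames(res) <- NULL
  }
  res
}
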