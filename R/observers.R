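# Dirichlet-Categorical ideal observers with exponential forgetting, read out
# by three surprise functions, plus the train-length change-detection (TLCD)
# baseline.

#' Create a Dirichlet-Categorical belief
#'
#' Pseudo-counts per context over outcomes, with a flat conjugate prior
#' `alpha0` per outcome and exponential forgetting rate `tau` (counts decay
#' by `exp(-tau)` at every observation; half-life in stimuli is `ln 2 / tau`).
#'
#' @param contexts character vector of context labels.
#' @param n_outcomes number of categorical outcomes per context.
#' @param alpha0 flat prior pseudo-count per outcome (default 1).
#' @param tau forgetting rate >= 0 (default 0 = perfect memory).
#' @return object of class `dircat_belief`.
#' @export
dircat_belief <- function(contexts, n_outcomes = 2, alpha0 = 1, tau = 0) {
  stopifnot(length(contexts) >= 1, n_outcomes >= 2, alpha0 > 0, tau >= 0)
  counts <- matrix(0, length(contexts), n_outcomes,
                   dimnames = list(contexts, NULL))
  structure(list(counts = counts, alpha0 = alpha0, tau = tau),
            class = "dircat_belief")
}

#' Update a belief with one observation
#'
#' All contexts' counts are first decayed by `exp(-tau)` (time passes with
#' the arriving stimulus), then one count is added for the realized outcome
#' in the active context. The input belief is not modified. Within an
#' observer trace the read-out order is decay, predict/surprise, increment:
#' surprise at trial t is computed from the decayed belief before the count
#' is added (see [decay_belief()]).
#'
#' @param belief a `dircat_belief`.
#' @param context active context label.
#' @param outcome realized outcome index (1-based).
#' @param decay apply the forgetting step (default TRUE); set FALSE when the
#'   belief was already decayed via [decay_belief()].
#' @return the updated `dircat_belief`.
#' @export
update_belief <- function(belief, context, outcome, decay = TRUE) {
  stopifnot(inherits(belief, "dircat_belief"))
  if (!context %in% rownames(belief$counts)) stop("unknown context: ", context)
  if (outcome < 1 || outcome > ncol(belief$counts)) stop("unknown outcome")
  if (decay) belief <- decay_belief(belief)
  belief$counts[context, outcome] <- belief$counts[context, outcome] + 1
  belief
}

#' Apply one forgetting step to all contexts
#' @param belief a `dircat_belief`.
#' @return belief with all counts multiplied by `exp(-tau)`.
#' @export
decay_belief <- function(belief) {
  stopifnot(inherits(belief, "dircat_belief"))
  belief$counts <- belief$counts * exp(-belief$tau)
  belief
}

#' Posterior predictive distribution for a context
#'
#' @param belief a `dircat_belief`.
#' @param context context label.
#' @return probability vector over outcomes (Laplace-smoothed counts).
#' @export
predictive_prob <- function(belief, context) {
  stopifnot(inherits(belief, "dircat_belief"))
  a <- belief$alpha0 + belief$counts[context, ]
  a / sum(a)
}

#' Kullback-Leibler divergence between two Dirichlet distributions
#'
#' Closed form via log-Beta and digamma terms:
#' `KL(Dir(a) || Dir(b)) = ln B(b) - ln B(a) + sum((a_i - b_i) (psi(a_i) - psi(a_0)))`.
#' Vectorized: `alpha` and `beta` may be matrices (one distribution per row).
#'
#' @param alpha,beta positive Dirichlet parameter vectors (or row-wise
#'   matrices) of equal length.
#' @return KL divergence(s) in nats, >= 0.
#' @export
kl_dirichlet <- function(alpha, beta) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  stopifnot(all(dim(alpha) == dim(beta)))
  if (any(alpha <= 0) || any(beta <= 0)) stop("Dirichlet parameters must be positive")
  a0 <- rowSums(alpha)
  b0 <- rowSums(beta)
  lb_a <- rowSums(lgamma(alpha)) - lgamma(a0)
  lb_b <- rowSums(lgamma(beta)) - lgamma(b0)
  kl <- lb_b - lb_a + rowSums((alpha - beta) * (digamma(alpha) - digamma(a0)))
  pmax(drop(kl), 0)
}

#' Predictive surprise
#'
#' Negative log posterior-predictive probability of the realized outcome.
#'
#' @inheritParams update_belief
#' @return surprise in nats, >= 0.
#' @export
surprise_ps <- function(belief, context, outcome) {
  -log(predictive_prob(belief, context)[outcome])
}

#' Bayesian surprise
#'
#' KL divergence from the prior to the posterior Dirichlet of the updated
#' context (the other contexts are excluded; at `tau = 0` they are unchanged
#' and contribute nothing).
#'
#' @param belief_pre belief before the update.
#' @param belief_post belief after `update_belief(belief_pre, context, .)`.
#' @param context the updated context.
#' @return surprise in nats.
#' @export
surprise_bs <- function(belief_pre, belief_post, context) {
  stopifnot(identical(rownames(belief_pre$counts), rownames(belief_post$counts)))
  kl_dirichlet(belief_pre$alpha0 + belief_pre$counts[context, ],
               belief_post$alpha0 + belief_post$counts[context, ])
}

#' Confidence-corrected surprise
#'
#' KL divergence from the informed prior of the active context to the naive
#' posterior: a flat `Dir(alpha0, ...)` prior updated with only the current
#' event. Scales with the commitment of the belief; equals Bayesian surprise
#' whenever the informed prior is itself flat.
#'
#' @inheritParams update_belief
#' @return surprise in nats.
#' @export
surprise_cs <- function(belief, context, outcome) {
  a <- belief$alpha0 + belief$counts[context, ]
  naive <- rep(belief$alpha0, ncol(belief$counts))
  naive[outcome] <- naive[outcome] + 1
  kl_dirichlet(a, naive)
}

# Vectorized observer core. Events are (context, outcome) pairs for trials
# t = 2..T. Exponentially decayed counts are obtained with a recursive
# filter per (context, outcome) cell; surprise read-outs are computed in
# closed form from the count series. Equivalent to stepping
# update_belief()/surprise_*() through the sequence (tested against it).
run_dircat_observer <- function(ctx, out, n_ctx, n_out, tau, alpha0) {
  stopifnot(length(ctx) == length(out))
  nT <- length(ctx)
  dec <- exp(-tau)
  cell <- (ctx - 1L) * n_out + out  # 1..n_ctx*n_out
  n_cell <- n_ctx * n_out
  I <- matrix(0, nT, n_cell)
  I[cbind(seq_len(nT), cell)] <- 1
  N <- apply(I, 2, function(x) stats::filter(x, dec, method = "recursive"))
  N <- matrix(N, nT, n_cell)
  # prior counts at event t are the decayed state after event t-1
  Nprior <- rbind(0, N[-nT, , drop = FALSE]) * dec
  # counts of the active context, prior and posterior to the update
  idx_ctx <- function(k) ((ctx - 1L) * n_out + k)
  Aprior <- vapply(seq_len(n_out),
                   function(k) Nprior[cbind(seq_len(nT), idx_ctx(k))] + alpha0,
                   numeric(nT))
  Apost <- Aprior
  Apost[cbind(seq_len(nT), out)] <- Apost[cbind(seq_len(nT), out)] + 1
  p_pred <- Aprior / rowSums(Aprior)
  ps <- -log(p_pred[cbind(seq_len(nT), out)])
  bs <- kl_dirichlet(Aprior, Apost)
  naive <- matrix(alpha0, nT, n_out)
  naive[cbind(seq_len(nT), out)] <- alpha0 + 1
  cs <- kl_dirichlet(Aprior, naive)
  data.frame(context = ctx, outcome = out, p_pred = p_pred[cbind(seq_len(nT), out)],
             PS = ps, BS = bs, CS = cs)
}

#' Run the unimodal transition-probability observer
#'
#' Binary sequence observer estimating transition probabilities: one context
#' per previous stimulus identity, outcomes = current identity. The trace
#' starts at trial 2.
#'
#' @param sequence binary (0/1) stimulus vector of one modality, one run.
#' @param tau forgetting rate (default 0).
#' @param alpha0 flat prior pseudo-count (default 1).
#' @return data.frame of class `surprise_trace` with one row per trial
#'   2..T: `trial`, `context`, `outcome`, `p_pred`, `PS`, `BS`, `CS`.
#' @export
run_unimodal_observer <- function(sequence, tau = 0, alpha0 = 1) {
  stopifnot(length(sequence) >= 2, all(sequence %in% c(0, 1)))
  nT <- length(sequence)
  ctx <- sequence[-nT] + 1L   # previous outcome
  out <- sequence[-1] + 1L
  tr <- run_dircat_observer(ctx, out, 2L, 2L, tau, alpha0)
  tr <- cbind(trial = 2:nT, tr)
  class(tr) <- c("surprise_trace", "data.frame")
  tr
}

#' Run the cross-modal alternation-given-congruency observer
#'
#' Estimates repetition/alternation probabilities of one modality with two
#' hidden parameter sets: one for trials whose other two modalities were
#' congruent at t-1, one for incongruent. Outcome space is
#' {repeat, alternate}; the trace starts at trial 2.
#'
#' @param sequence binary stimulus vector of one modality, one run.
#' @param congruency logical vector aligned to trials 2..T: were the other
#'   two modalities congruent at t-1?
#' @inheritParams run_unimodal_observer
#' @return `surprise_trace` data.frame as for [run_unimodal_observer()].
#' @export
run_crossmodal_observer <- function(sequence, congruency, tau = 0, alpha0 = 1) {
  stopifnot(length(sequence) >= 2, all(sequence %in% c(0, 1)))
  nT <- length(sequence)
  if (length(congruency) != nT - 1) stop("congruency must align to trials 2..T")
  d <- as.integer(sequence[-1] != sequence[-nT])  # 1 = alternate
  ctx <- ifelse(congruency, 1L, 2L)               # 1 = congruent context
  tr <- run_dircat_observer(ctx, d + 1L, 2L, 2L, tau, alpha0)
  tr <- cbind(trial = 2:nT, tr)
  class(tr) <- c("surprise_trace", "data.frame")
  tr
}

#' Run the train-length change-detection (TLCD) baseline
#'
#' Tracks the repetition counter `c_t = d_t (c_{t-1} + d_t)` where `d_t = 1`
#' for a repetition and 0 for a change, and outputs `-c_t` on repetitions and
#' `c_{t-1}` on changes: values grow linearly with train length with opposite
#' signs for standards and deviants.
#'
#' @param sequence binary stimulus vector of one modality, one run.
#' @return data.frame of class `tlcd_trace` with one row per trial 2..T:
#'   `trial`, `d`, `c`, `output`.
#' @export
run_tlcd <- function(sequence) {
  stopifnot(length(sequence) >= 2, all(sequence %in% c(0, 1)))
  nT <- length(sequence)
  d <- as.integer(sequence[-1] == sequence[-nT])  # 1 = repetition
  # c_t counts consecutive repetitions; vectorized run-length reset
  cc <- integer(nT - 1)
  run_len <- 0L
  # c_t = d_t * (c_{t-1} + d_t): cumulative count of 1s since last 0
  idx <- seq_len(nT - 1)
  last_zero <- cummax(ifelse(d == 0L, idx, 0L))
  cc <- ifelse(d == 1L, idx - last_zero, 0L)
  c_prev <- c(0L, cc[-(nT - 1)])
  out <- ifelse(d == 1L, -cc, c_prev)
  tr <- data.frame(trial = 2:nT, d = d, c = cc, output = out)
  class(tr) <- c("tlcd_trace", "data.frame")
  tr
}

MODEL_FAMILIES <- c("tlcd", "um-ps", "um-bs", "um-cs", "ucm-ps", "ucm-bs", "ucm-cs")

#' Build z-scored single-trial regressor matrices
#'
#' For an annotated experiment, computes per-modality model outputs (beliefs
#' reset at run boundaries, catch trials excluded) and z-scores each column
#' over the included trials (all non-first trials of each run).
#'
#' @param table a `trial_table` (multi-run allowed).
#' @param model_family one of `"tlcd"`, `"um-ps"`, `"um-bs"`, `"um-cs"`
#'   (3 unimodal columns) or `"ucm-ps"`, `"ucm-bs"`, `"ucm-cs"` (3 unimodal
#'   + 3 cross-modal columns, same surprise read-out).
#' @param tau forgetting rate for the Dirichlet-Categorical observers.
#' @param alpha0 flat prior pseudo-count.
#' @param z_score z-score columns (default TRUE).
#' @return numeric matrix, rows = included trials (attribute `trials` maps to
#'   `(run, trial)`), columns named e.g. `um_A`, `cm_A`.
#' @export
build_regressors <- function(table, model_family, tau = 0, alpha0 = 1,
                             z_score = TRUE) {
  model_family <- match.arg(model_family, MODEL_FAMILIES)
  tab <- table[!table$is_catch, , drop = FALSE]
  runs <- split(tab, tab$run)
  readout <- toupper(sub(".*-", "", model_family))  # PS/BS/CS
  kind <- sub("-.*", "", model_family)              # tlcd/um/ucm
  cols <- lapply(runs, function(r) {
    obs <- as.matrix(r[, c("obs_A", "obs_S", "obs_V")])
    n <- nrow(obs)
    block <- list()
    for (m in 1:3) {
      x <- obs[, m]
      if (kind == "tlcd") {
        block[[paste0("tlcd_", MODALITIES[m])]] <- run_tlcd(x)$output
      } else {
        block[[paste0("um_", MODALITIES[m])]] <-
          run_unimodal_observer(x, tau, alpha0)[[readout]]
      }
    }
    if (kind == "ucm") {
      for (m in 1:3) {
        others <- obs[, -m, drop = FALSE]
        cong <- others[-n, 1] == others[-n, 2]
        block[[paste0("cm_", MODALITIES[m])]] <-
          run_crossmodal_observer(obs[, m], cong, tau, alpha0)[[readout]]
      }
    }
    cbind(run = r$run[-1], trial = r$trial[-1], as.data.frame(block))
  })
  df <- do.call(rbind, cols)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  if (z_score) {
    X <- scale(X)
    if (any(!is.finite(X))) stop("zero-variance regressor; cannot z-score")
    X <- X[, , drop = FALSE]
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  attr(X, "trials") <- df[, 1:2]
  attr(X, "model_family") <- model_family
  attr(X, "tau") <- tau
  X
}
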