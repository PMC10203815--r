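# Log-evidence (free energy) maps for the eight regression models over a
# subjects x channels x time grid, with tau-grid optimization and the
# evidence-inflation penalty for the Bayesian-learner models.

EVIDENCE_MODELS <- c("null", "tlcd", "um-ps", "um-bs", "um-cs",
                     "ucm-ps", "ucm-bs", "ucm-cs")
BL_MODELS <- setdiff(EVIDENCE_MODELS, c("null", "tlcd"))

# One regressor bank for all models and taus: intercept, TLCD (3 cols) and,
# per tau, unimodal and cross-modal PS/BS/CS columns (18 per tau). Columns
# are z-scored. A single observer run per (run, modality, tau, model kind)
# yields all three read-outs.
regressor_bank <- function(table, tau_grid = tau_grid_default(), alpha0 = 1) {
  tab <- table[!table$is_catch, , drop = FALSE]
  runs <- split(tab, tab$run)
  blocks <- lapply(runs, function(r) {
    obs <- as.matrix(r[, c("obs_A", "obs_S", "obs_V")])
    n <- nrow(obs)
    cols <- list()
    for (m in 1:3) {
      cols[[paste0("tlcd_", MODALITIES[m])]] <- run_tlcd(obs[, m])$output
    }
    for (ti in seq_along(tau_grid)) {
      for (m in 1:3) {
        x <- obs[, m]
        um <- run_unimodal_observer(x, tau_grid[ti], alpha0)
        others <- obs[, -m, drop = FALSE]
        cong <- others[-n, 1] == others[-n, 2]
        cm <- run_crossmodal_observer(x, cong, tau_grid[ti], alpha0)
        for (ro in c("PS", "BS", "CS")) {
          cols[[sprintf("um_%s_%s_t%d", tolower(ro), MODALITIES[m], ti)]] <- um[[ro]]
          cols[[sprintf("cm_%s_%s_t%d", tolower(ro), MODALITIES[m], ti)]] <- cm[[ro]]
        }
      }
    }
    as.data.frame(cols)
  })
  bank <- as.matrix(do.call(rbind, blocks))
  bank <- scale(bank)
  if (any(!is.finite(bank))) stop("zero-variance regressor in bank")
  attr(bank, "scaled:center") <- NULL
  attr(bank, "scaled:scale") <- NULL
  attr(bank, "tau_grid") <- tau_grid
  bank
}

# column indices (into cbind(1, bank)) for one model variant
variant_columns <- function(bank_names, model, tau_index = NULL) {
  sel <- switch(sub("-.*", "", model),
    null = character(0),
    tlcd = paste0("tlcd_", MODALITIES),
    um = sprintf("um_%s_%s_t%d", sub(".*-", "", model), MODALITIES, tau_index),
    ucm = c(sprintf("um_%s_%s_t%d", sub(".*-", "", model), MODALITIES, tau_index),
            sprintf("cm_%s_%s_t%d", sub(".*-", "", model), MODALITIES, tau_index)))
  c(1L, 1L + match(sel, bank_names))
}

#' Compute free-energy maps for the eight regression models
#'
#' Fits, per subject and channel x time cell, VB linear regressions for the
#' null model (offset only), the TLCD model (offset + 3 train-length
#' regressors) and the six Bayesian-learner models (UM: offset + 3 unimodal
#' surprise regressors; UCM: + 3 cross-modal regressors) over the full tau
#' grid. For the learner models, tau is optimized per subject and time bin
#' (free energy summed over channels) and the average evidence inflation of
#' that optimization is subtracted prior to model comparison.
#'
#' @param data a `channel_time_data` object or a plain array
#'   `[subject, trial, channel, time]` aligned to the included trials.
#' @param table the generating `trial_table`.
#' @param tau_grid forgetting-rate grid (default [tau_grid_default()]).
#' @param alpha0 observer prior pseudo-count.
#' @param priors,tol,max_iter VB settings, see [vb_linear_regression()].
#' @param penalize apply the evidence-inflation penalty to learner models
#'   (default TRUE).
#' @return list with `F` (array `[subject, channel, time, model]`, penalized
#'   for learner models), `F_unpenalized`, `tau` (selected tau per
#'   model/subject/time), `penalty` (per learner model), `converged`.
#' @export
compute_evidence_maps <- function(data, table, tau_grid = tau_grid_default(),
                                  alpha0 = 1, priors = VB_PRIORS, tol = 1e-4,
                                  max_iter = 200, penalize = TRUE) {
  Y <- if (inherits(data, "channel_time_data")) data$amplitudes else data
  stopifnot(length(dim(Y)) == 4)
  nS <- dim(Y)[1]; nTr <- dim(Y)[2]; nC <- dim(Y)[3]; nT <- dim(Y)[4]
  bank <- regressor_bank(table, tau_grid, alpha0)
  stopifnot(nrow(bank) == nTr)
  Xall <- cbind(offset = 1, bank)
  XtX_all <- crossprod(Xall)
  ncell <- nC * nT
  J <- nS * ncell
  C_big <- matrix(NA_real_, ncol(Xall), J)
  yty <- numeric(J)
  for (s in seq_len(nS)) {
    Ys <- matrix(Y[s, , , ], nTr, ncell)
    idx <- (s - 1) * ncell + seq_len(ncell)
    C_big[, idx] <- crossprod(Xall, Ys)
    yty[idx] <- colSums(Ys^2)
  }
  fit_variant <- function(cols) {
    vb_fit_batch(XtX_all[cols, cols, drop = FALSE],
                 C_big[cols, , drop = FALSE], yty, nTr,
                 priors = priors, tol = tol, max_iter = max_iter)
  }
  bn <- colnames(bank)
  all_conv <- TRUE
  Fmod <- array(NA_real_, dim = c(nS, nC, nT, length(EVIDENCE_MODELS)),
                dimnames = list(NULL, NULL, NULL, EVIDENCE_MODELS))
  to_arr <- function(f) aperm(array(f, dim = c(nC, nT, nS)), c(3, 1, 2))
  for (m in c("null", "tlcd")) {
    ft <- fit_variant(variant_columns(bn, m))
    all_conv <- all_conv && all(ft$converged)
    Fmod[, , , m] <- to_arr(ft$F)
  }
  tau_sel <- list()
  penalty <- c()
  Funpen <- Fmod
  for (m in BL_MODELS) {
    Fg <- array(NA_real_, dim = c(nS, nC, nT, length(tau_grid)))
    for (ti in seq_along(tau_grid)) {
      ft <- fit_variant(variant_columns(bn, m, ti))
      all_conv <- all_conv && all(ft$converged)
      Fg[, , , ti] <- to_arr(ft$F)
    }
    opt <- optimize_tau(Fg, tau_grid)
    tau_sel[[m]] <- opt$tau
    Funpen[, , , m] <- opt$F_opt
    if (penalize) {
      pen <- tau_penalty(Fg, opt$F_opt, tau_grid)
      Fmod[, , , m] <- pen$F_penalized
      penalty[m] <- pen$penalty
    } else {
      Fmod[, , , m] <- opt$F_opt
      penalty[m] <- 0
    }
  }
  list(F = Fmod, F_unpenalized = Funpen, tau = tau_sel, penalty = penalty,
       tau_grid = tau_grid, converged = all_conv)
}

#' Family-wise BMS over a channel x time evidence map
#'
#' Runs [family_bms()] per channel x time cell for one model-space
#' partition.
#'
#' @param F_models array `[subject, channel, time, model]` with model
#'   dimnames (from [compute_evidence_maps()]).
#' @param partition one element of [model_partitions()] (or a custom named
#'   list of model-name vectors).
#' @param method exceedance method; default `"quadrature"` (exact, fast).
#' @param n_samples,seed for `method = "sampling"`.
#' @return list with `phi` and `r` arrays `[channel, time, family]`.
#' @export
family_bms_map <- function(F_models, partition, method = "quadrature",
                           n_samples = 1e6, seed = NULL) {
  dn <- dimnames(F_models)[[4]]
  models <- unlist(partition)
  stopifnot(all(models %in% dn))
  nC <- dim(F_models)[2]; nT <- dim(F_models)[3]
  fams <- names(partition)
  phi <- array(NA_real_, dim = c(nC, nT, length(fams)),
               dimnames = list(NULL, NULL, fams))
  r <- phi
  for (ci in seq_len(nC)) for (ti in seq_len(nT)) {
    L <- F_models[, ci, ti, models, drop = TRUE]
    colnames(L) <- models
    res <- family_bms(L, partition, method = method, n_samples = n_samples,
                      seed = seed)
    phi[ci, ti, ] <- res$phi
    r[ci, ti, ] <- res$r
  }
  list(phi = phi, r = r, families = fams)
}
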