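# Synthetic single-trial channel x time EEG with known linear dependence on
# model regressors. Desk-scale stand-in for real recordings: 8 channels x
# 20 post-stimulus time bins (30 ms each, centers 15..585 ms), i.i.d.
# Gaussian noise, subject-level variability on effect amplitudes only.

EEG_CHANNELS <- 8L
EEG_TIMEBINS <- 20L

#' Time-bin centers of the synthetic grid (ms)
#' @param n_time number of bins.
#' @return numeric vector of bin centers.
#' @export
time_bin_centers <- function(n_time = EEG_TIMEBINS) {
  seq(15, by = 30, length.out = n_time)
}

# channel x time index windows emulating the canonical mismatch components
mmn_window <- function() list(channels = 3:6, times = which(
  time_bin_centers() >= 100 & time_bin_centers() <= 200))
p3_window <- function() list(channels = 4:5, times = which(
  time_bin_centers() >= 300 & time_bin_centers() <= 350))

#' Construct a ground-truth specification for synthetic EEG
#'
#' @param model_family generating model: `"null"` or one of
#'   `r paste0('"', MODEL_FAMILIES, '"', collapse = ", ")`.
#' @param beta array `[channel, time, regressor]` of effect amplitudes in
#'   microvolts per SD of the (z-scored) regressor; `NULL` for the null
#'   family.
#' @param beta0 intercept amplitude (default 2).
#' @param sigma trial-level noise SD (> 0, default 10).
#' @param subject_sd between-subject SD of the nonzero effect amplitudes.
#' @param n_subjects number of simulated subjects (default 32).
#' @param tau generating forgetting rate (default 0.05, half-life 13).
#' @param n_channels,n_time grid size.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(model_family = "null", beta = NULL, beta0 = 2,
                         sigma = 10, subject_sd = 0.5, n_subjects = 32,
                         tau = 0.05, n_channels = EEG_CHANNELS,
                         n_time = EEG_TIMEBINS) {
  stopifnot(sigma > 0, subject_sd >= 0, n_subjects >= 1)
  model_family <- match.arg(model_family, c("null", MODEL_FAMILIES))
  p <- if (model_family == "null") 0L else if (startsWith(model_family, "ucm")) 6L else 3L
  if (is.null(beta)) beta <- array(0, dim = c(n_channels, n_time, max(p, 1)))
  if (p > 0 && !all(dim(beta) == c(n_channels, n_time, p))) {
    stop("beta must be [n_channels, n_time, n_regressors]")
  }
  structure(list(model_family = model_family, beta = beta, beta0 = beta0,
                 sigma = sigma, subject_sd = subject_sd,
                 n_subjects = n_subjects, tau = tau,
                 n_channels = n_channels, n_time = n_time),
            class = "ground_truth")
}

#' Named ground-truth presets
#'
#' Five generating families (null, TLCD, UM-BS, UCM-BS, UCM-CS) at three
#' signal-to-noise levels. Unimodal (and TLCD) effects are planted in an
#' MMN-like window (channels 3-6, 100-200 ms); cross-modal effects only in a
#' central-channel P3-like window (channels 4-5, 300-350 ms). Effect
#' amplitudes: weak 0.5, medium 1, strong 2 microvolts per regressor SD,
#' against a trial-noise SD of 10; between-subject SD is half the amplitude.
#'
#' @param n_subjects subjects per scenario (default 32).
#' @return named list of `ground_truth` objects, e.g. `"ucm-bs-medium"`.
#' @export
default_scenarios <- function(n_subjects = 32) {
  snr <- c(weak = 0.5, medium = 1, strong = 2)
  out <- list()
  out[["null"]] <- ground_truth("null", n_subjects = n_subjects)
  for (s in names(snr)) {
    b <- snr[[s]]
    for (fam in c("tlcd", "um-bs", "ucm-bs", "ucm-cs")) {
      p <- if (startsWith(fam, "ucm")) 6L else 3L
      beta <- array(0, dim = c(EEG_CHANNELS, EEG_TIMEBINS, p))
      mw <- mmn_window()
      beta[mw$channels, mw$times, 1:3] <- b
      if (p == 6) {
        pw <- p3_window()
        beta[, , 4:6] <- 0
        beta[pw$channels, pw$times, 4:6] <- b
      }
      out[[paste0(fam, "-", s)]] <- ground_truth(
        fam, beta = beta, subject_sd = b / 2, n_subjects = n_subjects)
    }
  }
  out
}

#' Serialize / deserialize a ground truth through JSON
#' @param truth a `ground_truth`.
#' @return JSON string.
#' @export
ground_truth_to_json <- function(truth) {
  x <- unclass(truth)
  x$beta_dim <- dim(x$beta)
  x$beta <- as.numeric(x$beta)
  jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
}

#' @rdname ground_truth_to_json
#' @param json JSON string from [ground_truth_to_json()].
#' @export
ground_truth_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  beta <- array(x$beta, dim = x$beta_dim)
  ground_truth(x$model_family, beta = beta, beta0 = x$beta0, sigma = x$sigma,
               subject_sd = x$subject_sd, n_subjects = x$n_subjects,
               tau = x$tau, n_channels = x$n_channels, n_time = x$n_time)
}

#' Simulate single-trial channel x time EEG data
#'
#' Amplitudes are linear in the generating family's z-scored regressors:
#' `y = beta0 + sum_k beta_k(channel, time) x_k(trial) + e`,
#' `e ~ N(0, sigma^2)` i.i.d. Each subject's nonzero effect amplitudes are
#' drawn `N(beta, subject_sd^2)`; zero entries stay zero so planted
#' locations remain interpretable.
#'
#' @param table a `trial_table` experiment.
#' @param truth a `ground_truth`.
#' @param seed integer seed.
#' @return object of class `channel_time_data`: list with `amplitudes`
#'   (array `[subject, trial, channel, time]` over included trials),
#'   `trials` (run/trial index), `truth`.
#' @export
simulate_eeg <- function(table, truth, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  X <- if (truth$model_family == "null") NULL else {
    build_regressors(table, truth$model_family, tau = truth$tau)
  }
  tab <- table[!table$is_catch, , drop = FALSE]
  n_trials <- sum(unlist(lapply(split(tab, tab$run), nrow)) - 1L)
  trials <- if (is.null(X)) NULL else attr(X, "trials")
  C <- truth$n_channels; Tt <- truth$n_time
  set.seed(seed)
  Y <- array(NA_real_, dim = c(truth$n_subjects, n_trials, C, Tt))
  B <- matrix(truth$beta, C * Tt, dim(truth$beta)[3])  # cell x p
  for (s in seq_len(truth$n_subjects)) {
    Ys <- matrix(rnorm(n_trials * C * Tt, truth$beta0, truth$sigma),
                 n_trials, C * Tt)
    if (!is.null(X)) {
      Bs <- B
      nz <- B != 0
      Bs[nz] <- B[nz] + rnorm(sum(nz), 0, truth$subject_sd)
      Ys <- Ys + X %*% t(Bs)
    }
    Y[s, , , ] <- array(Ys, dim = c(n_trials, C, Tt))
  }
  structure(list(amplitudes = Y, trials = trials, truth = truth),
            class = "channel_time_data")
}
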