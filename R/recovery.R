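# Model-recovery experiments: simulate from a known generating scenario,
# run the full evidence + family-BMS pipeline, and check which family wins
# where. Desk-scale mirror of the real-data model comparison.

#' Default schedule for recovery experiments
#'
#' Three runs, one per probability setting (600 trials each). The full
#' six-run experiment doubles the data volume without changing what the
#' recovery test establishes, so recovery replications use this reduced
#' schedule.
#' @return character vector of setting labels.
#' @export
recovery_schedule <- function() {
  c("congruent_unlikely", "incongruent_unlikely", "neutral")
}

#' One model-recovery replication
#'
#' Generates an experiment, simulates EEG from the named scenario, computes
#' penalized evidence maps for all eight models and returns family-wise BMS
#' maps for the three canonical comparisons.
#'
#' @param scenario name in [default_scenarios()] (e.g. `"ucm-bs-medium"`).
#' @param seed integer seed driving sequence, data and BMS.
#' @param n_subjects subjects (default 32).
#' @param schedule run schedule (default [recovery_schedule()]).
#' @param tau_grid forgetting-rate grid.
#' @return list with `phi` per comparison (arrays `[channel, time, family]`),
#'   `truth`, `evidence` (the [compute_evidence_maps()] output).
#' @export
recovery_replication <- function(scenario, seed, n_subjects = 32,
                                 schedule = recovery_schedule(),
                                 tau_grid = tau_grid_default()) {
  truth <- default_scenarios(n_subjects)[[scenario]]
  if (is.null(truth)) stop("unknown scenario: ", scenario)
  exper <- generate_experiment(schedule, seed = seed)
  dat <- simulate_eeg(exper, truth, seed = derive_seed(seed, 7001))
  ev <- compute_evidence_maps(dat, exper, tau_grid = tau_grid)
  parts <- model_partitions()
  phi <- lapply(parts, function(p) family_bms_map(ev$F, p)$phi)
  list(phi = phi, truth = truth, evidence = ev)
}

#' Planted cross-modal locations of the UCM scenarios
#' @return data.frame of channel/time indices in the P3-like window.
#' @export
planted_cm_cells <- function() {
  w <- p3_window()
  expand.grid(channel = w$channels, time = w$times)
}

#' Model-recovery confusion matrix over generating scenarios
#'
#' For each generating scenario, simulates one experiment, sums the
#' penalized evidence per subject and model over the scenario's distinctive
#' cells, and records the model-level random-effects BMS posterior. The
#' distinctive cells are where the generator's identifying signature is
#' planted: the whole grid for the null scenario, the MMN-like window for
#' TLCD and unimodal scenarios, and the P3-like cross-modal window for UCM
#' scenarios (at MMN cells a UCM generator restricts to its unimodal part,
#' so recovery is only defined where the cross-modal effect lives).
#'
#' @param scenarios character vector of scenario names.
#' @param seed integer seed.
#' @param n_subjects subjects per scenario.
#' @param tau_grid forgetting-rate grid.
#' @return matrix `[generator, selected model]` of expected posterior model
#'   probabilities `r`.
#' @export
recovery_confusion <- function(scenarios = c("null", "tlcd-medium",
                                             "um-bs-medium", "ucm-bs-medium",
                                             "ucm-cs-medium"),
                               seed = 1, n_subjects = 32,
                               tau_grid = tau_grid_default()) {
  out <- matrix(NA_real_, length(scenarios), length(EVIDENCE_MODELS),
                dimnames = list(scenarios, EVIDENCE_MODELS))
  for (i in seq_along(scenarios)) {
    rep <- recovery_replication(scenarios[i], seed = derive_seed(seed, i),
                                n_subjects = n_subjects, tau_grid = tau_grid)
    mw <- mmn_window()
    win <- if (scenarios[i] == "null") {
      expand.grid(channel = seq_len(dim(rep$evidence$F)[2]),
                  time = seq_len(dim(rep$evidence$F)[3]))
    } else if (startsWith(scenarios[i], "ucm")) {
      planted_cm_cells()
    } else {
      expand.grid(channel = mw$channels, time = mw$times)
    }
    Fw <- rep$evidence$F[, unique(win$channel), unique(win$time), ,
                         drop = FALSE]
    L <- apply(Fw, c(1, 4), sum)  # subject x model over distinctive cells
    res <- rfx_bms(L, method = "quadrature")
    out[i, ] <- res$r
  }
  out
}
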