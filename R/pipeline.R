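# Pipeline orchestration: configuration, end-to-end run, fixture
# generation, and a thin command-line dispatcher.

#' Default pipeline configuration
#'
#' All stochastic stages receive sub-seeds derived from the single master
#' seed, so stages can be rerun independently and deterministically.
#'
#' @param seed master seed.
#' @param schedule run schedule (default: the six-run experiment with each
#'   setting twice, order drawn from the seed).
#' @param n_trials,n_catch per-run sizes.
#' @param p_low,p_high,p_neutral nominal change probabilities.
#' @param scenario synthetic-EEG scenario name (default `"ucm-bs-medium"`).
#' @param n_subjects simulated subjects.
#' @param tau_grid forgetting-rate grid for evidence maps.
#' @param regressor_families families written out by the regressor stage.
#' @param run_glm,run_bms enable the GLM / model-comparison stages.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, schedule = NULL, n_trials = 600,
                            n_catch = 6, p_low = 0.025, p_high = 0.15,
                            p_neutral = 0.0875, scenario = "ucm-bs-medium",
                            n_subjects = 32, tau_grid = tau_grid_default(),
                            regressor_families = c("tlcd", "um-bs", "ucm-bs"),
                            run_glm = TRUE, run_bms = TRUE,
                            out_dir = tempfile("mmr_pipeline_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate-seq -> make-regressors -> simulate-eeg -> evidence maps ->
#' family BMS (three comparisons) and the condition-GLM stage, writing
#' human-readable TSV/JSON outputs to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  writeLines(cfg_json, file.path(config$out_dir, "config.json"))

  exper <- generate_experiment(config$schedule, seed = derive_seed(config$seed, 1),
                               n_trials = config$n_trials,
                               n_catch = config$n_catch, p_low = config$p_low,
                               p_high = config$p_high,
                               p_neutral = config$p_neutral)
  write_trial_table(exper, file.path(config$out_dir, "trials.tsv"))
  ann <- annotate(exper)
  data.table::fwrite(ann, file.path(config$out_dir, "annotation.tsv"),
                     sep = "\t", na = "NA")

  for (fam in config$regressor_families) {
    X <- build_regressors(exper, fam, tau = 0.05)
    write_regressors(X, file.path(config$out_dir,
                                  paste0("regressors_", fam, ".tsv")))
  }

  truth <- default_scenarios(config$n_subjects)[[config$scenario]]
  if (is.null(truth)) stop("unknown scenario: ", config$scenario)
  dat <- simulate_eeg(exper, truth, seed = derive_seed(config$seed, 2))
  writeLines(ground_truth_to_json(truth),
             file.path(config$out_dir, "ground_truth.json"))

  out <- list(experiment = exper, annotation = ann, data = dat,
              out_dir = config$out_dir)

  if (config$run_bms) {
    ev <- compute_evidence_maps(dat, exper, tau_grid = config$tau_grid)
    parts <- model_partitions()
    bms_rows <- list()
    for (cmp in names(parts)) {
      m <- family_bms_map(ev$F, parts[[cmp]])
      for (f in m$families) {
        idx <- which(!is.na(m$phi[, , f]), arr.ind = TRUE)
        bms_rows[[paste(cmp, f)]] <- data.frame(
          comparison = cmp, family = f,
          channel = idx[, 1], time = idx[, 2],
          r = as.numeric(m$r[, , f]), phi = as.numeric(m$phi[, , f]))
      }
      out$bms[[cmp]] <- m
    }
    bms_tab <- do.call(rbind, bms_rows)
    data.table::fwrite(bms_tab, file.path(config$out_dir, "bms.tsv"), sep = "\t")
    summary <- lapply(names(parts), function(cmp) {
      m <- out$bms[[cmp]]
      lapply(stats::setNames(m$families, m$families), function(f) {
        list(n_cells_phi_gt_0.95 = sum(m$phi[, , f] > 0.95),
             max_phi = max(m$phi[, , f]))
      })
    })
    names(summary) <- names(parts)
    summary$penalty <- as.list(ev$penalty)
    jsonlite::write_json(summary, file.path(config$out_dir, "bms_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out$evidence <- ev
  }

  if (config$run_glm) {
    out$glm <- glm_stage(dat, ann, config$out_dir)
  }
  invisible(out)
}

# condition-GLM stage: train-length contrasts per modality, conjunction of
# deviants > standards, predictability ANOVA
glm_stage <- function(dat, ann, out_dir) {
  Xtl <- build_trainlength_design(ann)
  fit_tl <- fit_massunivariate(dat, Xtl)
  res <- list()
  t_dev <- list()
  nS <- dim(fit_tl$beta)[1]
  for (m in MODALITIES) {
    std_cols <- match(paste(m, "std", TRAIN_BINS, sep = "_"), colnames(Xtl))
    dev_cols <- match(paste(m, "dev", TRAIN_BINS, sep = "_"), colnames(Xtl))
    mmr <- fit_tl$beta[, dev_cols, , , drop = FALSE] -
      fit_tl$beta[, std_cols, , , drop = FALSE]
    res[[paste0("trainlength_", m)]] <- list(
      std = linear_contrast(fit_tl$beta[, std_cols, , , drop = FALSE]),
      dev = linear_contrast(fit_tl$beta[, dev_cols, , , drop = FALSE]),
      mmr = linear_contrast(mmr))
  }
  Xcj <- build_conjunction_design(ann)
  fit_cj <- fit_massunivariate(dat, Xcj)
  for (m in MODALITIES) {
    d <- fit_cj$beta[, paste(m, "dev", sep = "_"), , ] -
      fit_cj$beta[, paste(m, "std", sep = "_"), , ]
    tt <- one_sample_t(array(d, dim = dim(fit_cj$beta)[c(1, 3, 4)]))
    t_dev[[m]] <- tt$t
  }
  res$conjunction <- conjunction(t_dev, df = nS - 1)
  Xpr <- build_predictability_design(ann, "subject")
  fit_pr <- fit_massunivariate(dat, Xpr)
  cb <- condition_beta_array(fit_pr$beta, colnames(Xpr))
  res$anova <- anova_predictability(cb)
  tl_tab <- do.call(rbind, lapply(MODALITIES, function(m) {
    r <- res[[paste0("trainlength_", m)]]
    do.call(rbind, lapply(names(r), function(k) data.frame(
      modality = m, contrast = k, max_abs_t = max(abs(r[[k]]$t)),
      min_p = min(r[[k]]$p))))
  }))
  data.table::fwrite(tl_tab, file.path(out_dir, "glm_trainlength.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(conjunction_min_p = min(res$conjunction$p),
         anova_min_p = apply(res$anova$p, 3, min)),
    file.path(out_dir, "glm_summary.json"), auto_unbox = TRUE, digits = NA)
  res
}

# MMR (deviant - standard) per predictability condition, averaged over the
# congruency split: [subject, modality, condition, channel, time]
condition_beta_array <- function(beta, col_names) {
  nS <- dim(beta)[1]; nC <- dim(beta)[3]; nT <- dim(beta)[4]
  out <- array(NA_real_, dim = c(nS, 3, 3, nC, nT))
  for (mi in seq_along(MODALITIES)) {
    for (ci in seq_along(PRED_CONDITIONS)) {
      pick <- function(role) {
        cols <- match(paste(MODALITIES[mi], role, PRED_CONDITIONS[ci],
                            c("congr", "incongr"), sep = "_"), col_names)
        cols <- cols[!is.na(cols)]
        apply(beta[, cols, , , drop = FALSE], c(1, 3, 4), mean)
      }
      out[, mi, ci, , ] <- pick("dev") - pick("std")
    }
  }
  out
}

#' Generate a small bundled test fixture
#'
#' One subject, one 200-trial run (2 catch trials), UM-BS generator at high
#' SNR on a reduced 4 x 10 grid, fully reproducible from the seed.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the directory; writes `trials.tsv`, `annotation.tsv`,
#'   `eeg.tsv` (+ sidecars) and `ground_truth.json`.
#' @export
make_fixtures <- function(seed = 42, dir = tempfile("mmr_fixture_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_transition_matrix("congruent_unlikely")
  tab <- generate_run(model, n_trials = 200, n_catch = 2,
                      seed = derive_seed(seed, 1))
  write_trial_table(tab, file.path(dir, "trials.tsv"))
  data.table::fwrite(annotate(tab), file.path(dir, "annotation.tsv"),
                     sep = "\t", na = "NA")
  beta <- array(0, dim = c(4, 10, 3))
  beta[2:3, 3:5, ] <- 2
  truth <- ground_truth("um-bs", beta = beta, sigma = 1, subject_sd = 0,
                        n_subjects = 1, n_channels = 4, n_time = 10)
  dat <- simulate_eeg(tab, truth, seed = derive_seed(seed, 2))
  write_array_tsv(dat$amplitudes, file.path(dir, "eeg.tsv"))
  writeLines(ground_truth_to_json(truth), file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate-seq`, `make-regressors`, `simulate-eeg`,
#' `pipeline`, `fixtures`. Flags are `--key value` pairs; see the README.
#' Installed as `inst/cli/mmrlearn.R`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) stop("usage: mmrlearn.R <subcommand> [--key value ...]")
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  get_opt <- function(name, default = NULL, as = identity) {
    if (!is.null(opts[[name]])) as(opts[[name]]) else default
  }
  out_dir <- get_opt("out", tempfile("mmr_out_"))
  seed <- get_opt("seed", 1, as.integer)
  switch(cmd,
    "simulate-seq" = {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      schedule <- if (!is.null(opts$setting)) {
        rep(opts$setting, get_opt("n-runs", 1, as.integer))
      } else NULL
      tab <- generate_experiment(
        schedule, seed = seed,
        n_trials = get_opt("n-trials", 600, as.integer),
        n_catch = get_opt("n-catch", 6, as.integer))
      write_trial_table(tab, file.path(out_dir, "trials.tsv"))
      data.table::fwrite(annotate(tab), file.path(out_dir, "annotation.tsv"),
                         sep = "\t", na = "NA")
      message("wrote ", out_dir)
      invisible(tab)
    },
    "make-regressors" = {
      tab <- read_trial_table(get_opt("in", stop("--in required")))
      X <- build_regressors(tab, get_opt("model", "um-bs"),
                            tau = get_opt("tau", 0, as.numeric))
      path <- get_opt("out", "regressors.tsv")
      write_regressors(X, path)
      message("wrote ", path)
      invisible(X)
    },
    "simulate-eeg" = {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      tab <- read_trial_table(get_opt("in", stop("--in required")))
      truth <- default_scenarios(
        get_opt("subjects", 32, as.integer))[[get_opt("scenario", "ucm-bs-medium")]]
      dat <- simulate_eeg(tab, truth, seed = seed)
      write_array_tsv(dat$amplitudes, file.path(out_dir, "eeg.tsv"))
      writeLines(ground_truth_to_json(truth),
                 file.path(out_dir, "ground_truth.json"))
      message("wrote ", out_dir)
      invisible(dat)
    },
    "pipeline" = {
      cfg <- pipeline_config(seed = seed, out_dir = out_dir,
                             scenario = get_opt("scenario", "ucm-bs-medium"),
                             n_subjects = get_opt("subjects", 32, as.integer))
      res <- run_pipeline(cfg)
      message("wrote ", out_dir)
      invisible(res)
    },
    "fixtures" = {
      make_fixtures(seed = seed, dir = out_dir)
      message("wrote ", out_dir)
      invisible(out_dir)
    },
    stop("unknown subcommand: ", cmd))
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}
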