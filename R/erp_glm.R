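# ERP-style condition GLM stage: design-matrix builders, mass-univariate
# least-squares fitting, linear train-length contrasts, cross-modal
# conjunction, predictability repeated-measures ANOVA, and a generic
# cluster-based permutation correction on the channel x time lattice.

design_rows <- function(ann) which(ann$included)

new_design <- function(X, ann, rows) {
  empty <- colSums(abs(X)) == 0
  if (any(empty)) {
    warning("empty design columns: ", paste(colnames(X)[empty], collapse = ", "))
  }
  attr(X, "trials") <- ann[rows, c("run", "trial")]
  attr(X, "empty_columns") <- colnames(X)[empty]
  class(X) <- c("design_matrix", class(X))
  X
}

#' Train-length design matrix (45 columns)
#'
#' Intercept + one-hot train-length bins (1, 2, 3, 4-5, 6-8, >8) for
#' standards and deviants of each modality (36 columns) + 4 global-standard
#' and 4 global-deviant bins (1, 2, 3, >3). Rows are the included
#' (non-catch, non-first) trials.
#'
#' @param ann a `trial_annotation` from [annotate()].
#' @return design matrix of class `design_matrix` with 45 named columns.
#' @export
build_trainlength_design <- function(ann) {
  rows <- design_rows(ann)
  a <- ann[rows, ]
  cols <- list(intercept = rep(1, nrow(a)))
  for (m in MODALITIES) {
    dv <- a[[paste0("dev_", m)]]
    bn <- a[[paste0("bin_", m)]]
    for (role in c("std", "dev")) {
      for (b in TRAIN_BINS) {
        cols[[paste(m, role, b, sep = "_")]] <-
          as.numeric(dv == (role == "dev") & bn == b)
      }
    }
  }
  for (role in c("global_standard", "global_deviant")) {
    for (b in GLOBAL_BINS) {
      cols[[paste(role, b, sep = "_")]] <-
        as.numeric(a$global_status == role & a$global_bin == b)
    }
  }
  new_design(do.call(cbind, cols), ann, rows)
}

PRED_CONDITIONS <- c("unpredictable", "predicted", "mispredicted")

#' Predictability design matrix (37 group-level / 36 subject-level columns)
#'
#' Condition indicators for modality x standard/deviant x predictability
#' condition (unpredictable, predicted, mispredicted), split by the
#' congruency of the other two modalities at t-1. The group-level form adds
#' an intercept (37 columns); the subject-level form is the 36
#' congruency-split indicators alone (they already span the intercept).
#'
#' @param ann a `trial_annotation`.
#' @param level `"group"` (default) or `"subject"`.
#' @return `design_matrix` with 37 (group) or 36 (subject) columns.
#' @export
build_predictability_design <- function(ann, level = c("group", "subject")) {
  level <- match.arg(level)
  rows <- design_rows(ann)
  a <- ann[rows, ]
  cols <- list()
  if (level == "group") cols$intercept <- rep(1, nrow(a))
  for (m in MODALITIES) {
    dv <- a[[paste0("dev_", m)]]
    pr <- a[[paste0("pred_", m)]]
    cg <- a[[paste0("congr_", m)]]
    for (role in c("std", "dev")) {
      for (cond in PRED_CONDITIONS) {
        for (congr in c("congr", "incongr")) {
          cols[[paste(m, role, cond, congr, sep = "_")]] <-
            as.numeric(dv == (role == "dev") & pr == cond &
                         cg == (congr == "congr"))
        }
      }
    }
  }
  new_design(do.call(cbind, cols), ann, rows)
}

#' P3-conjunction design matrix (7 columns)
#'
#' Intercept + all-standards and all-deviants indicators per modality.
#'
#' @param ann a `trial_annotation`.
#' @return `design_matrix` with 7 columns.
#' @export
build_conjunction_design <- function(ann) {
  rows <- design_rows(ann)
  a <- ann[rows, ]
  cols <- list(intercept = rep(1, nrow(a)))
  for (m in MODALITIES) {
    dv <- a[[paste0("dev_", m)]]
    cols[[paste(m, "std", sep = "_")]] <- as.numeric(!dv)
    cols[[paste(m, "dev", sep = "_")]] <- as.numeric(dv)
  }
  new_design(do.call(cbind, cols), ann, rows)
}

#' Mass-univariate least-squares fit per subject and channel x time cell
#'
#' Ordinary least squares via SVD pseudoinverse (minimum-norm solution).
#' The canonical condition designs are over-parameterized (one-hot blocks
#' plus intercept) as in standard ERP GLM practice; estimable (centered)
#' contrasts downstream are unaffected by the deficiency.
#'
#' @param data `channel_time_data` or array `[subject, trial, channel, time]`.
#' @param X design matrix, rows aligned to trials.
#' @param strict error (instead of message) on rank deficiency.
#' @return list with `beta` (array `[subject, p, channel, time]`),
#'   `sigma2` (residual variance, `[subject, channel, time]`), `rank`,
#'   `dof` (n - rank).
#' @export
fit_massunivariate <- function(data, X, strict = FALSE) {
  Y <- if (inherits(data, "channel_time_data")) data$amplitudes else data
  stopifnot(length(dim(Y)) == 4, dim(Y)[2] == nrow(X))
  nS <- dim(Y)[1]; nTr <- dim(Y)[2]; nC <- dim(Y)[3]; nT <- dim(Y)[4]
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < ncol(X)) {
    if (strict) stop("rank-deficient design (rank ", rank, " < ", ncol(X), ")")
  }
  P <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])  # p x n pseudoinverse
  ncell <- nC * nT
  beta <- array(NA_real_, dim = c(nS, ncol(X), nC, nT),
                dimnames = list(NULL, colnames(X), NULL, NULL))
  sigma2 <- array(NA_real_, dim = c(nS, nC, nT))
  dof <- nTr - rank
  for (s in seq_len(nS)) {
    Ys <- matrix(Y[s, , , ], nTr, ncell)
    Bs <- P %*% Ys
    res <- Ys - X %*% Bs
    beta[s, , , ] <- array(Bs, dim = c(ncol(X), nC, nT))
    sigma2[s, , ] <- matrix(colSums(res^2) / dof, nC, nT)
  }
  list(beta = beta, sigma2 = sigma2, rank = rank, dof = dof)
}

#' Centered linear contrast weights over the six train-length bins
#' @param n_bins number of bins (default 6).
#' @return weights summing to zero, linear in bin rank.
#' @export
linear_weights <- function(n_bins = 6) {
  w <- seq_len(n_bins) - (n_bins + 1) / 2
  w / sqrt(sum(w^2))
}

#' Group-level linear contrast over bin betas
#'
#' Weighted sum of per-subject bin betas with centered linear weights,
#' tested against zero with a one-sample t test across subjects. Accepts a
#' subjects x bins matrix (single cell) or an array
#' `[subject, bin, channel, time]` (stat map).
#'
#' @param betas_over_bins per-subject bin beta estimates.
#' @param weights contrast weights; default centered linear ranks.
#' @return list with `t`, `df`, `p` (two-sided), `estimate` (matrices or
#'   scalars matching the input's cell dimensions).
#' @export
linear_contrast <- function(betas_over_bins, weights = NULL) {
  x <- betas_over_bins
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1, 1))
  stopifnot(length(dim(x)) == 4)
  nS <- dim(x)[1]; nb <- dim(x)[2]
  if (nS < 2) stop("need at least 2 subjects")
  if (is.null(weights)) weights <- linear_weights(nb)
  stopifnot(length(weights) == nb, abs(sum(weights)) < 1e-12)
  cvals <- apply(x, c(1, 3, 4), function(b) sum(b * weights))
  one_sample_t(cvals)
}

# one-sample t across the first dimension of [subject, channel, time]
one_sample_t <- function(cvals) {
  nS <- dim(cvals)[1]
  m <- apply(cvals, c(2, 3), mean)
  sd <- apply(cvals, c(2, 3), stats::sd)
  t <- m / (sd / sqrt(nS))
  df <- nS - 1
  list(t = drop(t), df = df, p = drop(2 * stats::pt(-abs(t), df)),
       estimate = drop(m))
}

#' Minimum-statistic conjunction across modalities
#'
#' Conjunction-null test: significant only where every constituent map
#' exceeds threshold, implemented as the pointwise minimum t.
#'
#' @param t_maps list of aligned t maps (matrices/arrays of equal shape).
#' @param df degrees of freedom of the constituent maps.
#' @return list with `t` (minimum statistic), `df`, `p` (one-sided upper).
#' @export
conjunction <- function(t_maps, df) {
  stopifnot(is.list(t_maps), length(t_maps) >= 2)
  dims <- lapply(t_maps, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("shape mismatch between maps")
  }
  tmin <- Reduce(pmin, t_maps)
  list(t = tmin, df = df, p = stats::pt(tmin, df, lower.tail = FALSE))
}

#' Two-way repeated-measures ANOVA for modality x predictability
#'
#' Balanced within-subject ANOVA on condition beta estimates
#' `[subject, modality (3), condition (3)]` (optionally with trailing
#' channel x time dimensions), with each main effect and the interaction
#' tested against its subject-interaction error term, plus Bonferroni
#' post hoc paired t tests on the three predictability pairs.
#'
#' @param condition_betas array `[subject, 3, 3]` or
#'   `[subject, 3, 3, channel, time]`.
#' @return for a single cell: list with `anova` (data.frame: effect, df1,
#'   df2, F, p) and `posthoc` (data.frame: pair, t, df, p_bonf); for maps:
#'   arrays of F and p per effect.
#' @export
anova_predictability <- function(condition_betas) {
  x <- condition_betas
  if (length(dim(x)) == 3) return(rm_anova2_cell(x))
  stopifnot(length(dim(x)) == 5)
  nC <- dim(x)[4]; nT <- dim(x)[5]
  effects <- c("modality", "predictability", "interaction")
  Fm <- array(NA_real_, dim = c(nC, nT, 3), dimnames = list(NULL, NULL, effects))
  Pm <- Fm
  for (ci in seq_len(nC)) for (ti in seq_len(nT)) {
    res <- rm_anova2_cell(x[, , , ci, ti])
    Fm[ci, ti, ] <- res$anova$F
    Pm[ci, ti, ] <- res$anova$p
  }
  list(F = Fm, p = Pm, effects = effects)
}

rm_anova2_cell <- function(y) {
  if (any(is.na(y))) stop("missing cells")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  g <- mean(y)
  m_s <- apply(y, 1, mean)
  m_i <- apply(y, 2, mean)
  m_j <- apply(y, 3, mean)
  m_si <- apply(y, c(1, 2), mean)
  m_sj <- apply(y, c(1, 3), mean)
  m_ij <- apply(y, c(2, 3), mean)
  ss_a <- b * n * sum((m_i - g)^2)
  ss_b <- a * n * sum((m_j - g)^2)
  ss_as <- b * sum((m_si - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_i) + g)^2)
  ss_bs <- a * sum((m_sj - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_j) + g)^2)
  ss_ab <- n * sum((m_ij - outer(m_i, rep(1, b)) -
                      outer(rep(1, a), m_j) + g)^2)
  resid <- y
  for (s in seq_len(n)) {
    resid[s, , ] <- y[s, , ] - m_si[s, ] %o% rep(1, b) -
      rep(1, a) %o% m_sj[s, ] - m_ij + m_s[s] +
      outer(m_i, rep(1, b)) + outer(rep(1, a), m_j) - g
  }
  ss_abs <- sum(resid^2)
  tab <- data.frame(
    effect = c("modality", "predictability", "interaction"),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    F = c((ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
          (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
          (ss_ab / ((a - 1) * (b - 1))) / (ss_abs / ((a - 1) * (b - 1) * (n - 1)))))
  tab$p <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)
  cond_means <- apply(y, c(1, 3), mean)  # subject x condition
  pairs <- utils::combn(b, 2)
  ph <- apply(pairs, 2, function(pr) {
    d <- cond_means[, pr[1]] - cond_means[, pr[2]]
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    c(t = tt, df = n - 1, p_bonf = min(1, 2 * stats::pt(-abs(tt), n - 1) * ncol(pairs)))
  })
  posthoc <- data.frame(pair = apply(pairs, 2, paste, collapse = "-"),
                        t(ph))
  list(anova = tab, posthoc = posthoc)
}

#' Label connected clusters on the channel x time lattice
#'
#' 4-neighborhood adjacency in the channel index x time grid.
#'
#' @param mask logical matrix channels x time.
#' @return integer matrix of cluster labels (0 = background), consecutively
#'   numbered.
#' @export
label_clusters <- function(mask) {
  C <- nrow(mask); Tt <- ncol(mask)
  lab <- matrix(0L, C, Tt)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lab)
  big <- sum(mask) + 1L
  repeat {
    cur <- ifelse(mask, lab, big)
    up    <- rbind(big, cur[-C, , drop = FALSE])
    down  <- rbind(cur[-1, , drop = FALSE], big)
    left  <- cbind(big, cur[, -Tt, drop = FALSE])
    right <- cbind(cur[, -1, drop = FALSE], big)
    new <- pmin(cur, up, down, left, right)
    new[!mask] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, C, Tt)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

max_cluster_mass <- function(tmap, thr) {
  mx <- 0
  for (sgn in c(1, -1)) {
    mask <- sgn * tmap > thr
    if (!any(mask)) next
    lab <- label_clusters(mask)
    mass <- tapply(abs(tmap[mask]), lab[mask], sum)
    mx <- max(mx, mass)
  }
  mx
}

#' Cluster-based permutation test on subject-level maps
#'
#' One-sample test across subjects per channel x time cell; clusters are
#' contiguous cells (4-neighborhood) exceeding the two-sided
#' cluster-forming threshold, summarized by the sum of |t| (cluster mass).
#' The null distribution is the maximum cluster mass under random
#' subject-level sign flips; corrected p values are permutation ranks.
#'
#' @param subject_maps array `[subject, channel, time]`.
#' @param cluster_alpha cluster-forming alpha (two-sided, default 0.05).
#' @param n_perm number of sign-flip permutations (default 1000; < 100
#'   warns).
#' @param seed integer seed.
#' @return list with `t` (map), `df`, `threshold`, `clusters` (data.frame:
#'   id, sign, mass, p_corrected), `cluster_map` (labels), `null_max`.
#' @export
cluster_permutation <- function(subject_maps, cluster_alpha = 0.05,
                                n_perm = 1000, seed = 1) {
  stopifnot(length(dim(subject_maps)) == 3)
  if (n_perm < 100) warning("n_perm < 100; corrected p values are coarse")
  nS <- dim(subject_maps)[1]; nC <- dim(subject_maps)[2]; nT <- dim(subject_maps)[3]
  Y <- matrix(subject_maps, nS, nC * nT)
  df <- nS - 1
  thr <- stats::qt(1 - cluster_alpha / 2, df)
  t_from_sums <- function(S1, S2) {
    m <- S1 / nS
    v <- (S2 - nS * m^2) / df
    m / sqrt(v / nS)
  }
  S2 <- colSums(Y^2)
  t_obs <- t_from_sums(colSums(Y), S2)
  tmap <- matrix(t_obs, nC, nT)
  clusters <- data.frame()
  cl_map <- matrix(0L, nC, nT)
  next_id <- 1L
  for (sgn in c(1, -1)) {
    mask <- sgn * tmap > thr
    if (!any(mask)) next
    lab <- label_clusters(mask)
    for (k in seq_len(max(lab))) {
      cells <- lab == k
      clusters <- rbind(clusters, data.frame(
        id = next_id, sign = sgn, mass = sum(abs(tmap[cells])),
        n_cells = sum(cells)))
      cl_map[cells] <- next_id
      next_id <- next_id + 1L
    }
  }
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * nS, replace = TRUE), n_perm, nS)
  S1p <- flips %*% Y
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    null_max[b] <- max_cluster_mass(matrix(t_from_sums(S1p[b, ], S2), nC, nT), thr)
  }
  if (nrow(clusters) > 0) {
    clusters$p_corrected <- vapply(clusters$mass, function(m) {
      (1 + sum(null_max >= m)) / (n_perm + 1)
    }, numeric(1))
  }
  list(t = tmap, df = df, threshold = thr, clusters = clusters,
       cluster_map = cl_map, null_max = null_max)
}
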