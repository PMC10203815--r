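# Random-effects Bayesian model selection across subjects with Dirichlet
# population frequencies, expected posterior probabilities r and exceedance
# probabilities phi, plus family-level inference over a model-space
# partition.

#' Random-effects Bayesian model selection
#'
#' Variational update of a Dirichlet posterior over population model
#' frequencies from per-subject log evidences: subject-wise posterior model
#' assignments and Dirichlet counts are iterated until the alpha change
#' drops below `tol`.
#'
#' @param F matrix of log evidences, subjects x models.
#' @param alpha0 Dirichlet prior counts, scalar or per-model vector
#'   (default 1).
#' @param n_samples Monte-Carlo samples for exceedance probabilities when
#'   `method = "sampling"` (default 1e6).
#' @param seed seed for the sampling method.
#' @param method `"sampling"` (default), `"quadrature"` (exact 1-D Gamma
#'   integral) or `"none"` (skip phi).
#' @param tol convergence tolerance on alpha (default 1e-6).
#' @return object of class `bms_result`: list with `alpha`, `r` (expected
#'   posterior model probabilities), `phi` (exceedance probabilities), `u`
#'   (subject x model posterior assignments), `iterations`.
#' @export
rfx_bms <- function(F, alpha0 = 1, n_samples = 1e6, seed = NULL,
                    method = c("sampling", "quadrature", "none"), tol = 1e-6) {
  method <- match.arg(method)
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop("non-finite log evidences")
  n <- nrow(F)
  K <- ncol(F)
  stopifnot(n >= 2, K >= 2)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K)
  alpha <- alpha0 + n / K
  for (it in 1:10000) {
    lu <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  phi <- if (method == "none") NULL else {
    exceedance_prob(alpha, method = method, n_samples = n_samples, seed = seed)
  }
  structure(list(alpha = alpha, r = alpha / sum(alpha), phi = phi, u = u,
                 iterations = it, models = colnames(F)),
            class = "bms_result")
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' Probability that each component's frequency is the largest. The
#' quadrature method uses the independent-Gamma representation (the argmax
#' of a Dirichlet equals the argmax of independent Gamma(alpha_k, 1) draws)
#' and is exact up to 1-D numerical integration; sampling draws from the
#' Dirichlet directly.
#'
#' @param alpha Dirichlet parameter vector.
#' @param method `"sampling"` or `"quadrature"`.
#' @param n_samples number of Monte-Carlo draws.
#' @param seed optional seed for sampling.
#' @return vector of exceedance probabilities summing to 1.
#' @export
exceedance_prob <- function(alpha, method = c("sampling", "quadrature"),
                            n_samples = 1e6, seed = NULL) {
  method <- match.arg(method)
  K <- length(alpha)
  if (method == "sampling") {
    if (!is.null(seed)) set.seed(seed)
    G <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                n_samples, K)
    tabulate(max.col(G, ties.method = "first"), K) / n_samples
  } else {
    phi <- vapply(seq_len(K), function(k) {
      stats::integrate(function(x) {
        lg <- stats::dgamma(x, shape = alpha[k], log = TRUE)
        lp <- rowSums(matrix(stats::pgamma(rep(x, K - 1),
                                           shape = rep(alpha[-k], each = length(x)),
                                           log.p = TRUE),
                             length(x), K - 1))
        exp(lg + lp)
      }, lower = 0, upper = Inf, rel.tol = 1e-8)$value
    }, numeric(1))
    phi / sum(phi)
  }
}

#' The three canonical model-space partitions
#'
#' Families over the eight regression models (null, tlcd, um-ps/bs/cs,
#' ucm-ps/bs/cs): (1) Bayesian learning vs TLCD vs null; (2) unimodal vs
#' cross-modal vs null; (3) surprise read-out PS vs BS vs CS vs null.
#'
#' @return named list of partitions, each a named list mapping family name
#'   to model names.
#' @export
model_partitions <- function() {
  bl <- c("um-ps", "um-bs", "um-cs", "ucm-ps", "ucm-bs", "ucm-cs")
  list(
    bl_tlcd_null = list(NULL_ = "null", TLCD = "tlcd", BL = bl),
    um_ucm_null = list(NULL_ = "null",
                       UM = c("um-ps", "um-bs", "um-cs"),
                       UCM = c("ucm-ps", "ucm-bs", "ucm-cs")),
    surprise = list(NULL_ = "null",
                    PS = c("um-ps", "ucm-ps"),
                    BS = c("um-bs", "ucm-bs"),
                    CS = c("um-cs", "ucm-cs")))
}

#' Family-wise random-effects Bayesian model selection
#'
#' Runs [rfx_bms()] with the family-uniform prior (each model's prior count
#' is `1 / family size`, equalizing prior mass across families), then
#' aggregates the Dirichlet posterior by family (sums of Dirichlet
#' components are Dirichlet over the summed counts).
#'
#' @param F subjects x models log-evidence matrix with column names.
#' @param partition named list mapping family names to model name vectors;
#'   must cover all columns of `F`.
#' @param method,n_samples,seed passed to [exceedance_prob()] for the
#'   family-level Dirichlet.
#' @return object of class `bms_result` with family-level `alpha`, `r`,
#'   `phi`, plus `model_result` (the model-level fit).
#' @export
family_bms <- function(F, partition, method = c("sampling", "quadrature"),
                       n_samples = 1e6, seed = NULL) {
  method <- match.arg(method)
  F <- as.matrix(F)
  models <- colnames(F)
  if (is.null(models)) stop("F needs model column names")
  all_members <- unlist(partition)
  if (!setequal(all_members, models) || anyDuplicated(all_members) > 0) {
    stop("partition must cover every model exactly once")
  }
  if (any(lengths(partition) == 0)) stop("empty family")
  alpha0 <- numeric(ncol(F))
  names(alpha0) <- models
  for (fam in names(partition)) {
    alpha0[partition[[fam]]] <- 1 / length(partition[[fam]])
  }
  mres <- rfx_bms(F, alpha0 = alpha0, method = "none")
  fam_alpha <- vapply(partition, function(m) sum(mres$alpha[match(m, models)]),
                      numeric(1))
  phi <- exceedance_prob(fam_alpha, method = method, n_samples = n_samples,
                         seed = seed)
  structure(list(alpha = fam_alpha, r = fam_alpha / sum(fam_alpha),
                 phi = stats::setNames(phi, names(partition)),
                 families = names(partition), model_result = mres),
            class = "bms_result")
}
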