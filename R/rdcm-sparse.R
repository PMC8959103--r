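#' Sparsity configuration for sparse rDCM
#'
#' Controls the spike-and-slab extension: the grid of Bernoulli prior
#' inclusion probabilities p0 searched per subject, the posterior-probability
#' threshold used to binarize the result, and whether inhibitory
#' self-connections are exempt from pruning.
#'
#' @param p0_grid candidate prior inclusion probabilities (all in (0, 1));
#'   the default grid is 0.3 to 0.9 in steps of 0.1.
#' @param inclusion_threshold posterior inclusion probability below which a
#'   parameter is pruned to exactly zero.
#' @param exempt_self_connections keep self-connections always present.
#' @param tol,max_iter VB convergence controls.
#' @return object of class `sparsity_config`.
#' @export
sparsity_config <- function(p0_grid = seq(0.3, 0.9, by = 0.1),
                            inclusion_threshold = 0.5,
                            exempt_self_connections = TRUE,
                            tol = 1e-8, max_iter = 500) {
  stopifnot(length(p0_grid) >= 1, all(p0_grid > 0 & p0_grid < 1),
            inclusion_threshold > 0, inclusion_threshold < 1)
  structure(list(p0_grid = p0_grid, inclusion_threshold = inclusion_threshold,
                 exempt_self_connections = exempt_self_connections,
                 tol = tol, max_iter = max_iter),
            class = "sparsity_config")
}

# Bernoulli KL of q(gamma) against prior p0, guarding 0*log(0)
kl_bernoulli <- function(gamma, p0) {
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(x / y))
  sum(xlogy(gamma, p0) + xlogy(1 - gamma, 1 - p0))
}

#' Sparse VB inversion of one region with binary indicator variables
#'
#' Extends the per-region regression with one Bernoulli indicator per
#' parameter (feature selector): the mean-field factorisation
#' q(theta) q(tau) q(z) is optimised by closed-form coordinate ascent. The
#' Gaussian factor uses the expected effective Gram matrix
#' `Re(X^H X) * E[z z^T]`; each inclusion probability is updated through the
#' logistic of the prior log-odds plus the expected log-likelihood gain of
#' switching the indicator on. The negative free energy (including the
#' Bernoulli KL term) is evaluated after every sweep and is non-decreasing.
#'
#' @param design a `frequency_design`.
#' @param r region index.
#' @param priors a [prior_specification()].
#' @param p0 prior inclusion probability in (0, 1).
#' @param config a [sparsity_config()].
#' @return object of class `sparse_region_posterior`: everything in a
#'   `region_posterior` plus `gamma` (posterior inclusion probabilities) and
#'   `p0`.
#' @export
sparse_vb_region <- function(design, r, priors = prior_specification(),
                             p0 = 0.5, config = sparsity_config()) {
  stopifnot(p0 > 0, p0 < 1)
  pv <- region_prior_vectors(design, r, priors)
  ss <- region_suffstats(design, r)
  G <- ss$G; g <- ss$g; P <- length(pv$m0)
  alpha0 <- priors$alpha0; beta0 <- priors$beta0
  alpha <- alpha0 + ss$n_eff / 2
  exempt <- logical(P)
  if (config$exempt_self_connections) exempt[pv$cols == r] <- TRUE
  gamma <- rep(p0, P)
  gamma[exempt] <- 1
  prior_lo <- log(p0) - log1p(-p0)
  e_tau <- alpha0 / beta0
  mu <- pv$m0
  F_old <- -Inf; F_trace <- numeric(0); converged <- FALSE

  ezz <- function(gamma) {
    W <- tcrossprod(gamma)
    diag(W) <- gamma
    W
  }

  for (it in seq_len(config$max_iter)) {
    W <- G * ezz(gamma)
    prec <- diag(pv$l0, P) + e_tau * W
    Sigma <- tryCatch(chol2inv(chol(prec)), error = function(e)
      stop("posterior precision not positive definite in region ", r))
    mu <- as.numeric(Sigma %*% (pv$l0 * pv$m0 + e_tau * (gamma * g)))
    M2 <- Sigma + tcrossprod(mu)

    # sequential closed-form updates of the inclusion probabilities
    GM2 <- G * M2
    for (i in seq_len(P)) {
      if (exempt[i]) next
      cross <- sum(GM2[i, -i] * gamma[-i])
      delta <- e_tau * (g[i] * mu[i] - 0.5 * GM2[i, i] - cross)
      gamma[i] <- stats::plogis(prior_lo + delta)
    }

    W <- G * ezz(gamma)
    resid <- ss$yss - 2 * sum(gamma * mu * g) + sum(W * M2)
    beta <- beta0 + resid / 2
    e_tau <- alpha / beta

    F_new <- free_energy_terms(ss$n_eff, alpha, beta, resid, mu, Sigma,
                               pv$m0, pv$l0, alpha0, beta0) -
      kl_bernoulli(gamma[!exempt], p0)
    F_trace <- c(F_trace, F_new)
    if (is.finite(F_old) && abs(F_new - F_old) < config$tol) {
      converged <- TRUE
      F_old <- F_new
      break
    }
    F_old <- F_new
  }
  if (!converged) {
    warning("region ", r, ": sparse VB did not converge in ",
            config$max_iter, " sweeps")
  }
  structure(list(mu = mu, Sigma = Sigma, alpha = alpha, beta = beta,
                 gamma = gamma, p0 = p0, F = F_old, F_trace = F_trace,
                 iterations = length(F_trace), converged = converged,
                 columns = ss$cols, region = r),
            class = c("sparse_region_posterior", "region_posterior"))
}

#' Sparse rDCM inversion of a whole recording at a fixed p0
#'
#' @param recording a `session_recording`.
#' @param spec a [network_specification()].
#' @param priors a [prior_specification()].
#' @param p0 prior inclusion probability.
#' @param config a [sparsity_config()].
#' @return `rdcm_result` (variant "sparse") carrying per-region
#'   `sparse_region_posterior`s and a `gamma_A` / `gamma_C` matrix pair of
#'   posterior inclusion probabilities.
#' @export
invert_model_sparse <- function(recording, spec, priors = prior_specification(),
                                p0 = 0.5, config = sparsity_config()) {
  design <- build_frequency_design(recording, spec)
  posteriors <- lapply(seq_len(spec$n_regions), function(r) {
    sparse_vb_region(design, r, priors, p0, config)
  })
  R <- spec$n_regions; K <- spec$n_inputs
  gA <- matrix(0, R, R); gC <- matrix(0, R, max(K, 0))
  for (r in seq_len(R)) {
    po <- posteriors[[r]]
    is_reg <- po$columns <= R
    gA[r, po$columns[is_reg]] <- po$gamma[is_reg]
    if (K > 0 && any(!is_reg)) gC[r, po$columns[!is_reg] - R] <- po$gamma[!is_reg]
  }
  assemble_result(design, posteriors, variant = "sparse",
                  extra = list(gamma_A = gA, gamma_C = gC, p0 = p0))
}

#' Line search over the Bernoulli prior parameter p0
#'
#' Inverts the recording once per candidate p0 and selects the value with the
#' highest total negative free energy (summed over regions), mirroring the
#' per-participant model-evidence line search. Ties are broken toward the
#' larger (denser) p0 with a message.
#'
#' @param recording a `session_recording`.
#' @param spec a [network_specification()].
#' @param priors a [prior_specification()].
#' @param config a [sparsity_config()] (its `p0_grid` defines the search).
#' @return list: `best_p0`, `F_table` (data frame p0 / F), `best_fit`
#'   (the `rdcm_result` at the selected p0), `fits` (all fits, named by p0).
#' @export
line_search_p0 <- function(recording, spec, priors = prior_specification(),
                           config = sparsity_config()) {
  grid <- config$p0_grid
  fits <- lapply(grid, function(p0) {
    tryCatch(invert_model_sparse(recording, spec, priors, p0, config),
             error = function(e) e)
  })
  failed <- vapply(fits, inherits, TRUE, "error")
  if (all(failed)) {
    stop("sparse inversion failed for every p0 in the grid; first error: ",
         conditionMessage(fits[[1]]))
  }
  Fs <- ifelse(failed, -Inf, vapply(fits, function(f) f$F, 0))
  best <- max(which(Fs == max(Fs)))   # ties -> larger p0
  if (sum(Fs == max(Fs)) > 1) {
    message("p0 line search tie; keeping the denser model (p0 = ",
            grid[best], ")")
  }
  names(fits) <- format(grid)
  list(best_p0 = grid[best],
       F_table = data.frame(p0 = grid, F = Fs),
       best_fit = fits[[best]],
       fits = fits[!failed])
}

#' Prune a sparse rDCM result to a sparse connectivity estimate
#'
#' Parameters whose posterior inclusion probability falls below the
#' threshold are set to exactly zero (mean and variance); the rest keep
#' their posterior means. Exempt self-connections are never pruned.
#'
#' @param fit an `rdcm_result` from [invert_model_sparse()] or
#'   [line_search_p0()].
#' @param config a [sparsity_config()].
#' @return `rdcm_result` with pruned `A_mean` / `A_var` / `C_mean` / `C_var`
#'   and logical support matrices `support_A`, `support_C`.
#' @export
prune_result <- function(fit, config = sparsity_config()) {
  stopifnot(!is.null(fit$gamma_A))
  thr <- config$inclusion_threshold
  keep_A <- fit$gamma_A >= thr
  if (config$exempt_self_connections) diag(keep_A) <- TRUE
  out <- fit
  out$A_mean[!keep_A] <- 0
  out$A_var[!keep_A] <- 0
  if (length(fit$C_mean)) {
    keep_C <- fit$gamma_C >= thr
    out$C_mean[!keep_C] <- 0
    out$C_var[!keep_C] <- 0
    out$support_C <- keep_C
  } else {
    out$support_C <- matrix(FALSE, nrow(fit$A_mean), 0)
  }
  out$support_A <- keep_A
  out$pruned <- TRUE
  out
}
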