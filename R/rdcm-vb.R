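#' Prior specification for the per-region Bayesian regression
#'
#' Conjugate Gaussian priors on the coupling / driving-input parameters and a
#' Gamma prior on each region's noise precision. Between-region couplings and
#' input gains get a zero-centred unit-precision prior; inhibitory
#' self-connections are shrunk towards -0.5 with precision 16.
#'
#' @param mean_connection,precision_connection prior moments for off-diagonal
#'   couplings and input gains.
#' @param mean_self,precision_self prior moments for self-connections.
#' @param alpha0,beta0 Gamma shape and rate for the noise precision.
#' @return object of class `prior_spec`.
#' @export
prior_specification <- function(mean_connection = 0, precision_connection = 1,
                                mean_self = -0.5, precision_self = 16,
                                alpha0 = 2, beta0 = 1) {
  stopifnot(precision_connection > 0, precision_self > 0, alpha0 > 0, beta0 > 0)
  structure(list(mean_connection = mean_connection,
                 precision_connection = precision_connection,
                 mean_self = mean_self, precision_self = precision_self,
                 alpha0 = alpha0, beta0 = beta0),
            class = "prior_spec")
}

# per-column prior mean / precision vectors for region r's design columns
region_prior_vectors <- function(design, r, priors) {
  cols <- design_columns(design, r)
  m0 <- rep(priors$mean_connection, length(cols))
  l0 <- rep(priors$precision_connection, length(cols))
  self <- which(cols == r)
  m0[self] <- priors$mean_self
  l0[self] <- priors$precision_self
  list(cols = cols, m0 = m0, l0 = l0)
}

# sufficient statistics of one region's complex regression problem.
# Re(X^H X) and Re(X^H Y) are exactly the Gram/cross products of the
# stacked real+imaginary representation, giving N_eff = 2N real observations.
region_suffstats <- function(design, r) {
  cols <- design_columns(design, r)
  Xr <- design$X[, cols, drop = FALSE]
  Yr <- design$Y[, r]
  G <- Re(crossprod(Conj(Xr), Xr))
  g <- as.numeric(Re(crossprod(Conj(Xr), Yr)))
  list(G = G, g = g, yss = sum(Mod(Yr)^2), n_eff = 2 * design$N, cols = cols)
}

logdet_sym <- function(M) {
  2 * sum(log(diag(chol(M))))
}

kl_gamma <- function(alpha, beta, alpha0, beta0) {
  (alpha - alpha0) * digamma(alpha) - lgamma(alpha) + lgamma(alpha0) +
    alpha0 * (log(beta) - log(beta0)) + alpha * (beta0 - beta) / beta
}

# F = E_q[log lik] - KL(q(theta)||p) - KL(q(tau)||p) for the Gaussian/Gamma
# factorisation; `resid` is E_q ||Y - X theta||^2 (complex squared magnitudes)
free_energy_terms <- function(n_eff, alpha, beta, resid, mu, Sigma, m0, l0,
                              alpha0, beta0) {
  e_log_tau <- digamma(alpha) - log(beta)
  e_tau <- alpha / beta
  e_lik <- n_eff / 2 * (e_log_tau - log(2 * pi)) - e_tau / 2 * resid
  d <- mu - m0
  kl_theta <- 0.5 * (sum(l0 * diag(Sigma)) + sum(l0 * d^2) - length(mu) -
                       logdet_sym(Sigma) - sum(log(l0)))
  e_lik - kl_theta - kl_gamma(alpha, beta, alpha0, beta0)
}

#' Variational-Bayes inversion of one region's frequency-domain regression
#'
#' Closed-form coordinate ascent on the mean-field factorisation
#' q(theta_r) q(tau_r): the Gaussian factor is updated from the regularised
#' normal equations with the current noise-precision mean, the Gamma factor
#' from the expected residual power; the negative free energy is evaluated
#' after every sweep and is non-decreasing. All N complex DFT bins are kept
#' and counted as 2N real observations.
#'
#' @param design a [build_frequency_design()] result.
#' @param r region index.
#' @param priors a [prior_specification()].
#' @param tol convergence tolerance on the change in negative free energy.
#' @param max_iter maximum number of sweeps.
#' @return object of class `region_posterior`: `mu`, `Sigma`, `alpha`, `beta`,
#'   `F` (converged negative free energy), `F_trace`, `iterations`,
#'   `converged`, `columns` (design column indices), `region`.
#' @export
vb_update_region <- function(design, r, priors = prior_specification(),
                             tol = 1e-8, max_iter = 500) {
  pv <- region_prior_vectors(design, r, priors)
  ss <- region_suffstats(design, r)
  G <- ss$G; g <- ss$g; P <- length(pv$m0)
  alpha0 <- priors$alpha0; beta0 <- priors$beta0
  alpha <- alpha0 + ss$n_eff / 2          # fixed across sweeps
  e_tau <- alpha0 / beta0
  F_trace <- numeric(0)
  F_old <- -Inf
  beta <- beta0
  mu <- pv$m0; Sigma <- diag(1 / pv$l0, P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prec <- diag(pv$l0, P) + e_tau * G
    Sigma <- tryCatch(chol2inv(chol(prec)), error = function(e)
      stop("posterior precision not positive definite in region ", r))
    mu <- as.numeric(Sigma %*% (pv$l0 * pv$m0 + e_tau * g))
    M2 <- Sigma + tcrossprod(mu)
    resid <- ss$yss - 2 * sum(mu * g) + sum(G * M2)
    beta <- beta0 + resid / 2
    e_tau <- alpha / beta
    F_new <- free_energy_terms(ss$n_eff, alpha, beta, resid, mu, Sigma,
                               pv$m0, pv$l0, alpha0, beta0)
    F_trace <- c(F_trace, F_new)
    if (is.finite(F_old) && abs(F_new - F_old) < tol) {
      converged <- TRUE
      F_old <- F_new
      break
    }
    F_old <- F_new
  }
  if (!converged) {
    warning("region ", r, ": VB did not converge in ", max_iter, " sweeps")
  }
  structure(list(mu = mu, Sigma = Sigma, alpha = alpha, beta = beta,
                 F = F_old, F_trace = F_trace, iterations = length(F_trace),
                 converged = converged, columns = ss$cols, region = r),
            class = "region_posterior")
}

#' Negative free energy of a region posterior
#'
#' Recomputes F = E_q[log p(Y|theta,tau)] - KL(q(theta)||p(theta)) -
#' KL(q(tau)||p(tau)) from a posterior and the design it was fit to. Matches
#' the converged value reported by [vb_update_region()].
#'
#' @param design a `frequency_design`.
#' @param posterior a `region_posterior`.
#' @param priors the `prior_spec` used for the fit.
#' @return scalar negative free energy.
#' @export
negative_free_energy <- function(design, posterior, priors = prior_specification()) {
  r <- posterior$region
  pv <- region_prior_vectors(design, r, priors)
  ss <- region_suffstats(design, r)
  M2 <- posterior$Sigma + tcrossprod(posterior$mu)
  resid <- ss$yss - 2 * sum(posterior$mu * ss$g) + sum(ss$G * M2)
  free_energy_terms(ss$n_eff, posterior$alpha, posterior$beta, resid,
                    posterior$mu, posterior$Sigma, pv$m0, pv$l0,
                    priors$alpha0, priors$beta0)
}

# assemble per-region posteriors into A/C mean and variance matrices
assemble_result <- function(design, posteriors, variant = "classical",
                            extra = list()) {
  R <- design$n_regions; K <- design$n_inputs
  A_mean <- matrix(0, R, R); A_var <- matrix(0, R, R)
  C_mean <- matrix(0, R, max(K, 0)); C_var <- matrix(0, R, max(K, 0))
  for (r in seq_len(R)) {
    po <- posteriors[[r]]
    cols <- po$columns
    v <- diag(po$Sigma)
    is_reg <- cols <= R
    A_mean[r, cols[is_reg]] <- po$mu[is_reg]
    A_var[r, cols[is_reg]] <- v[is_reg]
    if (K > 0 && any(!is_reg)) {
      kc <- cols[!is_reg] - R
      C_mean[r, kc] <- po$mu[!is_reg]
      C_var[r, kc] <- v[!is_reg]
    }
  }
  structure(c(list(A_mean = A_mean, A_var = A_var, C_mean = C_mean,
                   C_var = C_var, F = sum(vapply(posteriors, `[[`, 0, "F")),
                   regions = posteriors, variant = variant,
                   region_labels = design$region_labels), extra),
            class = "rdcm_result")
}

#' Invert a whole recording with classical rDCM
#'
#' Builds the frequency-domain design and runs the per-region VB inversion
#' independently for every region (the mean-field approximation across
#' regions), assembling posterior means and variances into A / C matrices.
#' Entry (r, j) of the A matrices is the afferent connection from region j
#' to region r.
#'
#' @param recording a `session_recording`.
#' @param spec a [network_specification()].
#' @param priors a [prior_specification()].
#' @param tol,max_iter convergence controls passed to [vb_update_region()].
#' @return object of class `rdcm_result`: `A_mean`, `A_var`, `C_mean`,
#'   `C_var`, total negative free energy `F`, and the per-region posteriors.
#' @export
invert_model <- function(recording, spec, priors = prior_specification(),
                         tol = 1e-8, max_iter = 500) {
  design <- build_frequency_design(recording, spec)
  posteriors <- lapply(seq_len(spec$n_regions), function(r) {
    tryCatch(vb_update_region(design, r, priors, tol, max_iter),
             error = function(e) stop("inversion failed in region ", r, ": ",
                                      conditionMessage(e)))
  })
  assemble_result(design, posteriors, variant = "classical")
}
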