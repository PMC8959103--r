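#' Pearson functional connectivity matrix
#'
#' Full pairwise Pearson correlation of the regional time series. Regions
#' with zero variance yield NA entries (reported with a warning); an
#' all-constant recording is an error.
#'
#' @param recording a `session_recording` (or a plain numeric matrix,
#'   volumes x regions).
#' @return object of class `fc_matrix` with fields `values` (R x R), `kind`.
#' @export
fc_pearson <- function(recording) {
  bold <- if (is.matrix(recording)) recording else recording$bold
  if (nrow(bold) < 3) stop("need at least 3 volumes")
  sds <- apply(bold, 2, stats::sd)
  if (all(sds == 0)) stop("all regions are constant; correlation undefined")
  if (any(sds == 0)) {
    warning("zero-variance region(s) ", paste(which(sds == 0), collapse = ", "),
            "; entries set to NA")
  }
  vals <- suppressWarnings(stats::cor(bold))
  diag(vals) <- 1
  structure(list(values = vals, kind = "pearson", lambda = NULL),
            class = "fc_matrix")
}

# soft-threshold operator
soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# graphical lasso: block coordinate descent on the penalised precision
# (Friedman, Hastie & Tibshirani 2008), inner lasso by coordinate descent
graphical_lasso <- function(S, lambda, tol = 1e-6, max_iter = 200) {
  p <- ncol(S)
  W <- S + diag(lambda, p)
  B <- matrix(0, p - 1, p)           # lasso coefficients per column
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx]
      s12 <- S[idx, j]
      b <- B[, j]
      for (inner in seq_len(200)) {
        b_old <- b
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, -k] * b[-k])
          b[k] <- soft(r, lambda) / W11[k, k]
        }
        if (max(abs(b - b_old)) < tol * 0.1) break
      }
      B[, j] <- b
      W[idx, j] <- W11 %*% b
      W[j, idx] <- W[idx, j]
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(diag(S)))) break
  }
  Omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    o22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Omega[j, j] <- o22
    Omega[idx, j] <- -B[, j] * o22
  }
  (Omega + t(Omega)) / 2
}

#' L1-regularised partial correlation matrix
#'
#' Estimates a sparse precision matrix by L1-penalised Gaussian maximum
#' likelihood (graphical lasso; plain inverse covariance when `lambda = 0`)
#' on standardized time series, then converts to partial correlations
#' \eqn{\rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}} with a unit
#' diagonal by convention.
#'
#' @param recording a `session_recording` or numeric matrix.
#' @param lambda nonnegative L1 penalty on off-diagonal precision entries.
#' @return `fc_matrix` with `kind = "l1_partial"` and the penalty recorded.
#' @export
fc_l1_partial <- function(recording, lambda = 0.1) {
  bold <- if (is.matrix(recording)) recording else recording$bold
  stopifnot(lambda >= 0)
  p <- ncol(bold)
  if (lambda == 0 && nrow(bold) <= p) {
    stop("lambda = 0 requires more volumes than regions for an invertible ",
         "covariance; increase lambda")
  }
  Z <- scale(bold)
  S <- stats::cov(Z)
  Omega <- if (lambda == 0) solve(S) else graphical_lasso(S, lambda)
  d <- sqrt(diag(Omega))
  vals <- -Omega / tcrossprod(d)
  diag(vals) <- 1
  vals <- pmin(pmax(vals, -1), 1)
  structure(list(values = vals, kind = "l1_partial", lambda = lambda),
            class = "fc_matrix")
}
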