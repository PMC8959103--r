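#' Network architecture specification
#'
#' Binary masks declaring which afferent couplings and driving-input gains
#' are estimated. The diagonal of the A mask (inhibitory self-connections) is
#' always present.
#'
#' @param n_regions number of regions R.
#' @param n_inputs number of driving inputs K.
#' @param A_mask R x R binary matrix (default all ones: fully connected).
#' @param C_mask R x K binary matrix (default all ones: full C matrix).
#' @param region_labels optional character vector of length R.
#' @return object of class `network_spec`.
#' @export
network_specification <- function(n_regions, n_inputs = 0,
                                  A_mask = NULL, C_mask = NULL,
                                  region_labels = NULL) {
  R <- as.integer(n_regions); K <- as.integer(n_inputs)
  if (is.null(A_mask)) A_mask <- matrix(1L, R, R)
  if (is.null(C_mask)) C_mask <- matrix(1L, R, max(K, 0))
  stopifnot(all(dim(A_mask) == c(R, R)))
  if (K > 0) stopifnot(all(dim(C_mask) == c(R, K)))
  diag(A_mask) <- 1L
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(R))
  structure(list(n_regions = R, n_inputs = K,
                 A_mask = (A_mask != 0) * 1L,
                 C_mask = if (K > 0) (C_mask != 0) * 1L else matrix(0L, R, 0),
                 region_labels = region_labels),
            class = "network_spec")
}

#' Number of free between-region coupling parameters in a network
#'
#' @param spec a [network_specification()].
#' @return count of off-diagonal entries of the A mask that are estimated.
#' @export
count_between_parameters <- function(spec) {
  m <- spec$A_mask
  diag(m) <- 0L
  sum(m)
}

#' Build the frequency-domain regression problem
#'
#' Transforms a recording into the per-region linear model in the DFT domain:
#' the response for region r is the DFT of the temporal derivative of its
#' BOLD signal, \eqn{Y_r = (e^{2\pi i m/N} - 1)\,\hat y_r / TR}, and the
#' shared design matrix stacks the DFTs of all region signals followed by the
#' DFTs of the HRF-convolved driving inputs. The derivative factor
#' annihilates the m = 0 (DC) bin. Products of N-point DFTs correspond to
#' circular convolution in time; the synthetic cohort's event schedules are
#' built to end early enough that the wrap-around is negligible.
#'
#' @param recording a `session_recording`.
#' @param spec a [network_specification()] matching the recording dimensions.
#' @param hrf HRF sampled at TR (defaults to [canonical_hrf()] at the
#'   recording's TR); truncated or zero-padded to N before its DFT.
#' @return object of class `frequency_design`: complex response matrix `Y`
#'   (N x R), complex full design matrix `X` (N x (R+K), region columns then
#'   input columns), masks, `N`, `TR`, labels.
#' @export
build_frequency_design <- function(recording, spec, hrf = NULL) {
  bold <- recording$bold
  N <- nrow(bold); R <- ncol(bold)
  if (N < 8) stop("need at least 8 volumes")
  if (R != spec$n_regions) stop("recording has ", R, " regions; spec declares ",
                                spec$n_regions)
  K <- spec$n_inputs
  U <- recording$inputs
  if (K > 0 && (is.null(U) || ncol(U) < K)) {
    stop("spec declares ", K, " inputs but the recording provides fewer")
  }
  TR <- recording$TR
  if (is.null(hrf)) hrf <- canonical_hrf(TR, duration_s = min(32, N * TR))

  yhat <- stats::mvfft(bold)
  m <- 0:(N - 1)
  dfac <- exp(2i * pi * m / N) - 1
  Y <- sweep(yhat, 1, dfac, `*`) / TR

  if (K > 0) {
    h <- hrf[seq_len(min(length(hrf), N))]
    hpad <- c(h, rep(0, N - length(h)))
    hhat <- stats::fft(hpad)
    uhat <- stats::mvfft(U[, seq_len(K), drop = FALSE])
    # TR factor: DFT of the TR-sampled continuous convolution h (*) u,
    # keeping driving-input gains in 1/s units. The extra phase factor
    # advances the stimulus by one volume so that the forward difference over
    # (n, n+1] is paired with the input delivered in that same interval.
    Xu <- sweep(uhat, 1, hhat * dfac_shift(N), `*`) * TR
  } else {
    Xu <- matrix(0 + 0i, N, 0)
  }
  X <- cbind(yhat, Xu)
  colnames(X) <- c(spec$region_labels,
                   if (K > 0) paste0("u", seq_len(K)) else character(0))

  structure(list(Y = Y, X = X, A_mask = spec$A_mask, C_mask = spec$C_mask,
                 n_regions = R, n_inputs = K, N = N, TR = TR,
                 region_labels = spec$region_labels),
            class = "frequency_design")
}

# one-volume advance in the DFT domain
dfac_shift <- function(N) exp(2i * pi * (0:(N - 1)) / N)

# indices into the full design for region r's masked columns
design_columns <- function(design, r) {
  reg <- which(design$A_mask[r, ] == 1L)
  inp <- if (design$n_inputs > 0) {
    design$n_regions + which(design$C_mask[r, ] == 1L)
  } else integer(0)
  c(reg, inp)
}
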