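#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical two-gamma HRF
#' \deqn{h(t) = g(t; a_1, b_1) - c\, g(t; a_2, b_2)}
#' where \eqn{g} is the gamma density, on a regular grid of spacing \code{TR}
#' starting at \eqn{t = 0}. The defaults (peak shape 6, undershoot shape 16,
#' rates 1/s, undershoot ratio 1/6) give the familiar positive peak at about
#' 5 s followed by a shallow undershoot, and integrate to \eqn{1 - c} over an
#' infinite horizon.
#'
#' @param TR sampling interval in seconds (> 0).
#' @param duration_s length of the sampled kernel in seconds (>= 24).
#' @param hrf_params list with elements \code{a1}, \code{b1} (peak gamma shape
#'   and rate), \code{a2}, \code{b2} (undershoot gamma shape and rate) and
#'   \code{c} (undershoot amplitude ratio).
#' @return numeric vector of HRF samples at \code{t = 0, TR, 2 TR, ...}
#'   covering \code{duration_s} seconds; \code{h(0) == 0}.
#' @examples
#' h <- canonical_hrf(0.72, 32)
#' (which.max(h) - 1) * 0.72   # peak latency, seconds
#' @export
canonical_hrf <- function(TR, duration_s = 32, hrf_params = default_hrf_params()) {
  stopifnot(is.numeric(TR), length(TR) == 1L, TR > 0)
  if (duration_s < 24) {
    stop("HRF duration must be at least 24 s to contain peak and undershoot")
  }
  p <- hrf_params
  if (any(c(p$a1, p$b1, p$a2, p$b2) <= 0)) {
    stop("gamma shape and rate parameters of the HRF must be positive")
  }
  t <- seq(0, duration_s, by = TR)
  stats::dgamma(t, shape = p$a1, rate = p$b1) -
    p$c * stats::dgamma(t, shape = p$a2, rate = p$b2)
}

#' Default double-gamma HRF parameters
#'
#' @return list of shape/rate/undershoot parameters used by
#'   [canonical_hrf()].
#' @export
default_hrf_params <- function() {
  list(a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1 / 6)
}
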