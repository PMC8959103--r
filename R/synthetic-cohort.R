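#' Simulation configuration for the synthetic two-session cohort
#'
#' Bundles all knobs of the forward model: network size, run length,
#' repetition time, acquisition mode, signal-to-noise ratio, and the
#' integration / HRF settings. The defaults mirror a fast-TR whole-brain
#' acquisition (TR = 0.72 s) with a block-design task.
#'
#' @param n_regions number of network nodes R (>= 2).
#' @param n_inputs number of driving inputs K (forced to 0 in rest mode).
#' @param n_subjects cohort size S.
#' @param n_volumes volumes per run N (>= 32).
#' @param repetition_time TR in seconds.
#' @param mode `"task"` (boxcar driving inputs plus neuronal noise) or
#'   `"rest"` (neuronal noise only, all-zero C matrix).
#' @param snr per-region ratio of the temporal SD of the noiseless BOLD to the
#'   SD of the additive observation noise.
#' @param neuronal_sd SD of the white neuronal innovations driving the latent
#'   states (diffusion-scaled at the integration step), in state units.
#' @param upsample_factor Euler integration steps per TR.
#' @param between_sd_scale between-subject SD of each nonzero parameter as a
#'   fraction of the absolute group mean.
#' @param coupling_range length-2 positive vector: magnitudes of nonzero
#'   off-diagonal couplings are drawn uniformly from this range (1/s), with
#'   random sign.
#' @param input_gain_range length-2 positive vector: magnitudes of driving
#'   input gains (1/s), with random sign.
#' @param self_connection self-connection value placed on the diagonal of the
#'   group A matrix (1/s, must be negative).
#' @param master_seed integer seed from which all per-subject / per-session
#'   streams are derived.
#' @param hrf_params see [canonical_hrf()].
#' @param event_schedule optional data frame (onset_s, duration_s, input_index,
#'   amplitude); built by [default_event_schedule()] when `NULL` in task mode.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_regions = 20, n_inputs = 3, n_subjects = 10,
                              n_volumes = 600, repetition_time = 0.72,
                              mode = c("task", "rest"), snr = 3,
                              neuronal_sd = 0.2, upsample_factor = 8,
                              between_sd_scale = 0.25,
                              coupling_range = c(0.2, 0.6),
                              input_gain_range = c(0.2, 0.5),
                              self_connection = -0.5,
                              master_seed = 1L,
                              hrf_params = default_hrf_params(),
                              event_schedule = NULL) {
  mode <- match.arg(mode)
  if (mode == "rest") n_inputs <- 0L
  stopifnot(n_regions >= 2, n_volumes >= 32, repetition_time > 0, snr > 0,
            upsample_factor >= 1, between_sd_scale >= 0,
            self_connection < 0, n_subjects >= 1)
  cfg <- list(
    n_regions = as.integer(n_regions), n_inputs = as.integer(n_inputs),
    n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
    repetition_time = repetition_time, mode = mode, snr = snr,
    neuronal_sd = neuronal_sd, upsample_factor = as.integer(upsample_factor),
    between_sd_scale = between_sd_scale, coupling_range = coupling_range,
    input_gain_range = input_gain_range, self_connection = self_connection,
    master_seed = as.integer(master_seed), hrf_params = hrf_params,
    event_schedule = event_schedule
  )
  if (mode == "task" && is.null(cfg$event_schedule) && n_inputs > 0) {
    cfg$event_schedule <- default_event_schedule(cfg)
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Default stimulation schedule
#'
#' By default a randomized rapid event-related design: per input condition,
#' brief (2 s) events at jittered onsets, roughly one event per `isi_s`
#' seconds of run — the standard design for estimation efficiency. A blocked
#' design (boxcars with fixed gaps, the classic detection design) is
#' available via `type = "block"`. Either way the last event ends at least
#' 16 s before the end of the run so the HRF tail does not wrap around the
#' circular convolution implied by the N-point DFT. The randomized schedule
#' is drawn from a stream derived from the configuration's master seed.
#'
#' @param config a [simulation_config()].
#' @param type `"event"` (randomized event-related) or `"block"`.
#' @param duration_s event (or block) duration in seconds.
#' @param isi_s mean inter-onset interval per condition (event design).
#' @param gap_s gap between successive blocks of one input (block design).
#' @return data frame with columns onset_s, duration_s, input_index, amplitude.
#' @export
default_event_schedule <- function(config, type = c("event", "block"),
                                   duration_s = NULL, isi_s = 14, gap_s = 30) {
  type <- match.arg(type)
  run_s <- config$n_volumes * config$repetition_time
  last_allowed <- run_s - 16
  ev <- list()
  if (type == "event") {
    if (is.null(duration_s)) duration_s <- 2
    n_ev <- max(3L, floor(last_allowed / isi_s))
    set.seed(derive_seed(config$master_seed, "schedule"))
    for (k in seq_len(config$n_inputs)) {
      onsets <- sort(stats::runif(n_ev, 0, last_allowed - duration_s))
      ev[[k]] <- data.frame(onset_s = onsets, duration_s = duration_s,
                            input_index = k, amplitude = 1)
    }
  } else {
    if (is.null(duration_s)) duration_s <- 15
    for (k in seq_len(config$n_inputs)) {
      onset <- (k - 1) * (duration_s + gap_s) / config$n_inputs
      while (onset + duration_s <= last_allowed) {
        ev[[length(ev) + 1L]] <- data.frame(
          onset_s = onset, duration_s = duration_s,
          input_index = k, amplitude = 1)
        onset <- onset + duration_s + gap_s
      }
    }
  }
  if (!length(ev)) stop("run too short to place any stimulation event")
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

# derive a 32-bit substream seed from the master seed and a stream label;
# polynomial hash over label tokens (characters fed individually so that
# e.g. subject ids 11 and 20 cannot collide)
derive_seed <- function(master_seed, ...) {
  ids <- list(...)
  s <- as.double(master_seed) %% 2147483647
  step <- function(s, v) (s * 69069 + v * 7919 + 1) %% 2147483647
  for (x in ids) {
    if (is.character(x)) {
      for (ch in utf8ToInt(x)) s <- step(s, ch)
    } else {
      s <- step(s, as.double(x))
    }
  }
  as.integer(s)
}

spectral_abscissa <- function(A) max(Re(eigen(A, only.values = TRUE)$values))

# rescale off-diagonal couplings until the spectral abscissa is below -margin;
# bisection keeps couplings as strong as stability allows
stabilise <- function(A, margin = 0.05, max_iter = 60L) {
  if (spectral_abscissa(A) < -margin) return(A)
  D <- diag(diag(A))
  E <- A - D
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (spectral_abscissa(D + mid * E) < -margin) lo <- mid else hi <- mid
  }
  if (lo == 0) {
    stop("could not stabilise coupling matrix; diagonal decay too weak ",
         "for an unstable configuration")
  }
  D + lo * E
}

#' Draw group-level ground-truth coupling and input matrices
#'
#' Off-diagonal couplings are drawn from a zero-symmetric mixture (random sign
#' times a uniform magnitude from `coupling_range`) on a random support of the
#' requested density; the diagonal is fixed at the inhibitory self-connection.
#' The off-diagonal block is halved until the spectral abscissa is below
#' -0.05/s, guaranteeing stable subject dynamics. In rest mode the C matrix is
#' identically zero.
#'
#' @param config a [simulation_config()].
#' @param density fraction of off-diagonal connections truly present (0, 1].
#' @param seed optional seed; defaults to a stream derived from the master seed.
#' @return object of class `ground_truth` with fields `group_A`, `group_C`,
#'   `between_sd_scale`, `sparsity_mask_A`, `sparsity_mask_C`.
#' @export
sample_group_truth <- function(config, density = 1, seed = NULL) {
  stopifnot(density > 0, density <= 1)
  R <- config$n_regions; K <- config$n_inputs
  if (is.null(seed)) seed <- derive_seed(config$master_seed, "truth")
  set.seed(seed)

  mask_A <- matrix(0L, R, R)
  off_idx <- which(row(mask_A) != col(mask_A))
  n_on <- max(1L, round(density * length(off_idx)))
  mask_A[sample(off_idx, n_on)] <- 1L
  diag(mask_A) <- 1L

  A <- matrix(0, R, R)
  n_off <- sum(mask_A == 1L & row(mask_A) != col(mask_A))
  mag <- stats::runif(n_off, config$coupling_range[1], config$coupling_range[2])
  sgn <- sample(c(-1, 1), n_off, replace = TRUE)
  A[mask_A == 1L & row(mask_A) != col(mask_A)] <- sgn * mag
  diag(A) <- config$self_connection
  A <- stabilise(A)

  if (config$mode == "rest" || K == 0) {
    C <- matrix(0, R, max(K, 0))
    mask_C <- matrix(0L, R, max(K, 0))
  } else {
    mask_C <- matrix(1L, R, K)
    magc <- stats::runif(R * K, config$input_gain_range[1], config$input_gain_range[2])
    sgnc <- sample(c(-1, 1), R * K, replace = TRUE, prob = c(0.3, 0.7))
    C <- matrix(sgnc * magc, R, K)
  }

  structure(list(group_A = A, group_C = C,
                 between_sd_scale = config$between_sd_scale,
                 sparsity_mask_A = mask_A, sparsity_mask_C = mask_C),
            class = "ground_truth")
}

#' Sample one subject's coupling parameters around the group truth
#'
#' Each nonzero group parameter is perturbed by zero-mean Gaussian noise with
#' SD equal to `between_sd_scale` times its absolute group mean; zeros stay
#' exactly zero. Stability is re-enforced by the same halving rule used for
#' the group matrix, so strong draws are shrunk rather than rejected.
#'
#' @param truth a `ground_truth` object.
#' @param subject_seed integer seed for this subject's draw.
#' @return list with matrices `A` and `C`.
#' @export
sample_subject_parameters <- function(truth, subject_seed) {
  set.seed(as.integer(subject_seed))
  sc <- truth$between_sd_scale
  A <- truth$group_A
  nzA <- truth$sparsity_mask_A == 1L
  A[nzA] <- A[nzA] + stats::rnorm(sum(nzA), 0, sc * abs(truth$group_A[nzA]))
  # keep self-connections clearly inhibitory (inside the stability margin)
  diag(A) <- pmin(diag(A), -0.1)
  A <- stabilise(A)
  C <- truth$group_C
  if (length(C)) {
    nzC <- truth$sparsity_mask_C == 1L
    C[nzC] <- C[nzC] + stats::rnorm(sum(nzC), 0, sc * abs(truth$group_C[nzC]))
  }
  list(A = A, C = C)
}

# boxcar stimulus functions at volume resolution (N x K)
build_input_matrix <- function(config) {
  N <- config$n_volumes; K <- config$n_inputs; TR <- config$repetition_time
  U <- matrix(0, N, K)
  sched <- config$event_schedule
  if (K == 0 || is.null(sched)) return(U)
  t0 <- (seq_len(N) - 1) * TR
  for (i in seq_len(nrow(sched))) {
    on <- sched$onset_s[i]; off <- on + sched$duration_s[i]
    k <- sched$input_index[i]
    U[t0 >= on & t0 < off, k] <- U[t0 >= on & t0 < off, k] + sched$amplitude[i]
  }
  U
}

#' Simulate one subject-session BOLD recording
#'
#' Integrates the linear neuronal model dx/dt = A x + C u with fixed-step
#' Euler at TR/upsample_factor, adding diffusion-scaled white neuronal
#' innovations (the only drive in rest mode), convolves the states with the
#' canonical HRF, downsamples to TR and adds white Gaussian observation noise
#' scaled per region to the configured SNR.
#'
#' @param params list with subject matrices `A`, `C`.
#' @param config a [simulation_config()].
#' @param session_seed integer seed for this session's noise streams.
#' @param subject_id,session_id identifiers stored in the recording.
#' @return object of class `session_recording` with fields `bold` (N x R),
#'   `inputs` (N x K), `TR`, `subject_id`, `session_id`.
#' @export
simulate_session <- function(params, config, session_seed,
                             subject_id = 1L, session_id = 1L) {
  set.seed(as.integer(session_seed))
  A <- params$A; C <- params$C
  R <- nrow(A); N <- config$n_volumes; TR <- config$repetition_time
  up <- config$upsample_factor; dt <- TR / up
  n_fine <- N * up
  U <- build_input_matrix(config)

  # volume-resolution inputs held constant within each TR on the fine grid
  if (ncol(U) > 0) {
    U_fine <- U[rep(seq_len(N), each = up), , drop = FALSE]
  } else {
    U_fine <- matrix(0, n_fine, 0)
  }

  x <- matrix(0, n_fine, R)
  state <- numeric(R)
  M <- diag(R) + dt * A
  drive_all <- if (ncol(U_fine) > 0) U_fine %*% t(C) * dt else matrix(0, n_fine, R)
  innov <- matrix(stats::rnorm(n_fine * R), n_fine, R) * (config$neuronal_sd * sqrt(dt))
  for (n in seq_len(n_fine)) {
    state <- as.numeric(M %*% state) + drive_all[n, ] + innov[n, ]
    if (any(!is.finite(state))) {
      stop("non-finite neuronal state in region ",
           which(!is.finite(state))[1], " at step ", n)
    }
    x[n, ] <- state
  }

  h <- canonical_hrf(dt, duration_s = 32, hrf_params = config$hrf_params)
  y_fine <- apply(x, 2, function(col) {
    # linear (non-circular) convolution with the HRF, scaled by the step
    stats::convolve(col, rev(h), type = "open")[seq_len(n_fine)] * dt
  })
  bold <- y_fine[seq(up, n_fine, by = up), , drop = FALSE]

  sig_sd <- apply(bold, 2, stats::sd)
  noise_sd <- sig_sd / config$snr
  noise_sd[sig_sd == 0] <- 0
  bold <- bold + matrix(stats::rnorm(N * R), N, R) %*% diag(noise_sd, R)

  structure(list(bold = bold, inputs = U, TR = TR,
                 subject_id = subject_id, session_id = as.integer(session_id)),
            class = "session_recording")
}

#' Generate a full two-session cohort
#'
#' Draws the group truth, samples per-subject parameter sets, and simulates
#' two sessions per subject that share the subject's parameters but use
#' independent noise streams. Fully reproducible from the master seed.
#'
#' @param config a [simulation_config()].
#' @param density off-diagonal connection density passed to
#'   [sample_group_truth()].
#' @return object of class `cohort_dataset`: `recordings` (list of S lists of
#'   2 `session_recording`s), `truth` (group truth plus per-subject A, C),
#'   `config`, `provenance`.
#' @export
generate_cohort <- function(config, density = 1) {
  truth <- sample_group_truth(config, density = density)
  S <- config$n_subjects
  subjects <- vector("list", S)
  recordings <- vector("list", S)
  for (s in seq_len(S)) {
    subjects[[s]] <- sample_subject_parameters(
      truth, derive_seed(config$master_seed, "subject", s))
    recordings[[s]] <- lapply(1:2, function(j) {
      simulate_session(subjects[[s]], config,
                       derive_seed(config$master_seed, "subject", s, "session", j),
                       subject_id = s, session_id = j)
    })
  }
  structure(list(
    recordings = recordings,
    truth = list(group = truth, subjects = subjects),
    config = config,
    provenance = list(master_seed = config$master_seed, density = density)
  ), class = "cohort_dataset")
}
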