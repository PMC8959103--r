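# small deterministic fixtures shared across test files

tiny_config <- function(n_regions = 5, n_inputs = 2, n_subjects = 3,
                        n_volumes = 120, seed = 42, ...) {
  simulation_config(n_regions = n_regions, n_inputs = n_inputs,
                    n_subjects = n_subjects, n_volumes = n_volumes,
                    master_seed = seed, ...)
}

# one simulated recording plus its matching network spec
tiny_recording <- function(seed = 42, ...) {
  cfg <- tiny_config(seed = seed, ...)
  truth <- sample_group_truth(cfg)
  sub <- sample_subject_parameters(truth, seed * 7)
  rec <- simulate_session(sub, cfg, seed * 13)
  list(cfg = cfg, truth = truth, sub = sub, rec = rec,
       spec = network_specification(cfg$n_regions, cfg$n_inputs))
}

# hand-built frequency design for regression-level tests: complex response
# and regressor matrix wrapped in the design structure the VB code expects
toy_design <- function(X, y, TR = 1) {
  P <- ncol(X); N <- nrow(X)
  structure(list(Y = cbind(as.complex(y)), X = X + 0i,
                 A_mask = matrix(1L, 1, 1),
                 C_mask = matrix(1L, 1, P - 1),
                 n_regions = 1L, n_inputs = as.integer(P - 1), N = N, TR = TR,
                 region_labels = "R1"),
            class = "frequency_design")
}

# flat priors with an effectively fixed noise precision tau_star
fixed_tau_priors <- function(tau_star, precision = 1) {
  prior_specification(mean_connection = 0, precision_connection = precision,
                      mean_self = 0, precision_self = precision,
                      alpha0 = 1e12, beta0 = 1e12 / tau_star)
}

off_diagonal <- function(M) M[row(M) != col(M)]
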