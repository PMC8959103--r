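test_that("rest mode has no driving inputs and an all-zero C matrix", {
  cfg <- simulation_config(n_regions = 6, n_inputs = 4, n_subjects = 2,
                           n_volumes = 64, mode = "rest", master_seed = 1)
  expect_identical(cfg$n_inputs, 0L)
  truth <- sample_group_truth(cfg)
  expect_true(all(truth$group_C == 0))
})

test_that("sampled systems are stable by eigendecomposition", {
  for (seed in 1:8) {
    cfg <- tiny_config(n_regions = 12, seed = seed)
    truth <- sample_group_truth(cfg)
    expect_lt(max(Re(eigen(truth$group_A, only.values = TRUE)$values)), 0)
    sub <- sample_subject_parameters(truth, seed + 100)
    expect_lt(max(Re(eigen(sub$A, only.values = TRUE)$values)), 0)
  }
})

test_that("zero between-subject dispersion reproduces the group truth", {
  cfg <- tiny_config(between_sd_scale = 0)
  truth <- sample_group_truth(cfg)
  sub <- sample_subject_parameters(truth, 5)
  expect_identical(sub$A, truth$group_A)
  expect_identical(sub$C, truth$group_C)
})

test_that("between-subject dispersion has the configured SD", {
  cfg <- tiny_config(n_regions = 4, between_sd_scale = 0.25)
  truth <- sample_group_truth(cfg, density = 0.5)
  # pick one strong off-diagonal coupling and sample it many times
  idx <- which(truth$sparsity_mask_A == 1 & row(truth$group_A) != col(truth$group_A))
  target <- idx[which.max(abs(truth$group_A[idx]))]
  draws <- vapply(seq_len(10000), function(s)
    sample_subject_parameters(truth, s)$A[target], 0)
  expect_equal(stats::sd(draws), 0.25 * abs(truth$group_A[target]),
               tolerance = 0.1)
})

test_that("entries outside the sparsity mask stay exactly zero", {
  cfg <- tiny_config(n_regions = 8)
  truth <- sample_group_truth(cfg, density = 0.3)
  zero_idx <- truth$sparsity_mask_A == 0
  expect_true(any(zero_idx))
  for (s in 1:5) {
    expect_true(all(sample_subject_parameters(truth, s)$A[zero_idx] == 0))
  }
})

test_that("a zero-input noiseless system produces identically zero BOLD", {
  cfg <- tiny_config(n_regions = 3, n_inputs = 0, n_volumes = 64,
                     mode = "rest", neuronal_sd = 0)
  params <- list(A = diag(-0.5, 3), C = matrix(0, 3, 0))
  rec <- simulate_session(params, cfg, 1)
  expect_true(all(rec$bold == 0))
})

test_that("single-region impulse response matches the closed-form oracle", {
  N <- 200; TR <- 0.72; a <- -0.5; cc <- 0.3
  cfg <- simulation_config(n_regions = 2, n_inputs = 1, n_subjects = 1,
                           n_volumes = N, neuronal_sd = 0, snr = 1,
                           master_seed = 1)
  cfg$n_regions <- 1L
  cfg$event_schedule <- data.frame(onset_s = 19 * TR, duration_s = TR,
                                   input_index = 1, amplitude = 1)
  cfg$snr <- 1e12                      # negligible observation noise
  rec <- simulate_session(list(A = matrix(a, 1, 1), C = matrix(cc, 1, 1)),
                          cfg, 3)
  # independent reference: exact exponential integrator + direct convolution
  dt <- TR / cfg$upsample_factor
  tf <- seq(dt, N * TR, by = dt)
  u_f <- as.numeric(tf > 19 * TR & tf <= 20 * TR)
  x_ref <- as.numeric(stats::filter(cc * dt * u_f, exp(a * dt),
                                    method = "recursive"))
  h_f <- canonical_hrf(dt, 32)
  y_ref <- vapply(seq_along(tf), function(n) {
    k <- seq_len(min(n, length(h_f)))
    sum(h_f[k] * x_ref[n - k + 1]) * dt
  }, 0)
  y_ref <- y_ref[seq(cfg$upsample_factor, length(tf), cfg$upsample_factor)]
  expect_equal(rec$bold[, 1], y_ref, tolerance = 0.02)
})

test_that("realized SNR matches the configured value", {
  cfg <- simulation_config(n_regions = 50, n_inputs = 2, n_subjects = 1,
                           n_volumes = 320, snr = 3, master_seed = 9)
  truth <- sample_group_truth(cfg)
  sub <- sample_subject_parameters(truth, 11)
  noisy <- simulate_session(sub, cfg, 21)
  clean_cfg <- cfg; clean_cfg$snr <- 1e12
  clean <- simulate_session(sub, clean_cfg, 21)   # same noise stream order
  noise <- noisy$bold - clean$bold
  ratio <- apply(clean$bold, 2, stats::sd) / apply(noise, 2, stats::sd)
  # configured ratio up to the sampling error of the realized noise SD
  expect_equal(mean(ratio), 3, tolerance = 0.1)
  expect_true(all(ratio > 2.5 & ratio < 3.5))
})

test_that("cohort generation is deterministic and correctly structured", {
  cfg <- tiny_config(n_subjects = 4)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  expect_length(co1$recordings, 4)
  expect_length(unlist(co1$recordings, recursive = FALSE), 8)
  expect_length(co1$truth$subjects, 4)
  # sessions share truth but differ in data
  expect_false(identical(co1$recordings[[1]][[1]]$bold,
                         co1$recordings[[1]][[2]]$bold))
  # distinct subjects get distinct parameters
  expect_false(identical(co1$truth$subjects[[1]]$A, co1$truth$subjects[[2]]$A))
})

test_that("derived substream seeds do not collide across subjects/sessions", {
  seeds <- unlist(lapply(1:50, function(s) lapply(1:2, function(j)
    rdcmrel:::derive_seed(1L, "subject", s, "session", j))))
  expect_false(any(duplicated(seeds)))
})

test_that("event schedules end well before the end of the run", {
  cfg <- tiny_config(n_volumes = 200)
  sched <- cfg$event_schedule
  run_s <- cfg$n_volumes * cfg$repetition_time
  expect_true(all(sched$onset_s + sched$duration_s <= run_s - 16))
  blocks <- default_event_schedule(cfg, type = "block")
  expect_true(all(blocks$onset_s + blocks$duration_s <= run_s - 16))
})
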