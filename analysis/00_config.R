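# Shared study configuration for the analysis scripts. A two-session,
# ten-subject, ten-region task cohort at desk scale; every script rebuilds
# what it needs deterministically from this one seed.

library(rdcmrel)

study_config <- function() {
  simulation_config(n_regions = 10, n_inputs = 3, n_subjects = 10,
                    n_volumes = 300, repetition_time = 0.72, snr = 3,
                    master_seed = 20260929L)
}

study_spec <- function(cfg = study_config()) {
  network_specification(cfg$n_regions, cfg$n_inputs)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# classical rDCM fits for the whole cohort (used by several scripts)
fit_cohort_classical <- function(cohort, spec) {
  lapply(cohort$recordings, function(ss) lapply(ss, invert_model, spec = spec))
}
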