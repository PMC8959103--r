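#' Run configuration for the end-to-end reliability pipeline
#'
#' Bundles the stage toggles, the cohort configuration, and the knobs of the
#' downstream analyses into one reproducible description of a run.
#'
#' @param simulation a [simulation_config()].
#' @param stages character subset of
#'   `c("invert_classical", "invert_sparse", "fc", "reliability", "fingerprint")`;
#'   simulation always runs (or is resumed from `outdir`).
#' @param density true off-diagonal connection density of the cohort.
#' @param priors a [prior_specification()].
#' @param sparsity a [sparsity_config()].
#' @param fc_lambda penalty for the L1 partial-correlation baseline.
#' @param top_k strongest-connection mask size for the ICC report.
#' @param n_permutations fingerprinting permutations.
#' @param outdir output directory (`NULL` = keep everything in memory).
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       stages = c("invert_classical", "fc", "reliability",
                                  "fingerprint"),
                       density = 1, priors = prior_specification(),
                       sparsity = sparsity_config(), fc_lambda = 0.1,
                       top_k = 100, n_permutations = 1000, outdir = NULL) {
  stages <- match.arg(stages, c("invert_classical", "invert_sparse", "fc",
                                "reliability", "fingerprint"),
                      several.ok = TRUE)
  structure(list(simulation = simulation, stages = stages, density = density,
                 priors = priors, sparsity = sparsity, fc_lambda = fc_lambda,
                 top_k = top_k, n_permutations = n_permutations,
                 outdir = outdir),
            class = "run_config")
}

#' Run the full synthetic reliability study
#'
#' Executes the enabled stages in dependency order: cohort simulation, model
#' inversion (classical and/or sparse rDCM) and FC baselines per
#' subject-session, parameter panels, group consistency and ICC reports, and
#' connectome fingerprinting. Fully deterministic given the configuration
#' (all randomness derives from the simulation master seed). When `outdir`
#' is set, intermediate tables and a headline metrics table are written.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: `cohort`, per-method fits, panels,
#'   `consistency`, `icc`, `fingerprint`, and a `headline` data frame of the
#'   main metrics.
#' @export
run_pipeline <- function(config) {
  cfg <- config$simulation
  out <- list(config = config)
  cohort <- generate_cohort(cfg, density = config$density)
  out$cohort <- cohort
  if (!is.null(config$outdir)) write_cohort(cohort, file.path(config$outdir, "cohort"))

  spec <- network_specification(cfg$n_regions,
                                if (cfg$mode == "task") cfg$n_inputs else 0)
  S <- cfg$n_subjects
  methods <- list()

  fit_all <- function(fit_one) {
    lapply(seq_len(S), function(s) lapply(1:2, function(j)
      fit_one(cohort$recordings[[s]][[j]])))
  }
  if ("invert_classical" %in% config$stages) {
    methods$rdcm <- fit_all(function(rec) invert_model(rec, spec, config$priors))
  }
  if ("invert_sparse" %in% config$stages) {
    methods$rdcm_sparse <- fit_all(function(rec) {
      ls <- line_search_p0(rec, spec, config$priors, config$sparsity)
      prune_result(ls$best_fit, config$sparsity)
    })
  }
  if ("fc" %in% config$stages) {
    methods$fc_pearson <- fit_all(fc_pearson)
    methods$fc_l1 <- fit_all(function(rec) fc_l1_partial(rec, config$fc_lambda))
  }
  out$fits <- methods

  headline <- list()
  if (length(methods) && "reliability" %in% config$stages) {
    out$panels <- lapply(methods, build_parameter_panel)
    out$consistency <- lapply(out$panels, group_consistency)
    out$icc <- lapply(out$panels, icc_report, top_k = config$top_k)
    for (m in names(out$panels)) {
      ct <- out$consistency[[m]]$table
      ic <- out$icc[[m]]$summaries
      headline[[length(headline) + 1L]] <- data.frame(
        method = m, metric = paste0("consistency_r_", ct$family),
        value = ct$r)
      headline[[length(headline) + 1L]] <- data.frame(
        method = m,
        metric = paste0("mean_icc_", names(ic)),
        value = vapply(ic, `[[`, 0, "mean"))
    }
  }
  if (length(methods) && "fingerprint" %in% config$stages) {
    out$fingerprint <- lapply(names(methods), function(m) {
      panel <- build_parameter_panel(methods[[m]])
      fv <- fingerprint_vectors(panel)
      idr <- identification_accuracy(similarity_matrix(fv$s1, fv$s2))
      pf <- permutation_test(fv$s1, fv$s2, "forward",
                             P = config$n_permutations,
                             seed = derive_seed(cfg$master_seed, "perm", m, 1))
      pb <- permutation_test(fv$s1, fv$s2, "backward",
                             P = config$n_permutations,
                             seed = derive_seed(cfg$master_seed, "perm", m, 2))
      list(method = m, identification = idr, p_forward = pf$p, p_backward = pb$p)
    })
    names(out$fingerprint) <- names(methods)
    for (fp in out$fingerprint) {
      headline[[length(headline) + 1L]] <- data.frame(
        method = fp$method,
        metric = c("identification_pct_forward", "identification_pct_backward",
                   "identification_p_forward", "identification_p_backward"),
        value = c(fp$identification$accuracy_forward_pct,
                  fp$identification$accuracy_backward_pct,
                  fp$p_forward, fp$p_backward))
    }
  }
  out$headline <- if (length(headline)) do.call(rbind, headline) else
    data.frame(method = character(), metric = character(), value = numeric())
  rownames(out$headline) <- NULL

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$headline,
                       file.path(config$outdir, "headline_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(out$panels)) {
      for (m in names(out$panels)) {
        utils::write.table(out$panels[[m]],
                           file.path(config$outdir, paste0("panel_", m, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  class(out) <- "run_report"
  out
}
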