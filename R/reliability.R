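#' Assemble a subject x session x parameter panel of point estimates
#'
#' Vectorises per-subject-session fits into the long-format table on which
#' all reliability metrics operate. rDCM results contribute the requested
#' parameter families (between-region couplings, self-connections, driving
#' inputs) with stable parameter ids; symmetric FC matrices contribute the
#' upper triangle only.
#'
#' @param results list of S elements, each a list of two fits (sessions 1, 2);
#'   fits are `rdcm_result` or `fc_matrix` objects.
#' @param subset for rDCM fits, character vector from
#'   `c("between", "self", "input")`.
#' @return object of class `parameter_panel`: data frame with columns
#'   subject, session, parameter_id, type, estimate, precision (posterior
#'   precision where available, NA otherwise), plus attributes `n_subjects`
#'   and `parameters` (metadata table).
#' @export
build_parameter_panel <- function(results, subset = c("between", "self", "input")) {
  subset <- match.arg(subset, several.ok = TRUE)
  S <- length(results)
  stopifnot(S >= 1)
  for (s in seq_len(S)) {
    if (length(results[[s]]) != 2) {
      stop("subject ", s, " does not have exactly two sessions")
    }
  }
  vectorise <- function(fit) {
    if (inherits(fit, "rdcm_result")) {
      R <- nrow(fit$A_mean)
      out <- list()
      if ("between" %in% subset) {
        idx <- which(row(fit$A_mean) != col(fit$A_mean))
        out$between <- data.frame(
          parameter_id = sprintf("A_%03d_%03d", row(fit$A_mean)[idx],
                                 col(fit$A_mean)[idx]),
          type = "between", estimate = fit$A_mean[idx],
          precision = ifelse(fit$A_var[idx] > 0, 1 / fit$A_var[idx], NA))
      }
      if ("self" %in% subset) {
        out$self <- data.frame(
          parameter_id = sprintf("A_%03d_%03d", 1:R, 1:R),
          type = "self", estimate = diag(fit$A_mean),
          precision = ifelse(diag(fit$A_var) > 0, 1 / diag(fit$A_var), NA))
      }
      if ("input" %in% subset && length(fit$C_mean)) {
        idx <- seq_along(fit$C_mean)
        out$input <- data.frame(
          parameter_id = sprintf("C_%03d_%03d", row(fit$C_mean)[idx],
                                 col(fit$C_mean)[idx]),
          type = "input", estimate = as.numeric(fit$C_mean),
          precision = ifelse(as.numeric(fit$C_var)[idx] > 0,
                             1 / as.numeric(fit$C_var)[idx], NA))
      }
      do.call(rbind, out)
    } else if (inherits(fit, "fc_matrix")) {
      ut <- which(upper.tri(fit$values))
      data.frame(
        parameter_id = sprintf("FC_%03d_%03d", row(fit$values)[ut],
                               col(fit$values)[ut]),
        type = "between", estimate = fit$values[ut], precision = NA_real_)
    } else {
      stop("unsupported fit class: ", paste(class(fit), collapse = "/"))
    }
  }
  rows <- list()
  ids_ref <- NULL
  for (s in seq_len(S)) {
    for (j in 1:2) {
      v <- vectorise(results[[s]][[j]])
      if (is.null(ids_ref)) ids_ref <- v$parameter_id
      if (!identical(v$parameter_id, ids_ref)) {
        stop("subject ", s, " session ", j,
             " yields a different parameter set than the first fit")
      }
      v$subject <- s; v$session <- j
      rows[[length(rows) + 1L]] <- v
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel <- panel[, c("subject", "session", "parameter_id", "type",
                     "estimate", "precision")]
  meta <- unique(panel[panel$subject == 1 & panel$session == 1,
                       c("parameter_id", "type")])
  structure(panel, class = c("parameter_panel", "data.frame"),
            n_subjects = S, parameters = meta)
}

# S x 2 matrix of estimates for one parameter id
panel_matrix <- function(panel, id) {
  sub <- panel[panel$parameter_id == id, ]
  S <- attr(panel, "n_subjects")
  m <- matrix(NA_real_, S, 2)
  m[cbind(sub$subject, sub$session)] <- sub$estimate
  m
}

# estimates reshaped to subject x parameter per session (fast path)
panel_array <- function(panel) {
  ids <- attr(panel, "parameters")$parameter_id
  S <- attr(panel, "n_subjects")
  out <- lapply(1:2, function(j) {
    sub <- panel[panel$session == j, ]
    m <- matrix(NA_real_, S, length(ids),
                dimnames = list(NULL, ids))
    m[cbind(sub$subject, match(sub$parameter_id, ids))] <- sub$estimate
    m
  })
  names(out) <- c("s1", "s2")
  out
}

#' Group-level across-session consistency
#'
#' Averages each parameter across subjects within session and correlates the
#' session-1 with the session-2 group-mean vector, separately for the
#' connectivity family (between-region plus self-connections) and the
#' driving-input family. Significance is Bonferroni-corrected for the number
#' of paradigms analysed in the study (8 by default, giving the 0.00625
#' per-comparison threshold at family-wise alpha 0.05).
#'
#' @param panel a [build_parameter_panel()] result.
#' @param alpha family-wise significance level.
#' @param n_paradigms Bonferroni divisor.
#' @return object of class `consistency_report`: per-family r, p, Bonferroni
#'   threshold and flag, and the per-parameter session means.
#' @export
group_consistency <- function(panel, alpha = 0.05, n_paradigms = 8) {
  arr <- panel_array(panel)
  meta <- attr(panel, "parameters")
  m1 <- colMeans(arr$s1); m2 <- colMeans(arr$s2)
  fam <- ifelse(meta$type == "input", "input", "connectivity")
  threshold <- alpha / n_paradigms
  res <- lapply(unique(fam), function(f) {
    i <- which(fam == f)
    if (length(i) < 3) stop("need at least 3 parameters in family ", f)
    if (stats::sd(m1[i]) == 0 || stats::sd(m2[i]) == 0) {
      stop("zero-variance group-mean vector in family ", f)
    }
    ct <- stats::cor.test(m1[i], m2[i])
    data.frame(family = f, n = length(i), r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < threshold)
  })
  structure(list(table = do.call(rbind, res),
                 threshold = threshold,
                 session_means = data.frame(parameter_id = meta$parameter_id,
                                            family = fam, mean_s1 = m1,
                                            mean_s2 = m2)),
            class = "consistency_report")
}

#' Intraclass correlation ICC(3,1) for a two-session design
#'
#' Two-way mixed-effects, single-measurement, consistency-type ICC computed
#' from the ANOVA mean squares: with k = 2 sessions,
#' \deqn{ICC = (BMS - EMS) / (BMS + EMS)}
#' where BMS is the between-subject mean square and EMS the residual mean
#' square after removing subject and session effects. Equivalently the ratio
#' of (between - within) to (between + within) subject variability.
#' Consistency ICC is invariant to additive session effects. A degenerate
#' zero denominator returns NA.
#'
#' @param values numeric S x 2 matrix (subjects by sessions).
#' @return scalar ICC in [-1, 1], or NA when undefined.
#' @export
icc_3_1 <- function(values) {
  values <- as.matrix(values)
  S <- nrow(values)
  if (S < 3) stop("ICC(3,1) requires at least 3 subjects")
  if (ncol(values) != 2) stop("expected exactly 2 sessions")
  if (any(!is.finite(values))) stop("non-finite values in ICC input")
  grand <- mean(values)
  rm_ <- rowMeans(values); cm <- colMeans(values)
  k <- 2
  bms <- k * sum((rm_ - grand)^2) / (S - 1)
  resid <- values - outer(rm_, rep(1, k)) - outer(rep(1, S), cm) + grand
  ems <- sum(resid^2) / ((S - 1) * (k - 1))
  den <- bms + (k - 1) * ems
  if (den == 0) return(NA_real_)
  (bms - ems) / den
}

#' Classify an ICC value by the conventional reliability bands
#'
#' poor < 0.4, fair [0.4, 0.6), good [0.6, 0.75), excellent >= 0.75.
#'
#' @param icc numeric vector of ICC values in [-1, 1].
#' @return character vector of labels.
#' @export
classify_icc <- function(icc) {
  if (any(!is.na(icc) & (icc < -1 | icc > 1))) {
    stop("ICC values must lie in [-1, 1]")
  }
  cut(icc, breaks = c(-1, 0.4, 0.6, 0.75, 1),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

#' Fisher-z summary of a set of ICC (or correlation) values
#'
#' Transforms to z-space with atanh, computes the mean and a 95% interval as
#' mean plus/minus 1.96 times the z-space standard deviation of the values
#' (an interval describing the spread of the distribution of connection-wise
#' ICCs, not the standard error of the mean), and maps back with tanh.
#' Values at exactly +/-1 are clipped to 1 - 1e-7 in magnitude.
#'
#' @param values numeric vector of ICC values; NAs are dropped (count
#'   reported).
#' @return list: `mean`, `ci` (length 2), `n`, `n_dropped`.
#' @export
fisher_z_summary <- function(values) {
  n_na <- sum(is.na(values))
  values <- values[!is.na(values)]
  if (!length(values)) stop("no usable values under this mask")
  clipped <- pmin(pmax(values, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(clipped)
  mz <- mean(z)
  sz <- if (length(z) > 1) stats::sd(z) else 0
  list(mean = tanh(mz), ci = tanh(mz + c(-1.96, 1.96) * sz),
       n = length(z), n_dropped = n_na)
}

#' Mask of parameters significantly different from zero
#'
#' For each parameter, a two-sided one-sample t-test of the subject-wise
#' across-session means against zero; parameters pass when
#' p < alpha / (number of parameters tested) (Bonferroni).
#'
#' @param panel a [build_parameter_panel()] result.
#' @param alpha family-wise alpha.
#' @return logical vector, one entry per parameter (panel order).
#' @export
filter_significant <- function(panel, alpha = 0.05) {
  arr <- panel_array(panel)
  S <- nrow(arr$s1)
  if (S < 3) stop("need at least 3 subjects")
  m <- (arr$s1 + arr$s2) / 2
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  tstat <- ifelse(sdv > 0, mu / (sdv / sqrt(S)), NA)
  p <- 2 * stats::pt(-abs(tstat), df = S - 1)
  keep <- !is.na(p) & p < alpha / length(p)
  if (any(is.na(p))) keep[is.na(p)] <- FALSE
  stats::setNames(keep, colnames(m))
}

#' Mask of the k strongest between-region parameters
#'
#' Ranks between-region parameters by the absolute group mean (across all
#' subjects and both sessions) and keeps the top k; ties are broken by the
#' stable parameter-id order. Non-between parameters are never selected.
#'
#' @param panel a [build_parameter_panel()] result.
#' @param k number of parameters to keep.
#' @return logical vector, one entry per parameter (panel order).
#' @export
filter_top_k <- function(panel, k = 1000) {
  arr <- panel_array(panel)
  meta <- attr(panel, "parameters")
  eligible <- which(meta$type == "between")
  if (k > length(eligible)) stop("k exceeds the number of between-region parameters")
  score <- abs(colMeans(arr$s1) + colMeans(arr$s2)) / 2
  ord <- eligible[order(-score[eligible], eligible)]
  keep <- logical(nrow(meta))
  keep[ord[seq_len(k)]] <- TRUE
  stats::setNames(keep, meta$parameter_id)
}

#' Connection-wise ICC report with filters and summaries
#'
#' Computes ICC(3,1) per parameter, classifies each value, and summarises
#' the distribution (Fisher-z mean and 95% interval) under the three masks:
#' all parameters, significantly nonzero parameters, and the top-k strongest
#' between-region parameters.
#'
#' @param panel a [build_parameter_panel()] result.
#' @param top_k size of the strongest-connection mask (clamped to the number
#'   of between-region parameters).
#' @param alpha alpha for the significance filter.
#' @return object of class `icc_report`: per-parameter table (icc, class),
#'   `masks`, `summaries` (per mask), `n_undefined`.
#' @export
icc_report <- function(panel, top_k = 1000, alpha = 0.05) {
  arr <- panel_array(panel)
  ids <- colnames(arr$s1)
  icc <- vapply(seq_along(ids), function(i) {
    m <- cbind(arr$s1[, i], arr$s2[, i])
    icc_3_1(m)
  }, 0)
  meta <- attr(panel, "parameters")
  tab <- data.frame(parameter_id = ids, type = meta$type, icc = icc,
                    class = ifelse(is.na(icc), NA, classify_icc(icc)))
  n_between <- sum(meta$type == "between")
  masks <- list(
    all = stats::setNames(rep(TRUE, length(ids)), ids),
    significant = filter_significant(panel, alpha),
    top_k = filter_top_k(panel, min(top_k, n_between))
  )
  summaries <- lapply(masks, function(m) {
    if (!any(m & !is.na(icc))) {
      return(list(mean = NA_real_, ci = c(NA_real_, NA_real_), n = 0L,
                  n_dropped = sum(m)))
    }
    fisher_z_summary(icc[m])
  })
  structure(list(table = tab, masks = masks, summaries = summaries,
                 n_undefined = sum(is.na(icc))),
            class = "icc_report")
}

#' Correlate connection-wise ICC with a moderator
#'
#' Pearson correlation (with two-sided p) between ICC values and a moderator
#' such as the absolute group-mean parameter strength or the group-mean
#' posterior precision.
#'
#' @param icc numeric vector of ICC values.
#' @param moderator numeric vector, same length.
#' @return list with `r` and `p`.
#' @export
correlate_icc_with_moderator <- function(icc, moderator) {
  ok <- is.finite(icc) & is.finite(moderator)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(icc[ok]) == 0 || stats::sd(moderator[ok]) == 0) {
    stop("zero variance in ICC or moderator")
  }
  ct <- stats::cor.test(icc[ok], moderator[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}
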