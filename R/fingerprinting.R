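#' Extract per-subject fingerprint vectors from a parameter panel
#'
#' The default fingerprint is the vector of all between-region coupling
#' estimates (self-connections and driving inputs excluded).
#'
#' @param panel a [build_parameter_panel()] result.
#' @param types parameter families to include.
#' @return list with `s1`, `s2`: S x P matrices of estimates.
#' @export
fingerprint_vectors <- function(panel, types = "between") {
  arr <- panel_array(panel)
  meta <- attr(panel, "parameters")
  keep <- meta$type %in% types
  if (!any(keep)) stop("no parameters of the requested type(s)")
  list(s1 = arr$s1[, keep, drop = FALSE], s2 = arr$s2[, keep, drop = FALSE])
}

#' Cross-session similarity matrix
#'
#' Entry (i, j) is the Pearson correlation between subject i's session-1
#' connectivity vector and subject j's session-2 vector.
#'
#' @param vectors_s1,vectors_s2 S x P matrices (subjects by parameters).
#' @return S x S numeric matrix.
#' @export
similarity_matrix <- function(vectors_s1, vectors_s2) {
  stopifnot(ncol(vectors_s1) == ncol(vectors_s2),
            nrow(vectors_s1) == nrow(vectors_s2), nrow(vectors_s1) >= 2)
  bad1 <- which(apply(vectors_s1, 1, stats::sd) == 0)
  bad2 <- which(apply(vectors_s2, 1, stats::sd) == 0)
  if (length(c(bad1, bad2))) {
    stop("zero-variance fingerprint vector for subject(s) ",
         paste(unique(c(bad1, bad2)), collapse = ", "))
  }
  stats::cor(t(vectors_s1), t(vectors_s2))
}

#' Identification accuracies from a similarity matrix
#'
#' Forward: each session-1 subject (row) is predicted as the session-2
#' subject (column) with the highest similarity; backward swaps the roles.
#' Ties at the argmax are broken toward the lowest index with a warning.
#'
#' @param similarity square S x S matrix from [similarity_matrix()].
#' @return object of class `identification_result`: accuracies (fraction and
#'   percent) in both directions, confusion matrices, argmax vectors, chance
#'   level 1/S.
#' @export
identification_accuracy <- function(similarity) {
  stopifnot(nrow(similarity) == ncol(similarity))
  S <- nrow(similarity)
  amax <- function(x) {
    w <- which(x == max(x))
    if (length(w) > 1) warning("similarity tie; keeping the lowest index")
    w[1]
  }
  pred_fwd <- apply(similarity, 1, amax)
  pred_bwd <- apply(similarity, 2, amax)
  conf_fwd <- table(factor(seq_len(S), levels = seq_len(S)),
                    factor(pred_fwd, levels = seq_len(S)))
  conf_bwd <- table(factor(seq_len(S), levels = seq_len(S)),
                    factor(pred_bwd, levels = seq_len(S)))
  acc_fwd <- mean(pred_fwd == seq_len(S))
  acc_bwd <- mean(pred_bwd == seq_len(S))
  structure(list(similarity = similarity,
                 accuracy_forward = acc_fwd, accuracy_backward = acc_bwd,
                 accuracy_forward_pct = 100 * acc_fwd,
                 accuracy_backward_pct = 100 * acc_bwd,
                 predictions_forward = pred_fwd,
                 predictions_backward = pred_bwd,
                 confusion_forward = conf_fwd, confusion_backward = conf_bwd,
                 chance = 1 / S, n_subjects = S),
            class = "identification_result")
}

#' Permutation test for identification accuracy
#'
#' Builds the empirical null by permuting the participant labels of the
#' session to be predicted and recomputing the identification accuracy for
#' each permutation. The p value is the fraction of permuted accuracies at
#' least as large as the observed one, floored at 1/P (the observed
#' arrangement counts as achievable by permutation).
#'
#' @param vectors_s1,vectors_s2 S x P fingerprint matrices.
#' @param direction `"forward"` (predict session 2 from session 1) or
#'   `"backward"`.
#' @param P number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return list: `p`, `observed` (accuracy), `null` (vector of P permuted
#'   accuracies), `P`, `direction`, `seed`.
#' @export
permutation_test <- function(vectors_s1, vectors_s2,
                             direction = c("forward", "backward"),
                             P = 1000, seed = 1) {
  direction <- match.arg(direction)
  stopifnot(P >= 100)
  sim <- similarity_matrix(vectors_s1, vectors_s2)
  S <- nrow(sim)
  pred <- if (direction == "forward") {
    apply(sim, 1, which.max)
  } else {
    apply(sim, 2, which.max)
  }
  observed <- mean(pred == seq_len(S))
  set.seed(as.integer(seed))
  null <- vapply(seq_len(P), function(i) {
    perm <- sample.int(S)
    # relabelling the predicted session: subject i's true match becomes perm[i]
    mean(pred == perm)
  }, 0)
  p <- max(sum(null >= observed), 1) / P
  list(p = p, observed = observed, null = null, P = P,
       direction = direction, seed = seed)
}
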