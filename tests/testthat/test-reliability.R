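# quick panel built from plain matrices wrapped as rdcm results
fake_result <- function(A, C = NULL) {
  R <- nrow(A)
  K <- if (is.null(C)) 0 else ncol(C)
  structure(list(A_mean = A, A_var = matrix(1, R, R),
                 C_mean = if (K) C else matrix(0, R, 0),
                 C_var = if (K) matrix(1, R, K) else matrix(0, R, 0)),
            class = "rdcm_result")
}

panel_from_values <- function(values) {
  # values: S x 2 for a single synthetic "parameter"; embed into 2x2 A mats
  S <- nrow(values)
  res <- lapply(seq_len(S), function(s) lapply(1:2, function(j) {
    A <- matrix(c(-0.5, 0, values[s, j], -0.5), 2, 2)
    fake_result(A)
  }))
  build_parameter_panel(res, subset = "between")
}

test_that("panels have the expected size, ids and determinism", {
  set.seed(1)
  res <- lapply(1:10, function(s) lapply(1:2, function(j)
    fake_result(matrix(rnorm(400), 20, 20))))
  p <- build_parameter_panel(res, subset = c("between", "self"))
  expect_identical(nrow(p), 10L * 2L * 400L)
  expect_identical(nrow(attr(p, "parameters")), 400L)
  p2 <- build_parameter_panel(res, subset = c("between", "self"))
  expect_identical(p, p2)
  # FC input: upper triangle only
  resfc <- lapply(1:4, function(s) lapply(1:2, function(j) {
    v <- stats::cov2cor(crossprod(matrix(rnorm(30 * 20), 30, 20)))
    structure(list(values = v, kind = "pearson"), class = "fc_matrix")
  }))
  pfc <- build_parameter_panel(resfc)
  expect_identical(nrow(attr(pfc, "parameters")), 190L)
})

test_that("missing sessions are rejected with the subject named", {
  res <- list(list(fake_result(diag(-0.5, 2))))
  expect_error(build_parameter_panel(res), "subject 1")
})

test_that("group consistency behaves as a correlation of session means", {
  set.seed(2)
  S <- 6; P <- 6
  base <- rnorm(P, sd = 0.4)
  vals <- matrix(base, S, P, byrow = TRUE) + matrix(rnorm(S * P, 0, 0.1), S, P)
  mk <- function(v, flip = 1) {
    A <- matrix(0, 3, 3); A[row(A) != col(A)] <- flip * v; diag(A) <- -0.5
    fake_result(A)
  }
  res <- lapply(1:S, function(s) list(mk(vals[s, ]), mk(vals[s, ])))
  p <- build_parameter_panel(res, subset = "between")
  gc <- group_consistency(p)
  expect_identical(gc$threshold, 0.05 / 8)
  expect_equal(gc$table$r[gc$table$family == "connectivity"], 1,
               tolerance = 1e-9)                       # identical sessions
  # sign flip in session 2 gives r = -1
  resf <- lapply(1:S, function(s) list(mk(vals[s, ]), mk(vals[s, ], -1)))
  gcf <- group_consistency(build_parameter_panel(resf, subset = "between"))
  expect_equal(gcf$table$r[1], -1, tolerance = 1e-9)
  # brute-force formula oracle against the reported r on noisy sessions
  resn <- lapply(1:S, function(s) list(mk(vals[s, ]),
                                       mk(vals[s, ] + rnorm(P, 0, 0.05))))
  pn <- build_parameter_panel(resn, subset = "between")
  gcn <- group_consistency(pn)
  arr <- rdcmrel:::panel_array(pn)
  m1 <- colMeans(arr$s1); m2 <- colMeans(arr$s2)
  brute <- sum((m1 - mean(m1)) * (m2 - mean(m2))) /
    sqrt(sum((m1 - mean(m1))^2) * sum((m2 - mean(m2))^2))
  expect_equal(gcn$table$r[1], brute, tolerance = 1e-12)
})

test_that("ICC(3,1) matches the two-way ANOVA oracle to 1e-10", {
  set.seed(3)
  for (i in 1:12) {
    v <- matrix(rnorm(12), 6, 2)
    d <- data.frame(y = as.numeric(v),
                    subj = factor(rep(1:6, 2)),
                    sess = factor(rep(1:2, each = 6)))
    ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]$`Mean Sq`
    bms <- ms[1]; ems <- ms[3]
    expect_equal(icc_3_1(v), (bms - ems) / (bms + ems), tolerance = 1e-10)
  }
})

test_that("ICC(3,1) edge cases behave as a consistency coefficient", {
  v <- cbind(c(1, 3, 5), c(1, 3, 5))
  expect_equal(icc_3_1(v), 1)
  expect_equal(icc_3_1(matrix(c(1, 3, 5, 2, 4, 6), 3, 2)), 1)  # +1 shift
  v2 <- matrix(rnorm(14), 7, 2)
  expect_equal(icc_3_1(v2), icc_3_1(v2 + cbind(0, rep(5, 7))),
               tolerance = 1e-12)
  expect_error(icc_3_1(matrix(1:4, 2, 2)), "at least 3")
  expect_true(is.na(icc_3_1(matrix(1, 5, 2))))
})

test_that("ICC classification uses the conventional half-open bands", {
  expect_identical(classify_icc(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75, -0.2)),
                   c("poor", "fair", "fair", "good", "good", "excellent",
                     "poor"))
  expect_error(classify_icc(1.2), "-1, 1")
})

test_that("Fisher-z summaries average in z-space", {
  s <- fisher_z_summary(rep(0.5, 10))
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci, c(0.5, 0.5))
  s2 <- fisher_z_summary(c(0.2, 0.8))
  expect_equal(s2$mean, tanh(mean(atanh(c(0.2, 0.8)))), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s2$mean, 0.5)))
  # symmetric in z, asymmetric in r for nonzero mean
  z <- atanh(s2$mean)
  expect_equal(atanh(s2$ci[2]) - z, z - atanh(s2$ci[1]), tolerance = 1e-9)
  expect_gt((s2$mean - s2$ci[1]) - (s2$ci[2] - s2$mean), 0)
  expect_error(fisher_z_summary(c(NA_real_)), "no usable")
  expect_identical(fisher_z_summary(c(0.3, NA, 0.4))$n_dropped, 1L)
})

test_that("the significance filter applies a Bonferroni-corrected t-test", {
  set.seed(4)
  S <- 20
  strong <- matrix(0.5 + rnorm(S * 2, 0, 0.01), S, 2)
  null <- matrix(0, S, 2)
  weak <- matrix(rnorm(S * 2, 0, 1), S, 2)
  res <- lapply(1:S, function(s) lapply(1:2, function(j) {
    A <- diag(c(-0.5, -0.3, -0.4))
    A[2, 1] <- strong[s, j]                 # clearly nonzero
    A[3, 1] <- weak[s, j]                   # zero-mean noise
    A[1, 2] <- null[s, j]                   # identically zero
    A[3, 2] <- 0.1; A[1, 3] <- 0.2; A[2, 3] <- -0.1
    fake_result(A)
  }))
  p <- build_parameter_panel(res, subset = "between")
  keep <- filter_significant(p)
  ids <- names(keep)
  expect_true(keep[ids == "A_002_001"])     # the strong parameter
  expect_false(keep[ids == "A_001_002"])    # identically zero
  # t statistic matches the hand formula for the strong parameter
  m <- rowMeans(strong)
  tref <- mean(m) / (stats::sd(m) / sqrt(S))
  pref <- 2 * stats::pt(-abs(tref), S - 1)
  expect_lt(pref, 0.05 / 6)
})

test_that("the top-k filter ranks by absolute mean and ignores sign", {
  means <- c(0.9, -0.8, 0.1, 0, 0.05, 0.3)
  res <- lapply(1:4, function(s) lapply(1:2, function(j) {
    A <- matrix(0, 3, 3); A[row(A) != col(A)] <- means; diag(A) <- -0.5
    fake_result(A)
  }))
  p <- build_parameter_panel(res, subset = "between")
  keep2 <- filter_top_k(p, 2)
  ord <- order(-abs(means))
  expect_identical(unname(which(keep2)), sort(ord[1:2]))
  expect_identical(unname(which(filter_top_k(p, 6))), 1:6)
  # global sign flip leaves the mask unchanged
  resf <- lapply(res, function(ss) lapply(ss, function(f) {
    f$A_mean <- -f$A_mean; f
  }))
  pf <- build_parameter_panel(resf, subset = "between")
  expect_identical(filter_top_k(pf, 2), keep2)
  expect_error(filter_top_k(p, 7), "exceeds")
})

test_that("moderator correlations reduce to Pearson r", {
  set.seed(5)
  icc <- runif(10, -0.2, 0.9)
  expect_equal(correlate_icc_with_moderator(icc, icc)$r, 1, tolerance = 1e-12)
  mod <- rnorm(10)
  out <- correlate_icc_with_moderator(icc, mod)
  brute <- sum((icc - mean(icc)) * (mod - mean(mod))) /
    sqrt(sum((icc - mean(icc))^2) * sum((mod - mean(mod))^2))
  expect_equal(out$r, brute, tolerance = 1e-12)
  expect_error(correlate_icc_with_moderator(icc, rep(1, 10)), "zero variance")
})

test_that("group consistency r is invariant to a common id permutation", {
  set.seed(6)
  res <- lapply(1:5, function(s) lapply(1:2, function(j)
    fake_result(matrix(rnorm(16, sd = 0.3) - diag(0.5, 4), 4, 4))))
  p <- build_parameter_panel(res, subset = "between")
  r0 <- group_consistency(p)$table$r
  perm <- sample(12)
  arr <- rdcmrel:::panel_array(p)
  m1 <- colMeans(arr$s1)[perm]; m2 <- colMeans(arr$s2)[perm]
  expect_equal(unname(stats::cor(m1, m2)), r0, tolerance = 1e-12)
})
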