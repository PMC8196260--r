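# PLS engine: decomposition oracles, invariants, permutation and bootstrap
# behavior, and bootstrap-ratio cluster extraction.

test_that("a one-direction condition difference yields a single LV carrying
           all variance", {
  mu1 <- c(0, 0, 0, 0)
  mu2 <- c(3, 0, 0, 0)   # means differ along voxel 1 only
  X <- rbind(matrix(mu1, 3, 4, byrow = TRUE), matrix(mu2, 3, 4, byrow = TRUE))
  cond <- factor(rep(c("A", "B"), each = 3))
  fit <- mean_centered_pls(X, cond, subject = rep(1:3, 2))
  expect_length(fit$d, 1L)
  expect_equal(fit$pct_var, 100, tolerance = 1e-6)
  expect_equal(abs(fit$saliences[, 1]), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("mean-centered decomposition matches an eigen-based oracle", {
  set.seed(71)
  n <- 4; V <- 5
  X <- matrix(rnorm(3 * n * V), 3 * n, V)
  cond <- factor(rep(c("aHC", "mHC", "pHC"), each = n))
  fit <- mean_centered_pls(X, cond, subject = rep(1:n, 3))
  # independent oracle: explicit loops + eigendecomposition
  M <- t(sapply(levels(cond), function(cc) colMeans(X[cond == cc, ])))
  Mc <- sweep(M, 2, colMeans(M))
  ev <- eigen(crossprod(Mc), symmetric = TRUE)
  d_oracle <- sqrt(pmax(ev$values, 0))[1:2]
  expect_equal(fit$d, d_oracle, tolerance = 1e-10)
  for (l in 1:2) {
    v_o <- ev$vectors[, l]
    expect_equal(abs(sum(fit$saliences[, l] * v_o)), 1, tolerance = 1e-10)
  }
  # brain-score identity against the voxel-by-salience summation oracle
  scores_oracle <- matrix(0, nrow(X), length(fit$d))
  for (r in seq_len(nrow(X)))
    for (l in seq_along(fit$d))
      scores_oracle[r, l] <- sum(X[r, ] * fit$saliences[, l])
  expect_equal(fit$brain_scores, scores_oracle, tolerance = 1e-10)
})

test_that("salience orthogonality, variance accounting and scale
           equivariance hold", {
  set.seed(72)
  X <- matrix(rnorm(30 * 12), 30, 12)
  cond <- factor(rep(c("a", "b", "c"), each = 10))
  subj <- rep(1:10, 3)
  fit <- mean_centered_pls(X, cond, subj)
  expect_equal(crossprod(fit$saliences), diag(length(fit$d)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(fit$pct_var), 100, tolerance = 1e-6)
  expect_true(all(diff(fit$d) <= 1e-12))
  fit2 <- mean_centered_pls(2.5 * X, cond, subj)
  expect_equal(fit2$d, 2.5 * fit$d, tolerance = 1e-10)
  # behavioral variant is invariant to scaling (blocks are z-scored)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  b1 <- behavioral_pls(X, Y, cond, subj)
  b2 <- behavioral_pls(2.5 * X, 10 * Y + 3, cond, subj)
  expect_equal(b1$d, b2$d, tolerance = 1e-10)
  expect_equal(abs(b1$saliences), abs(b2$saliences), tolerance = 1e-10)
})

# Printed 6-subject, 2-condition, 2-voxel, 1-behavior fixture.
pls_fixture <- list(
  x1 = matrix(c(1.2, -0.4, 0.7, 2.1, -1.0, 0.3,
                0.5, 1.8, -0.2, 0.9, 1.1, -0.7), ncol = 2),
  x2 = matrix(c(0.4, 1.5, -0.8, 0.2, 1.9, -0.3,
                -1.1, 0.6, 1.4, 0.8, -0.5, 1.0), ncol = 2),
  y = c(3.2, 4.8, 2.9, 5.5, 3.8, 2.4))

test_that("behavioral cross-block matrix and SVD match a hand-computed
           oracle on the printed fixture", {
  fx <- pls_fixture
  X <- rbind(fx$x1, fx$x2)
  Y <- matrix(rep(fx$y, 2), ncol = 1)
  cond <- factor(rep(c("c1", "c2"), each = 6))
  expect_warning(fit <- behavioral_pls(X, Y, cond, subject = rep(1:6, 2)),
                 "single behavior")
  # hand-computed oracle: explicit z-scores and sums
  zs <- function(v) (v - mean(v)) / sd(v)
  R_oracle <- matrix(NA_real_, 2, 2)
  for (ci in 1:2) {
    xb <- if (ci == 1) fx$x1 else fx$x2
    for (v in 1:2)
      R_oracle[ci, v] <- sum(zs(fx$y) * zs(xb[, v])) / 5
  }
  ev <- eigen(crossprod(R_oracle), symmetric = TRUE)
  d_oracle <- sqrt(pmax(ev$values, 0))
  expect_equal(fit$d, d_oracle, tolerance = 1e-10)
  for (l in 1:2)
    expect_equal(abs(sum(fit$saliences[, l] * ev$vectors[, l])), 1,
                 tolerance = 1e-10)
  # R entries are plain Pearson correlations
  expect_equal(R_oracle[1, 1], cor(fx$y, fx$x1[, 1]), tolerance = 1e-12)
})

test_that("a behavior equal to one voxel's values dominates the salience
           pattern and its reliability", {
  set.seed(74)
  n <- 50; V <- 6
  X <- do.call(rbind, lapply(1:3, function(i) matrix(rnorm(n * V), n, V)))
  cond <- factor(rep(c("a", "b", "c"), each = n))
  Y <- matrix(X[, 3], ncol = 1)   # behavior = voxel 3 in every condition
  suppressWarnings(fit <- behavioral_pls(X, Y, cond, rep(1:n, 3)))
  expect_equal(which.max(abs(fit$saliences[, 1])), 3L)
  bt <- pls_bootstrap(fit, X, Y, n_boot = 200, seed = 75)
  expect_gt(abs(bt$bsr[3, 1]), 3.3)
})

test_that("constant behavior within a condition is rejected by name", {
  X <- matrix(rnorm(24), 12, 2)
  Y <- cbind(mem = c(rep(1, 6), rnorm(6)))
  cond <- factor(rep(c("c1", "c2"), each = 6))
  expect_error(suppressWarnings(behavioral_pls(X, Y, cond, rep(1:6, 2))),
               "mem.*c1")
})

test_that("permutation p-values behave at their logical extremes", {
  set.seed(76)
  n <- 8
  X <- matrix(rnorm(3 * n * 10), 3 * n, 10)
  cond <- factor(rep(c("a", "b", "c"), each = n))
  fit <- mean_centered_pls(X, cond, rep(1:n, 3))
  expect_error(permutation_test(fit, X, n_perm = 50), "n_perm")
  # identity permutation only: p = 1 on every LV
  p_id <- permutation_test(fit, X, n_perm = 100, seed = 1,
                           perm_fun = function(i) seq_len(3 * n))
  expect_true(all(p_id == 1))
  # saturated planted effect: p at the attainable minimum 1/(1 + n_perm)
  Xs <- X
  Xs[cond == "a", 1] <- Xs[cond == "a", 1] + 50
  Xs[cond == "c", 2] <- Xs[cond == "c", 2] + 50
  fs <- mean_centered_pls(Xs, cond, rep(1:n, 3))
  ps <- permutation_test(fs, Xs, n_perm = 100, seed = 2)
  expect_equal(ps[1], 1 / 101)
})

test_that("bootstrap collapses to zero error in the noiseless limit and is
           sign-invariant", {
  # distinct singular values: exact ties would let resampling-order noise
  # at the ulp level rotate the tied subspace
  mu <- rbind(c(3, 0, 0, 0, 0), c(0, 2, 0, 0, 0), c(0, 0, 1, 0, 0))
  X <- mu[rep(1:3, each = 4), ]   # zero within-condition noise
  cond <- factor(rep(c("a", "b", "c"), each = 4))
  fit <- mean_centered_pls(X, cond, rep(1:4, 3))
  bt <- pls_bootstrap(fit, X, n_boot = 100, seed = 3)
  planted <- 1:3
  expect_true(all(bt$se[planted, 1] < 1e-6))
  expect_true(all(abs(bt$bsr[planted, 1]) > 3.3))
  # negating the solution leaves the BSR magnitudes identical
  fit2 <- fit
  fit2$saliences <- -fit2$saliences
  fit2$cond_saliences <- -fit2$cond_saliences
  bt2 <- pls_bootstrap(fit2, X, n_boot = 100, seed = 3)
  expect_equal(abs(bt2$bsr), abs(bt$bsr))
})

test_that("degenerate resamples are redrawn and the redraw is logged", {
  set.seed(77)
  n <- 4  # tiny cohort: draws with < 3 distinct subjects are common
  X <- matrix(rnorm(3 * n * 5), 3 * n, 5)
  cond <- factor(rep(c("a", "b", "c"), each = n))
  fit <- mean_centered_pls(X, cond, rep(1:n, 3))
  bt <- pls_bootstrap(fit, X, n_boot = 200, seed = 4)
  expect_gt(bt$n_redrawn, 0L)
})

test_that("cluster extraction enforces minimum size, merges nearby peaks
           and handles empty maps", {
  g <- c(12L, 12L, 8L)
  # blob of 12 and blob of 9 far apart: only the 12-voxel cluster survives
  m <- array(0, g)
  m[1:3, 1:2, 1:2] <- 4          # 12 voxels
  m[9:11, 9:11, 7] <- 4          # 9 voxels
  ct <- extract_clusters(m, threshold = 3.3, min_size = 10,
                         min_peak_sep = 3, vox_mm = c(1, 1, 1))
  expect_equal(nrow(ct$clusters), 1L)
  expect_equal(ct$clusters$size, 12L)
  # two disconnected blobs with peaks 6 mm apart: merged into one row with
  # one sub-peak
  m2 <- array(0, g)
  m2[1:2, 1:3, 1:3] <- 4; m2[2, 2, 2] <- 6
  m2[4:5, 1:3, 1:3] <- 4; m2[4, 2, 2] <- 5
  ct2 <- extract_clusters(m2, threshold = 3.3, min_size = 10,
                          min_peak_sep = 10, vox_mm = c(3, 3, 3))
  expect_equal(nrow(ct2$clusters), 1L)
  expect_equal(ct2$clusters$size, 36L)
  expect_equal(ct2$clusters[, c("x", "y", "z")],
               data.frame(x = 2L, y = 2L, z = 2L), ignore_attr = TRUE)
  expect_true(any(ct2$subpeaks$x == 4 & ct2$subpeaks$y == 2 &
                    ct2$subpeaks$z == 2))
  # negative-salience clusters keep their sign
  ct3 <- extract_clusters(-m, threshold = 3.3, min_size = 10,
                          min_peak_sep = 3)
  expect_equal(ct3$clusters$sign, -1)
  expect_equal(ct3$clusters$bsr, -4)
  # all-zero map: empty table, no error
  ct4 <- extract_clusters(array(0, g))
  expect_equal(nrow(ct4$clusters), 0L)
  expect_error(extract_clusters(array(NA_real_, g)), "finite")
})
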