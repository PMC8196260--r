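# Cohort-level scoring and inference.

test_that("mean imputation replaces missing trials with observed means and
           logs fractions", {
  tr <- data.frame(word_t1 = c(10, 12, 14, NA), word_t2 = c(8, 9, 10, 11))
  out <- impute_missing(tr)
  expect_equal(out$trials$word_t1[4], 12)
  expect_equal(out$log$n_missing, c(1L, 0L))
  expect_equal(out$log$fraction, c(0.25, 0))
  # no missing values: identity transform
  clean <- data.frame(a = 1:5, b = 6:10)
  expect_identical(impute_missing(clean)$trials, clean)
  expect_error(impute_missing(data.frame(a = c(NA, NA))), "entirely missing")
  # generated missingness is fully repaired and the log matches the truth
  gm <- gen_memory_trials(memory_config(170, missing_rate = 0.01), seed = 3)
  rep <- impute_missing(gm$scores)
  expect_false(anyNA(rep$trials))
  expect_equal(sum(rep$log$n_missing), length(gm$truth$missing_cells))
})

test_that("memory composite is a T score and matches a hand-computed
           oracle", {
  tr <- gen_memory_trials(memory_config(60, ability = rnorm(60)), seed = 4)
  cm <- composite_memory(tr$scores)
  expect_equal(mean(cm), 50, tolerance = 1e-9)
  expect_equal(stats::sd(cm), 10, tolerance = 1e-9)
  # subject at the sample mean of every task sum scores exactly 50
  sums <- attr(cm, "task_sums")
  toy <- data.frame(word_t1 = c(10, 14, 12), word_t2 = c(12, 16, 14),
                    numword_t1 = c(4, 8, 6), numword_t2 = c(5, 7, 6),
                    objloc_t1 = c(6, 10, 8), objloc_t2 = c(7, 11, 9))
  cm_toy <- composite_memory(toy)
  expect_equal(cm_toy[3], 50)  # the middle subject is at every task mean
  # 5-subject hand-computed spreadsheet oracle
  toy5 <- data.frame(word_t1 = c(9, 11, 13, 7, 15),
                     word_t2 = c(10, 12, 14, 8, 16),
                     numword_t1 = c(3, 5, 7, 2, 8),
                     numword_t2 = c(4, 6, 8, 3, 7),
                     objloc_t1 = c(5, 7, 9, 4, 11),
                     objloc_t2 = c(6, 8, 10, 5, 12))
  sums5 <- cbind(word = toy5$word_t1 + toy5$word_t2,
                 numword = toy5$numword_t1 + toy5$numword_t2,
                 objloc = toy5$objloc_t1 + toy5$objloc_t2)
  zavg <- rowMeans(apply(sums5, 2, function(s) (s - mean(s)) / sd(s)))
  oracle <- 50 + 10 * (zavg - mean(zavg)) / sd(zavg)
  expect_equal(as.vector(composite_memory(toy5)), oracle, tolerance = 1e-10)
  # zero-variance task is an error naming the task
  flat <- toy5; flat$numword_t1 <- 5; flat$numword_t2 <- 5
  expect_error(composite_memory(flat), "numword")
})

test_that("ICV covariance adjustment removes the ICV dependence exactly", {
  set.seed(81)
  icv <- rnorm(20, 1.5e6, 1e5)
  vol <- 500 + 3e-4 * icv + rnorm(20, 0, 30)
  adj <- icv_adjust(vol, icv)
  expect_lt(abs(stats::cor(adj, icv)), 1e-10)
  expect_equal(mean(adj), mean(vol), tolerance = 1e-9)
  # subject exactly at the mean ICV is unchanged
  icv2 <- c(icv, mean(icv))
  vol2 <- c(vol, 600)
  expect_equal(icv_adjust(vol2, icv2)[21], 600, tolerance = 1e-9)
  # b = 0 when volume is uncorrelated with ICV by construction
  v0 <- qr.resid(qr(cbind(1, icv)), vol)
  expect_equal(icv_adjust(v0, icv), v0, tolerance = 1e-9, ignore_attr = TRUE)
  # 4-subject normal-equations oracle
  icv4 <- c(1.2, 1.4, 1.5, 1.9) * 1e6
  vol4 <- c(480, 530, 520, 610)
  b <- solve(crossprod(cbind(1, icv4)), crossprod(cbind(1, icv4), vol4))[2]
  expect_equal(as.vector(icv_adjust(vol4, icv4)),
               vol4 - b * (icv4 - mean(icv4)), tolerance = 1e-10)
  expect_error(icv_adjust(vol4, rep(1e6, 4)), "variance")
})

test_that("nuisance residualization is exact and rank-checked", {
  set.seed(82)
  n <- 30
  nuis <- cbind(sex = rbinom(n, 1, 0.5), fd = runif(n, 0.05, 0.4),
                snr = rnorm(n, 400, 100))
  y <- 2 + 0.5 * nuis[, "fd"] + rnorm(n)
  res <- residualize(y, nuis)
  for (j in 1:3) expect_lt(abs(stats::cor(res, nuis[, j])), 1e-10)
  expect_equal(mean(res), mean(y), tolerance = 1e-10)
  # values that are an exact linear function of nuisance become the mean
  ylin <- 1 + 2 * nuis[, "fd"] - 3 * nuis[, "snr"]
  expect_equal(residualize(ylin, nuis), rep(mean(ylin), n), tolerance = 1e-8)
  # orthogonal nuisance leaves the input unchanged
  x <- rnorm(n)
  northo <- qr.resid(qr(cbind(1, x)), rnorm(n))
  expect_equal(residualize(x, northo), x, tolerance = 1e-10)
  # brute-force pseudo-inverse oracle on a 6 x 2 system
  N6 <- matrix(c(1, 2, 3, 4, 5, 6, 2, 1, 4, 3, 6, 5), 6, 2)
  y6 <- c(3, 1, 4, 1, 5, 9)
  X6 <- cbind(1, N6)
  beta <- solve(t(X6) %*% X6) %*% t(X6) %*% y6
  expect_equal(residualize(y6, N6), as.vector(y6 - X6 %*% beta + mean(y6)),
               tolerance = 1e-10)
  expect_error(residualize(y, cbind(nuis, dup = nuis[, "fd"])),
               "rank deficient")
})

test_that("Wilks' lambda reduces to the univariate ANCOVA F and matches
           stats::manova for multivariate responses", {
  set.seed(83)
  n <- 40
  covs <- data.frame(sex = rbinom(n, 1, 0.5), fd = runif(n))
  pred <- data.frame(bs = rnorm(n))
  y1 <- 0.4 * pred$bs + rnorm(n)
  # single dependent: Wilks F equals the ANCOVA F
  fit1 <- manova_predict(cbind(y = y1), pred, covs)
  lm_full <- lm(y1 ~ sex + fd + bs, data = cbind(covs, pred))
  an <- anova(lm_full)
  expect_equal(fit1$wilks$F, an["bs", "F value"], tolerance = 1e-8)
  expect_equal(fit1$wilks$p, an["bs", "Pr(>F)"], tolerance = 1e-8)
  # multivariate: cross-check against summary.manova (independent route)
  Y <- cbind(y1 = y1, y2 = 0.2 * pred$bs + rnorm(n), y3 = rnorm(n))
  fit3 <- manova_predict(Y, pred, covs)
  mv <- summary(stats::manova(Y ~ sex + fd + bs, data = cbind(covs, pred)),
                test = "Wilks")
  expect_equal(fit3$wilks$lambda, mv$stats["bs", "Wilks"], tolerance = 1e-8)
  expect_equal(fit3$wilks$F, mv$stats["bs", "approx F"], tolerance = 1e-8)
  expect_error(manova_predict(Y[1:5, ], pred[1:5, , drop = FALSE],
                              covs[1:5, ]), "too few|rank")
})

test_that("multivariate null rejection rate is calibrated and planted
           coupling is detected with power", {
  set.seed(84)
  n <- 40
  rej <- replicate(500, {
    Y <- matrix(rnorm(n * 2), n, 2)
    P <- data.frame(p1 = rnorm(n))
    manova_predict(Y, P)$wilks$p <= 0.05
  })
  band <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
  # planted multivariate coupling: power >= 0.8 at this effect size
  hit <- replicate(200, {
    x <- rnorm(n)
    Y <- cbind(0.6 * x + rnorm(n), 0.5 * x + rnorm(n))
    manova_predict(Y, data.frame(x = x))$wilks$p <= 0.05
  })
  expect_gte(mean(hit), 0.8)
})

test_that("correlation tables match the textbook formula and have uniform
           null p-values", {
  x5 <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y5 <- c(2.0, 3.1, 2.5, 4.9, 4.2)
  tab <- correlation_table(data.frame(x = x5), data.frame(y = y5))
  r_oracle <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((y5 - mean(y5))^2))
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(tab$r, r_oracle, tolerance = 1e-12)
  expect_equal(tab$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)
  # y = -x gives r = -1
  tabneg <- correlation_table(data.frame(x = x5), data.frame(y = -x5))
  expect_equal(tabneg$r, -1, tolerance = 1e-12)
  # constant columns are skipped with a warning
  expect_warning(
    tc <- correlation_table(data.frame(a = x5, c = rep(1, 5)),
                            data.frame(y = y5)), "constant")
  expect_equal(nrow(tc), 1L)
  # null p-values are uniform (Kolmogorov distance < 0.05 over 1000 reps)
  set.seed(85)
  pv <- replicate(1000,
    correlation_table(data.frame(x = rnorm(30)), data.frame(y = rnorm(30)))$p)
  ks <- max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
  expect_lt(ks, 0.05)
})

test_that("axis-group classification applies the sign rule set, including
           the exclusion rule", {
  sc <- data.frame(
    subject = 1:6,
    aHC = c(1.2, 1.1, 0.4, -0.5, 0.5, -0.6),
    mHC = c(0.3, -0.2, 0.2, -0.1, -0.2, 0.4),
    pHC = c(-0.8, -0.9, 0.6, -2.0, 0.9, -0.7))
  g <- classify_axis_groups(sc)
  expect_equal(as.character(g$group),
               c("division-mid-anterior", "division-mid-posterior",
                 "all-anterior", "all-posterior", "excluded", "excluded"))
  # partition: every subject carries exactly one label; counts sum to n
  expect_equal(sum(attr(g, "counts")), 6)
  expect_false(anyNA(g$group))
  # flipped sign convention mirrors the labels
  gflip <- classify_axis_groups(transform(sc, aHC = -aHC, mHC = -mHC,
                                          pHC = -pHC),
                                anterior_positive = FALSE)
  expect_equal(g$group, gflip$group)
  # zero scores error without a tolerance; with one they are excluded
  sc0 <- sc; sc0$mHC[1] <- 0
  expect_error(classify_axis_groups(sc0), "zero")
  g0 <- classify_axis_groups(sc0, tol = 1e-8)
  expect_equal(as.character(g0$group[1]), "excluded")
  expect_error(classify_axis_groups(transform(sc, aHC = NA)), "missing")
})

test_that("one-tailed group comparison matches the pooled-variance oracle
           and is calibrated under the null", {
  out <- group_compare(c(1, 2, 3, 2, 3, 4),
                       factor(rep(c("g1", "g2"), each = 3)),
                       direction = "less")
  sp <- sqrt((2 * var(c(1, 2, 3)) + 2 * var(c(2, 3, 4))) / 4)
  t_oracle <- (2 - 3) / (sp * sqrt(2 / 3))
  expect_equal(out$t, t_oracle, tolerance = 1e-10)
  expect_equal(out$p, pt(t_oracle, 4), tolerance = 1e-10)
  # identical groups: t = 0, one-tailed p = 0.5
  same <- group_compare(rep(c(5, 6, 7), 2),
                        factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_error(group_compare(c(1, 2), factor(c("a", "b"))), ">= 2")
  # null calibration of the one-tailed test
  set.seed(86)
  rej <- replicate(500, {
    g <- factor(rep(c("a", "b"), each = 10))
    group_compare(rnorm(20), g, direction = "greater")$p <= 0.05
  })
  band <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})
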