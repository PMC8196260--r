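# Cohort-level scoring and inference: episodic-memory composite, mean
# imputation, ICV covariance adjustment, nuisance residualization,
# multivariate tests, correlation tables, axis-group classification, and
# one-tailed group comparisons.

.default_tasks <- list(word = c("word_t1", "word_t2"),
                       numword = c("numword_t1", "numword_t2"),
                       objloc = c("objloc_t1", "objloc_t2"))

#' Replace missing trial scores by the observed mean
#'
#' Each missing entry is replaced by the across-subject mean of the
#' observed values of that variable (mean imputation, appropriate under
#' missingness completely at random). A variable with no observed values
#' is an error.
#'
#' @param trials data.frame of per-trial scores (may contain `NA`).
#' @return list with `trials` (completed data.frame) and `log` (data.frame
#'   of per-variable missing counts and fractions).
#' @export
impute_missing <- function(trials) {
  log <- data.frame(variable = names(trials),
                    n_missing = vapply(trials, function(v) sum(is.na(v)),
                                       integer(1)),
                    row.names = NULL)
  log$fraction <- log$n_missing / nrow(trials)
  for (v in names(trials)) {
    if (all(is.na(trials[[v]])))
      stopf("variable %s is entirely missing; cannot impute", v)
    miss <- is.na(trials[[v]])
    if (any(miss)) trials[[v]][miss] <- mean(trials[[v]][!miss])
  }
  list(trials = trials, log = log)
}

#' Episodic-memory composite (T units)
#'
#' For each task, trial scores are summed; the three task sums are
#' z-standardized across subjects, averaged, and the average is linearly
#' rescaled to a sample mean of 50 and SD of 10 (a T score). With the
#' default battery the task sums are bounded by the maxima 32 (word),
#' 16 (number-word) and 24 (object-location).
#'
#' @param trials data.frame of per-trial scores (no missing values; run
#'   [impute_missing()] first).
#' @param tasks named list mapping each task to its trial columns.
#' @return numeric vector of composite scores; `attr(, "task_sums")` holds
#'   the per-task sum matrix.
#' @export
composite_memory <- function(trials, tasks = .default_tasks) {
  if (nrow(trials) < 3L) stopf("composite needs >= 3 subjects")
  if (anyNA(trials[unlist(tasks)]))
    stopf("trials contain missing values; impute first")
  sums <- vapply(tasks, function(cols)
    rowSums(trials[, cols, drop = FALSE]), numeric(nrow(trials)))
  zvar <- apply(sums, 2L, stats::sd)
  if (any(zvar == 0))
    stopf("task %s has zero between-subject variance",
          paste(names(tasks)[zvar == 0], collapse = ", "))
  zavg <- rowMeans(scale(sums))
  out <- 50 + 10 * (zavg - mean(zavg)) / stats::sd(zavg)
  attr(out, "task_sums") <- sums
  out
}

#' Intracranial-volume covariance adjustment of regional volumes
#'
#' Applies `adjusted = raw - b (ICV - mean ICV)` where `b` is the
#' least-squares slope of the regional volume on ICV. The adjusted volumes
#' preserve the regional mean and have exactly zero sample correlation with
#' ICV.
#'
#' @param raw_volume numeric vector of regional volumes (mm^3).
#' @param icv numeric vector of intracranial volumes (mm^3).
#' @return numeric vector of adjusted volumes; `attr(, "slope")` is `b`.
#' @export
icv_adjust <- function(raw_volume, icv) {
  if (length(raw_volume) != length(icv)) stopf("length mismatch")
  if (length(icv) < 3L) stopf("ICV adjustment needs >= 3 subjects")
  if (stats::var(icv) == 0) stopf("ICV has zero variance")
  b <- stats::cov(raw_volume, icv) / stats::var(icv)
  out <- raw_volume - b * (icv - mean(icv))
  attr(out, "slope") <- b
  out
}

#' Residualize a variable on nuisance covariates
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' nuisance columns, with the original mean added back. The output is
#' exactly uncorrelated with every nuisance column.
#'
#' @param values numeric vector.
#' @param nuisance numeric matrix or data.frame of nuisance columns (factors
#'   in a data.frame are expanded to dummies).
#' @return numeric vector of mean-restored residuals.
#' @export
residualize <- function(values, nuisance) {
  X <- if (is.data.frame(nuisance))
    stats::model.matrix(~ ., data = nuisance)
  else cbind(`(Intercept)` = 1, as.matrix(nuisance))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stopf("nuisance matrix is rank deficient; collinear columns: %s",
          paste(drop, collapse = ", "))
  }
  qr.resid(qrX, values) + mean(values)
}

# Wilks' lambda with Rao's F approximation for the hypothesis block with
# hypothesis cross-products H and error cross-products E.
.wilks_f <- function(E, H, p, q, v) {
  lambda <- det(E) / det(E + H)
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q - 2) / 2
  lroot <- lambda^(1 / tt)
  Fstat <- (1 - lroot) / lroot * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Multivariate prediction test (Wilks' lambda) with covariates
#'
#' Tests the predictor block against the dependent set after the
#' covariates: the error matrix E comes from the full linear model
#' `Y ~ covariates + predictors`, the hypothesis matrix H from the drop in
#' residual cross-products relative to `Y ~ covariates`. Reports Wilks'
#' lambda with Rao's F approximation (which reduces exactly to the
#' univariate ANCOVA F when there is a single dependent), per-dependent
#' univariate F tests, and coefficients, alongside the Bonferroni-adjusted
#' significance level.
#'
#' @param dependents numeric matrix/data.frame of dependent variables.
#' @param predictors numeric matrix/data.frame of predictors of interest.
#' @param covariates optional matrix/data.frame of control covariates.
#' @param alpha_adjusted Bonferroni-adjusted significance level to report
#'   against (default 0.01).
#' @return object of class `manova_fit`: `wilks` (lambda, F, df, p for the
#'   predictor block), `univariate` (per-dependent F and p),
#'   `coefficients`, `alpha_adjusted`.
#' @export
manova_predict <- function(dependents, predictors, covariates = NULL,
                           alpha_adjusted = 0.01) {
  Y <- as.matrix(dependents)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  P <- stats::model.matrix(~ ., data = as.data.frame(predictors))[, -1,
                                                                  drop = FALSE]
  C <- if (!is.null(covariates))
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                               drop = FALSE]
  else NULL
  n <- nrow(Y)
  X_red <- cbind(rep(1, n), C)
  X_full <- cbind(X_red, P)
  if (n <= ncol(X_full) + 1L)
    stopf("too few observations (%d) for %d model columns", n, ncol(X_full))
  qf <- qr(X_full); qr_red <- qr(X_red)
  if (qf$rank < ncol(X_full)) stopf("model matrix is rank deficient")
  Rf <- qr.resid(qf, Y)
  Rr <- qr.resid(qr_red, Y)
  E <- crossprod(Rf)
  H <- crossprod(Rr) - E
  p <- ncol(Y)
  q <- ncol(P)
  v <- n - qf$rank
  if (abs(det(E)) < .Machine$double.xmin)
    stopf("singular error cross-product matrix")
  wil <- .wilks_f(E, H, p, q, v)
  uni <- data.frame(dependent = colnames(Y),
                    F = (diag(H) / q) / (diag(E) / v),
                    df1 = q, df2 = v, row.names = NULL)
  uni$p <- stats::pf(uni$F, q, v, lower.tail = FALSE)
  structure(list(wilks = wil, univariate = uni,
                 coefficients = qr.coef(qf, Y),
                 alpha_adjusted = alpha_adjusted, n = n),
            class = "manova_fit")
}

#' Pairwise correlation table with raw and adjusted significance flags
#'
#' Pearson r and two-sided p for every (x column, y column) pair, flagged
#' at the raw level `alpha` and at the Bonferroni-adjusted level
#' `alpha_adjusted`. Constant columns are skipped with a warning.
#'
#' @param x,y data.frames/matrices of numeric columns.
#' @param alpha raw significance level.
#' @param alpha_adjusted adjusted significance level (default 0.01).
#' @return data.frame with columns `x`, `y`, `r`, `p`, `sig_raw`,
#'   `sig_adjusted`.
#' @export
correlation_table <- function(x, y, alpha = 0.05, alpha_adjusted = 0.01) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (nrow(x) < 4L) stopf("correlation table needs >= 4 subjects")
  rows <- list()
  for (cx in names(x)) for (cy in names(y)) {
    if (stats::sd(x[[cx]]) == 0 || stats::sd(y[[cy]]) == 0) {
      warnf("skipping constant pair (%s, %s)", cx, cy)
      next
    }
    ct <- stats::cor.test(x[[cx]], y[[cy]])
    rows[[length(rows) + 1L]] <-
      data.frame(x = cx, y = cy, r = unname(ct$estimate),
                 p = ct$p.value, sig_raw = ct$p.value < alpha,
                 sig_adjusted = ct$p.value < alpha_adjusted)
  }
  do.call(rbind, rows)
}

#' Classify subjects by the sign pattern of their axis brain scores
#'
#' With the convention that positive LV1 brain scores denote adherence to
#' the anterior network: subjects whose aHC and pHC scores disagree in sign
#' express the anterior-posterior division and are split by their mHC sign
#' into `division-mid-anterior` (mHC positive) and `division-mid-posterior`
#' (mHC negative); subjects with all three scores positive are
#' `all-anterior`, all negative `all-posterior`; aHC and pHC same-signed
#' with an opposing mHC is `excluded`. Exact zero scores are an error
#' unless a tolerance is configured, in which case scores within the
#' tolerance of zero are `excluded` as unclassifiable.
#'
#' @param scores data.frame with numeric columns `aHC`, `mHC`, `pHC` (LV1
#'   brain scores per subject) and optionally `subject`.
#' @param anterior_positive if `FALSE`, the sign convention is flipped
#'   before classification.
#' @param tol optional magnitude below which a score counts as untypeable.
#' @return data.frame with `subject` and `group` (factor with the four
#'   group labels plus `excluded`); group counts in `attr(, "counts")`.
#' @export
classify_axis_groups <- function(scores, anterior_positive = TRUE,
                                 tol = NULL) {
  need <- c("aHC", "mHC", "pHC")
  if (!all(need %in% names(scores)))
    stopf("scores must have columns aHC, mHC, pHC")
  s <- as.matrix(scores[, need])
  if (anyNA(s)) stopf("missing brain scores for %d subject(s)", sum(!stats::complete.cases(s)))
  if (!anterior_positive) s <- -s
  if (is.null(tol)) {
    if (any(s == 0))
      stopf("exact zero brain scores cannot be signed; configure a tolerance")
    small <- rep(FALSE, nrow(s))
  } else {
    small <- apply(abs(s) <= tol, 1L, any)
  }
  sg <- sign(s)
  lab <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (small[i]) { lab[i] <- "excluded"; next }
    a <- sg[i, "aHC"]; m <- sg[i, "mHC"]; p <- sg[i, "pHC"]
    lab[i] <- if (a != p) {
      if (m > 0) "division-mid-anterior" else "division-mid-posterior"
    } else if (m == a) {
      if (a > 0) "all-anterior" else "all-posterior"
    } else "excluded"
  }
  lv <- c("division-mid-anterior", "division-mid-posterior", "all-anterior",
          "all-posterior", "excluded")
  out <- data.frame(subject = if ("subject" %in% names(scores))
    scores$subject else seq_len(nrow(s)),
    group = factor(lab, levels = lv))
  attr(out, "counts") <- table(out$group)
  out
}

#' One-tailed two-sample comparison of an outcome between groups
#'
#' Pooled-variance two-sample t-test with a one-tailed p-value in the
#' stated direction (`"greater"`: first group mean larger).
#'
#' @param outcome numeric outcome vector.
#' @param group two-level factor (first level is the reference group).
#' @param direction `"greater"` or `"less"` for the alternative on the
#'   first group's mean.
#' @param var_equal pooled (TRUE, default) or Welch variance.
#' @return list with `t`, `df`, `p` (one-tailed), `means`, `direction`.
#' @export
group_compare <- function(outcome, group, direction = c("greater", "less"),
                          var_equal = TRUE) {
  direction <- match.arg(direction)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stopf("group must have exactly 2 levels")
  n <- table(group)
  if (any(n < 2L)) stopf("both groups need >= 2 subjects")
  x1 <- outcome[group == levels(group)[1]]
  x2 <- outcome[group == levels(group)[2]]
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0 && mean(x1) == mean(x2)) {
    return(list(t = 0, df = sum(n) - 2, p = 0.5,
                means = c(mean(x1), mean(x2)), direction = direction))
  }
  tt <- stats::t.test(x1, x2, alternative = direction, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = c(mean(x1), mean(x2)), direction = direction)
}
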