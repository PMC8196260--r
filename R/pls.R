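# Partial least squares on stacked connectivity maps: mean-centered
# (condition-contrast) and behavioral variants, permutation tests on
# singular values, bootstrap resampling with procrustes alignment, BSR
# maps, and cluster extraction.

.rank_keep <- function(d, tol = 1e-12) {
  if (!length(d) || d[1] <= 0) return(1L)
  max(1L, sum(d > d[1] * tol))
}

# Condition-mean matrix, grand-mean centered (task-PLS centering).
.mc_center <- function(X, cond) {
  M <- rowsum(X, cond, reorder = FALSE) / as.vector(table(cond)[levels(cond)])
  # rowsum with reorder = FALSE keeps first-appearance order; re-align to
  # factor level order for a stable condition axis
  M <- M[levels(cond), , drop = FALSE]
  sweep(M, 2L, colMeans(M))
}

.mc_d <- function(X, cond) {
  Mc <- .mc_center(X, cond)
  La.svd(Mc, nu = 0L, nv = 0L)$d
}

#' Mean-centered (condition-contrast) PLS
#'
#' Builds the condition-mean matrix (one row per condition: the mean over
#' subjects of that condition's rows of `X`), removes the grand column mean
#' across conditions, and decomposes the centered matrix by SVD. Each
#' latent variable (LV) is a singular triplet: a condition-salience vector,
#' a singular value, and a voxel-salience pattern. Brain scores are the
#' projections of each (subject, condition) row of `X` onto the voxel
#' saliences. Percent variance of LV i is \eqn{s_i^2 / \sum_j s_j^2}.
#' Numerically null singular values (below `1e-12` of the largest) are
#' dropped, so with C conditions at most C - 1 LVs are returned.
#'
#' @param x a [conn_stack()] or a numeric matrix with one row per
#'   (subject, condition).
#' @param condition factor of condition labels per row (taken from the
#'   `conn_stack` when omitted).
#' @param subject subject ids per row (required for resampling inference).
#' @return object of class `pls_result` with elements `saliences`
#'   (voxel x LV), `d` (singular values), `cond_saliences`
#'   (condition x LV), `brain_scores` (row x LV; the plain
#'   voxel-by-salience summation), `brain_scores_centered` (the same
#'   scores relative to the grand condition-mean score, the scale on which
#'   condition contributions straddle zero), `score_center`, `pct_var`,
#'   `condition`, `subject`, `mode = "mean_centered"`.
#' @export
mean_centered_pls <- function(x, condition = NULL, subject = NULL) {
  if (inherits(x, "conn_stack")) {
    condition <- x$condition; subject <- x$subject; X <- x$X
  } else X <- x
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) < 2L)
    stopf("mean-centered PLS needs >= 2 conditions; got %d", nlevels(condition))
  cnt <- table(condition)
  if (any(cnt < 3L))
    stopf("every condition needs >= 3 subjects; smallest has %d", min(cnt))
  if (is.null(subject)) subject <- rep(seq_len(cnt[1]), nlevels(condition))
  Mc <- .mc_center(X, condition)
  sv <- svd(Mc)
  L <- .rank_keep(sv$d)
  v <- sv$v[, seq_len(L), drop = FALSE]
  u <- sv$u[, seq_len(L), drop = FALSE]
  d <- sv$d[seq_len(L)]
  rownames(u) <- levels(condition)
  M <- rowsum(X, condition, reorder = FALSE)[levels(condition), ,
                                             drop = FALSE] /
    as.vector(table(condition)[levels(condition)])
  score_center <- drop(colMeans(M) %*% v)  # grand-mean score per LV
  scores <- X %*% v
  structure(list(saliences = v, d = d, cond_saliences = u,
                 brain_scores = scores,
                 brain_scores_centered = sweep(scores, 2L, score_center),
                 score_center = score_center,
                 pct_var = 100 * d^2 / sum(sv$d^2),
                 condition = condition, subject = subject,
                 mode = "mean_centered"),
            class = "pls_result")
}

# z-score columns within a block; zero-variance columns are set to 0 (and
# counted) rather than NaN.
.zscore_block <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2L, stats::sd)
  Z <- sweep(M, 2L, mu)
  ok <- sd > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, sd[ok], "/")
  Z[, !ok] <- 0
  attr(Z, "n_constant") <- sum(!ok)
  Z
}

.behav_prepare <- function(X, Y, condition) {
  conds <- levels(condition)
  Xz <- X; Yz <- Y
  for (cc in conds) {
    sel <- condition == cc
    yb <- Y[sel, , drop = FALSE]
    sds <- apply(yb, 2L, stats::sd)
    if (any(sds == 0))
      stopf("behavior column(s) %s constant within condition %s",
            paste(colnames(Y)[sds == 0], collapse = ", "), cc)
    Yz[sel, ] <- scale(yb)
    Xz[sel, ] <- .zscore_block(X[sel, , drop = FALSE])
  }
  list(Xz = Xz, Yz = Yz)
}

# Stacked cross-block correlation matrix R = [Y_c' X_c / (n_c - 1)]_c.
.behav_R <- function(Xz, Yz, condition) {
  do.call(rbind, lapply(levels(condition), function(cc) {
    sel <- condition == cc
    crossprod(Yz[sel, , drop = FALSE], Xz[sel, , drop = FALSE]) /
      (sum(sel) - 1)
  }))
}

#' Behavioral PLS
#'
#' Within each condition, the columns of the connectivity block `X` and the
#' behavior block `Y` are z-scored across subjects and the condition-wise
#' cross-block correlation matrices \eqn{R_c = Y_c^T X_c} are stacked and
#' decomposed by SVD. Correlation scores are the per-condition correlations
#' between each behavior column and the LV brain scores.
#'
#' @inheritParams mean_centered_pls
#' @param y numeric matrix of behavioral covariates, rows aligned with `x`
#'   (e.g. episodic memory and hippocampal D2DR binding potential).
#' @return object of class `pls_result` with additionally
#'   `behav_saliences` ((condition x behavior) x LV, row labels
#'   `<condition>.<behavior>`), `corr_scores` (condition x behavior x LV
#'   array) and `mode = "behavioral"`.
#' @export
behavioral_pls <- function(x, y, condition = NULL, subject = NULL) {
  if (inherits(x, "conn_stack")) {
    condition <- x$condition; subject <- x$subject; X <- x$X
  } else X <- x
  Y <- as.matrix(y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("b", seq_len(ncol(Y)))
  condition <- droplevels(as.factor(condition))
  if (nrow(Y) != nrow(X)) stopf("x and y must have aligned rows")
  if (ncol(Y) < 2L)
    warnf("behavioral PLS with a single behavior column")
  if (is.null(subject))
    subject <- rep(seq_len(sum(condition == levels(condition)[1])),
                   nlevels(condition))
  pb <- .behav_prepare(X, Y, condition)
  R <- .behav_R(pb$Xz, pb$Yz, condition)
  sv <- svd(R)
  L <- .rank_keep(sv$d)
  v <- sv$v[, seq_len(L), drop = FALSE]
  u <- sv$u[, seq_len(L), drop = FALSE]
  d <- sv$d[seq_len(L)]
  rownames(u) <- paste(rep(levels(condition), each = ncol(Y)),
                       colnames(Y), sep = ".")
  scores <- pb$Xz %*% v
  corr <- .corr_scores(scores, pb$Yz, condition, ncol(Y), L)
  dimnames(corr) <- list(levels(condition), colnames(Y), NULL)
  structure(list(saliences = v, d = d, behav_saliences = u,
                 brain_scores = scores, pct_var = 100 * d^2 / sum(sv$d^2),
                 corr_scores = corr, condition = condition, subject = subject,
                 behaviors = colnames(Y), mode = "behavioral"),
            class = "pls_result")
}

.corr_scores <- function(scores, Y, condition, B, L) {
  conds <- levels(condition)
  out <- array(NA_real_, c(length(conds), B, L))
  for (ci in seq_along(conds)) {
    sel <- condition == conds[ci]
    out[ci, , ] <- stats::cor(Y[sel, , drop = FALSE],
                              scores[sel, , drop = FALSE])
  }
  out
}

#' Permutation test of latent-variable significance
#'
#' For the mean-centered variant, condition labels are permuted within
#' subject (each subject's rows are randomly reassigned across conditions);
#' for the behavioral variant, behavior rows are permuted across subjects
#' within each condition. The decomposition is recomputed for each
#' permutation and \eqn{p_i = (1 + \#\{s_i^{perm} \ge s_i^{obs}\}) /
#' (1 + n_{perm})}, so p can never be exactly zero.
#'
#' @param fit a `pls_result`.
#' @param x the `conn_stack` or matrix the fit was computed from.
#' @param y the behavior block (behavioral variant only).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param perm_fun optional function(iteration) returning the permutation
#'   of row indices to use, for diagnostics (e.g. the identity permutation
#'   yields p = 1 on every LV).
#' @return numeric vector of per-LV p-values.
#' @export
permutation_test <- function(fit, x, y = NULL, n_perm = 1000L, seed = 1L,
                             perm_fun = NULL) {
  stopifnot(inherits(fit, "pls_result"))
  if (n_perm < 100L) stopf("n_perm must be >= 100, got %d", n_perm)
  X <- if (inherits(x, "conn_stack")) x$X else x
  condition <- fit$condition
  L <- length(fit$d)
  d_obs <- fit$d
  count <- numeric(L)
  with_seed(seed, {
    if (fit$mode == "mean_centered") {
      rows_by_subject <- split(seq_len(nrow(X)), fit$subject)
      cond_int <- condition
      for (b in seq_len(n_perm)) {
        cp <- condition
        if (is.null(perm_fun)) {
          for (idx in rows_by_subject)
            cp[idx] <- condition[idx][sample.int(length(idx))]
        } else {
          cp <- condition[perm_fun(b)]
        }
        dp <- .mc_d(X, cp)
        count <- count + (dp[seq_len(L)] >= d_obs - 1e-12)
      }
    } else {
      Y <- as.matrix(y)
      if (is.null(colnames(Y))) colnames(Y) <- paste0("b", seq_len(ncol(Y)))
      pb <- .behav_prepare(X, Y, condition)
      idx_by_cond <- split(seq_len(nrow(X)), condition)
      for (b in seq_len(n_perm)) {
        Yp <- pb$Yz
        for (idx in idx_by_cond) {
          pr <- if (is.null(perm_fun)) idx[sample.int(length(idx))]
          else idx[perm_fun(b)[seq_along(idx)]]
          Yp[idx, ] <- pb$Yz[pr, , drop = FALSE]
        }
        dp <- La.svd(.behav_R(pb$Xz, Yp, condition), nu = 0L, nv = 0L)$d
        count <- count + (dp[seq_len(L)] >= d_obs - 1e-12)
      }
    }
  })
  (1 + count) / (1 + n_perm)
}

# Orthogonal procrustes rotation aligning columns of A to columns of B.
.procrustes_rot <- function(A, B) {
  sv <- svd(crossprod(A, B))
  sv$u %*% t(sv$v)
}

#' Bootstrap resampling of a PLS solution
#'
#' Subjects are resampled with replacement, keeping each subject's rows
#' across conditions together; draws with fewer than 3 distinct subjects
#' are redrawn (and counted). Every bootstrap solution is aligned to the
#' original by an orthogonal procrustes rotation of the voxel saliences
#' (the SVD sign/axis indeterminacy would otherwise corrupt the standard
#' errors). Outputs: per-voxel salience standard errors, the bootstrap
#' ratio map BSR = salience / SE (a pseudo-z; |BSR| >= 3.3 corresponds to
#' two-tailed p < 0.001), and 95 percent percentile confidence intervals
#' for condition-mean brain scores relative to the grand mean
#' (mean-centered variant; an interval covering zero reads as "no reliable
#' contribution to the contrast") or for the behavior-connectivity
#' correlation scores (behavioral variant). Score and correlation CIs
#' project each bootstrap sample onto the original saliences;
#' re-estimating the saliences per draw would re-inflate the
#' SVD-maximized contrast and bias the percentile interval.
#'
#' @inheritParams permutation_test
#' @param n_boot number of bootstrap draws (>= 100; default 1000).
#' @param ci_level confidence level for the percentile intervals.
#' @return object of class `pls_boot` with `se` (voxel x LV), `bsr`
#'   (voxel x LV), `ci` (list `lower`/`upper`; condition x LV for the
#'   mean-centered variant, condition x behavior x LV for the behavioral
#'   variant), `n_redrawn`, `boot_stats` (the raw bootstrap statistic
#'   draws, iterations first).
#' @export
pls_bootstrap <- function(fit, x, y = NULL, n_boot = 1000L, seed = 1L,
                          ci_level = 0.95) {
  stopifnot(inherits(fit, "pls_result"))
  if (n_boot < 100L) stopf("n_boot must be >= 100, got %d", n_boot)
  X <- if (inherits(x, "conn_stack")) x$X else x
  condition <- fit$condition
  subject <- fit$subject
  L <- length(fit$d)
  V0 <- fit$saliences
  subj_ids <- unique(subject)
  ns <- length(subj_ids)
  rows_by_subject <- lapply(subj_ids, function(s) which(subject == s))
  sal_sum <- matrix(0, nrow(V0), L)
  sal_sq <- matrix(0, nrow(V0), L)
  behav <- fit$mode == "behavioral"
  if (behav) {
    Y <- as.matrix(y)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("b", seq_len(ncol(Y)))
    B <- ncol(Y)
    stat_dim <- c(nlevels(condition), B, L)
  } else {
    stat_dim <- c(nlevels(condition), L)
  }
  boot_stats <- array(NA_real_, c(n_boot, stat_dim))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        draw <- sample.int(ns, ns, replace = TRUE)
        if (length(unique(draw)) >= 3L) break
        n_redrawn <- n_redrawn + 1L
      }
      idx <- unlist(rows_by_subject[draw])
      Xb <- X[idx, , drop = FALSE]
      cb <- condition[idx]
      if (!behav) {
        sv <- svd(.mc_center(Xb, cb))
        Lb <- min(L, ncol(sv$v))
        Vb <- sv$v[, seq_len(Lb), drop = FALSE]
        Q <- .procrustes_rot(Vb, V0[, seq_len(Lb), drop = FALSE])
        Va <- Vb %*% Q
        if (Lb < L) Va <- cbind(Va, matrix(0, nrow(Va), L - Lb))
        # score CIs: project the bootstrap sample onto the ORIGINAL
        # saliences (re-estimated saliences would re-inflate the contrast
        # each draw and shift the percentile interval off the estimand)
        Sb <- Xb %*% V0
        Mb <- rowsum(Sb, cb, reorder = FALSE) /
          as.vector(table(cb)[levels(cb)])
        Mb <- Mb[levels(condition), , drop = FALSE]
        # condition means relative to the draw's grand mean: "CI covers
        # zero" then reads as "no reliable contribution to the contrast"
        boot_stats[b, , ] <- sweep(Mb, 2L, colMeans(Mb))
      } else {
        Yb <- Y[idx, , drop = FALSE]
        pb <- .behav_prepare(Xb, Yb, cb)
        sv <- svd(.behav_R(pb$Xz, pb$Yz, cb))
        Lb <- min(L, ncol(sv$v))
        Vb <- sv$v[, seq_len(Lb), drop = FALSE]
        Q <- .procrustes_rot(Vb, V0[, seq_len(Lb), drop = FALSE])
        Va <- Vb %*% Q
        if (Lb < L) Va <- cbind(Va, matrix(0, nrow(Va), L - Lb))
        Sb <- pb$Xz %*% V0
        boot_stats[b, , , ] <- .corr_scores(Sb, pb$Yz, cb, ncol(Yb), L)
      }
      sal_sum <- sal_sum + Va
      sal_sq <- sal_sq + Va^2
    }
  })
  se_var <- (sal_sq - sal_sum^2 / n_boot) / (n_boot - 1)
  se_var[se_var < 0] <- 0
  se <- sqrt(se_var)
  bsr <- matrix(0, nrow(V0), L)
  nz <- se > 0
  bsr[nz] <- V0[nz] / se[nz]
  bsr[!nz] <- sign(V0[!nz]) * Inf
  bsr[!nz & V0 == 0] <- 0
  a <- (1 - ci_level) / 2
  lower <- apply(boot_stats, seq_along(stat_dim) + 1L, stats::quantile,
                 probs = a, names = FALSE)
  upper <- apply(boot_stats, seq_along(stat_dim) + 1L, stats::quantile,
                 probs = 1 - a, names = FALSE)
  dn <- if (behav) list(levels(condition), colnames(Y), NULL)
  else list(levels(condition), NULL)
  dim(lower) <- dim(upper) <- stat_dim
  dimnames(lower) <- dimnames(upper) <- dn
  structure(list(se = se, bsr = bsr,
                 ci = list(lower = lower, upper = upper, level = ci_level),
                 n_redrawn = n_redrawn, boot_stats = boot_stats,
                 mode = fit$mode),
            class = "pls_boot")
}

# --- cluster extraction -----------------------------------------------------

.neighbor_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]  # 26-connectivity
}

# Connected components (26-connectivity) over linear voxel indices `sel`.
.components <- function(sel, grid) {
  lab <- integer(prod(grid))
  lab[sel] <- -1L  # unvisited, in set
  offs <- .neighbor_offsets()
  comp <- 0L
  out <- list()
  for (s in sel) {
    if (lab[s] != -1L) next
    comp <- comp + 1L
    queue <- s; lab[s] <- comp; members <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, grid)
      nb <- sweep(offs, 2L, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] & nb[, 2] >= 1 &
        nb[, 2] <= grid[2] & nb[, 3] >= 1 & nb[, 3] <= grid[3]
      nbi <- nb[ok, 1] + (nb[ok, 2] - 1L) * grid[1] +
        (nb[ok, 3] - 1L) * grid[1] * grid[2]
      new <- nbi[lab[nbi] == -1L]
      if (length(new)) {
        lab[new] <- comp
        queue <- c(queue, new)
        members <- c(members, new)
      }
    }
    out[[comp]] <- sort(members)
  }
  out
}

#' Extract reliable clusters from a bootstrap-ratio map
#'
#' Suprathreshold voxels (|BSR| >= `threshold`, default 3.3, the two-tailed
#' standard-normal critical value at p = 0.001) are grouped by
#' 26-connectivity, separately for positive and negative saliences.
#' Clusters whose peaks lie closer than `min_peak_sep` mm are merged (the
#' weaker peak becomes a sub-peak); merged clusters smaller than `min_size`
#' voxels are dropped. Within a cluster, local maxima other than the peak
#' are reported as sub-peaks.
#'
#' @param bsr a 3-D numeric array of bootstrap ratios, or a vector with
#'   `grid` supplied.
#' @param grid grid dimensions when `bsr` is a vector.
#' @param threshold BSR magnitude threshold.
#' @param min_size minimum cluster extent in voxels.
#' @param min_peak_sep minimum distance between cluster peaks, mm.
#' @param vox_mm voxel edge lengths in mm.
#' @return list of class `cluster_table` with `clusters` (one row per
#'   cluster: sign, peak voxel coordinates, size, peak BSR) and `subpeaks`
#'   (one row per sub-peak with its cluster id).
#' @export
extract_clusters <- function(bsr, grid = NULL, threshold = 3.3,
                             min_size = 10L, min_peak_sep = 10,
                             vox_mm = c(1, 1, 1)) {
  if (is.array(bsr) && length(dim(bsr)) == 3L) {
    grid <- dim(bsr); bsr <- as.vector(bsr)
  }
  if (is.null(grid)) stopf("grid dimensions required for a vector map")
  grid <- as.integer(grid)
  if (any(!is.finite(bsr))) stopf("bsr map must be finite")
  coords <- grid_coords(grid)
  mm <- sweep(coords, 2L, vox_mm, "*")
  offs <- .neighbor_offsets()

  clusters <- list()
  for (sgn in c(1, -1)) {
    sel <- which(sgn * bsr >= threshold)
    if (!length(sel)) next
    comps <- .components(sel, grid)
    if (!length(comps)) next
    peaks <- vapply(comps, function(m) m[which.max(abs(bsr[m]))], numeric(1))
    ord <- order(-abs(bsr[peaks]))
    comps <- comps[ord]; peaks <- peaks[ord]
    merged_into <- rep(NA_integer_, length(comps))
    for (i in seq_along(comps)) {
      if (!is.na(merged_into[i])) next
      if (i < length(comps)) {
        for (j in seq(i + 1L, length(comps))) {
          if (!is.na(merged_into[j])) next
          dmm <- sqrt(sum((mm[peaks[i], ] - mm[peaks[j], ])^2))
          if (dmm < min_peak_sep) merged_into[j] <- i
        }
      }
    }
    for (i in which(is.na(merged_into))) {
      members <- sort(unlist(comps[c(i, which(merged_into == i))]))
      if (length(members) < min_size) next
      clusters[[length(clusters) + 1L]] <-
        list(sign = sgn, members = members,
             peak = members[which.max(abs(bsr[members]))])
    }
  }

  if (!length(clusters)) {
    return(structure(list(
      clusters = data.frame(cluster = integer(0), sign = numeric(0),
                            x = integer(0), y = integer(0), z = integer(0),
                            size = integer(0), bsr = numeric(0)),
      subpeaks = data.frame(cluster = integer(0), x = integer(0),
                            y = integer(0), z = integer(0),
                            bsr = numeric(0))), class = "cluster_table"))
  }

  in_set <- logical(prod(grid))
  crows <- list(); srows <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    in_set[] <- FALSE; in_set[cl$members] <- TRUE
    # local maxima of |BSR| within the cluster
    is_max <- vapply(cl$members, function(v) {
      co <- arrayInd(v, grid)
      nb <- sweep(offs, 2L, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] & nb[, 2] >= 1 &
        nb[, 2] <= grid[2] & nb[, 3] >= 1 & nb[, 3] <= grid[3]
      nbi <- nb[ok, 1] + (nb[ok, 2] - 1L) * grid[1] +
        (nb[ok, 3] - 1L) * grid[1] * grid[2]
      nbi <- nbi[in_set[nbi]]
      all(abs(bsr[v]) >= abs(bsr[nbi]))
    }, logical(1))
    maxima <- setdiff(cl$members[is_max], cl$peak)
    maxima <- maxima[order(-abs(bsr[maxima]))]
    pc <- coords[cl$peak, ]
    crows[[k]] <- data.frame(cluster = k, sign = cl$sign, x = pc[["x"]],
                             y = pc[["y"]], z = pc[["z"]],
                             size = length(cl$members), bsr = bsr[cl$peak])
    if (length(maxima)) {
      sc <- coords[maxima, , drop = FALSE]
      srows[[length(srows) + 1L]] <-
        data.frame(cluster = k, x = sc[, "x"], y = sc[, "y"], z = sc[, "z"],
                   bsr = bsr[maxima])
    }
  }
  structure(list(clusters = do.call(rbind, crows),
                 subpeaks = if (length(srows)) do.call(rbind, srows)
                 else data.frame(cluster = integer(0), x = integer(0),
                                 y = integer(0), z = integer(0),
                                 bsr = numeric(0))),
            class = "cluster_table")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("pls_result (%s): %d LV(s)\n", x$mode, length(x$d)))
  cat("  singular values:", signif(x$d, 4), "\n")
  cat("  %% variance:", signif(x$pct_var, 4), "\n")
  invisible(x)
}
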