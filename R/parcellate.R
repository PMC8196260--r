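# Data-driven longitudinal-axis parcellation: temporal-concatenation group
# spatial ICA restricted to a structure mask, cross-hemisphere component
# selection by expected axis centers, and ROI assembly.
#
# No fixed-point ICA implementation is available among the installed
# packages, so the standard algorithm (symmetric FastICA with the tanh
# negentropy contrast after PCA whitening) is implemented here.

# Symmetric fixed-point ICA on whitened data Z (k x n samples).
.fastica_symm <- function(Z, max_iter = 500L, tol = 1e-9) {
  k <- nrow(Z); n <- ncol(Z)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    W1 <- sym_decor(G %*% t(Z) / n - diag(rowMeans(1 - G^2), k) %*% W)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  W
}

#' Group spatial ICA over temporally concatenated subject series
#'
#' Each subject's masked series is variance-normalized per voxel, the
#' series are concatenated in time across subjects, reduced to `k`
#' principal components, and rotated to spatial independence by fixed-point
#' negentropy ICA. Component maps are unit-norm within the mask with the
#' sign convention that the peak weight is positive; each component carries
#' an axis-center coordinate (the `y` of its peak-|weight| voxel) when
#' voxel coordinates are supplied.
#'
#' @param series list (>= 2 subjects) of time x voxel matrices, already
#'   restricted to the structure mask; all with the same voxel count.
#' @param k number of components (<= achievable rank).
#' @param coords optional voxel coordinate matrix (voxel x 3, columns
#'   x/y/z) for the masked voxels, e.g. `grid_coords(grid)[mask, ]`.
#' @param hemisphere optional hemisphere label attached to all components.
#' @param mask_index optional linear voxel indices of the masked voxels in
#'   the full grid, carried on each component so that ROIs assembled from
#'   several ICA runs (e.g. one per hemisphere) live in one voxel space.
#' @param seed RNG seed for the ICA initialization (results are
#'   deterministic given a seed, up to the fixed sign convention).
#' @return list of `ica_component` objects: `map` (unit-norm voxel
#'   vector), `hemisphere`, `center_y`, `peak_voxel`, `grid_index`.
#' @export
group_ica <- function(series, k, coords = NULL, hemisphere = NA_character_,
                      mask_index = NULL, seed = 1L) {
  if (!is.list(series) || length(series) < 2L)
    stopf("group ICA needs >= 2 subjects")
  V <- ncol(series[[1]])
  if (k > V) stopf("k = %d exceeds masked voxel count %d", k, V)
  Xc <- do.call(rbind, lapply(series, function(s) {
    stopifnot(ncol(s) == V)
    sc <- sweep(s, 2L, colMeans(s))  # remove voxel means (baseline)
    tot <- sqrt(mean(sc^2))          # one variance scale per subject
    if (tot > 0) sc / tot else sc
  }))
  Xc <- sweep(Xc, 2L, colMeans(Xc))
  sv <- svd(Xc, nu = 0L)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank)
    stopf("concatenated matrix is rank deficient: k = %d requested but achievable rank is %d",
          k, rank)
  # whitened spatial variables: rows unit-variance across voxels
  Z <- sqrt(V) * t(sv$v[, seq_len(k), drop = FALSE])
  W <- with_seed(seed, .fastica_symm(Z))
  S <- W %*% Z
  lapply(seq_len(k), function(i) {
    m <- S[i, ]
    pk <- which.max(abs(m))
    if (m[pk] < 0) m <- -m
    m <- m / sqrt(sum(m^2))
    structure(list(map = m, hemisphere = hemisphere,
                   center_y = if (!is.null(coords)) coords[pk, "y"]
                   else NA_real_,
                   peak_voxel = pk,
                   grid_index = if (is.null(mask_index)) seq_len(V)
                   else mask_index),
              class = "ica_component")
  })
}

#' Match ICA components to expected axis centers across hemispheres
#'
#' Components are first paired across hemispheres (centers within
#' `pair_tol` of each other); components present in one hemisphere only are
#' excluded with a warning. Each expected axis center is then matched to
#' the nearest paired component center. Two expected centers claiming the
#' same component is an ambiguity error listing the candidates.
#'
#' @param components list of `ica_component`s from both hemispheres.
#' @param expected_centers data.frame with columns `label` (one of
#'   `"anterior"`, `"middle"`, `"posterior"`) and `y` (axis coordinate).
#' @param pair_tol maximum center distance for a cross-hemisphere pair
#'   (default 1: one voxel slice).
#' @return object of class `axis_assignment`: data.frame with one row per
#'   matched expected center (`label`, `y_expected`, `y_center`, `left`,
#'   `right` component indices), with unmatched expected centers reported
#'   in `attr(, "unmatched")` and the components in `attr(, "components")`.
#' @export
select_axis_components <- function(components, expected_centers,
                                   pair_tol = 1) {
  empty <- data.frame(label = character(0), y_expected = numeric(0),
                      y_center = numeric(0), left = integer(0),
                      right = integer(0))
  if (!length(components)) {
    return(structure(empty, unmatched = expected_centers,
                     components = components, class = c("axis_assignment",
                                                        "data.frame")))
  }
  hemi <- vapply(components, function(cp) cp$hemisphere, character(1))
  cy <- vapply(components, function(cp) as.numeric(cp$center_y), numeric(1))
  if (anyNA(cy)) stopf("components lack axis centers (supply coords to group_ica)")
  li <- which(hemi == "left"); ri <- which(hemi == "right")
  pairs <- list()
  used_r <- integer(0)
  for (i in li) {
    dists <- abs(cy[ri] - cy[i])
    j <- ri[which.min(dists)]
    if (length(j) && min(dists) <= pair_tol && !(j %in% used_r)) {
      pairs[[length(pairs) + 1L]] <- list(left = i, right = j,
                                          center = (cy[i] + cy[j]) / 2)
      used_r <- c(used_r, j)
    } else {
      warnf("component %d (left, center %g) has no right-hemisphere match; excluded",
            i, cy[i])
    }
  }
  lonely_r <- setdiff(ri, used_r)
  for (j in lonely_r)
    warnf("component %d (right, center %g) has no left-hemisphere match; excluded",
          j, cy[j])
  if (!length(pairs)) {
    return(structure(empty, unmatched = expected_centers,
                     components = components,
                     class = c("axis_assignment", "data.frame")))
  }
  centers <- vapply(pairs, `[[`, numeric(1), "center")
  claimed <- rep(NA_integer_, length(pairs))
  rows <- list(); unmatched <- list()
  for (e in seq_len(nrow(expected_centers))) {
    pi <- which.min(abs(centers - expected_centers$y[e]))
    if (!is.na(claimed[pi])) {
      prev <- expected_centers[claimed[pi], ]
      stopf(paste0("ambiguous assignment: expected centers %s (y = %g) and %s ",
                   "(y = %g) both match the component pair centered at y = %g"),
            prev$label, prev$y, expected_centers$label[e],
            expected_centers$y[e], centers[pi])
    }
    claimed[pi] <- e
    rows[[length(rows) + 1L]] <-
      data.frame(label = expected_centers$label[e],
                 y_expected = expected_centers$y[e],
                 y_center = centers[pi],
                 left = pairs[[pi]]$left, right = pairs[[pi]]$right)
  }
  structure(do.call(rbind, rows),
            unmatched = expected_centers[0, ], components = components,
            class = c("axis_assignment", "data.frame"))
}

#' Assemble anterior/middle/posterior ROIs from assigned components
#'
#' Each assigned component map is thresholded at
#' `|weight| >= threshold_sd x SD(map)`; a voxel claimed by several
#' components goes to the one with the larger |weight|, which keeps the
#' three ROIs mutually disjoint. Left/right components of a label are
#' merged into one bilateral ROI; the two middle and two posterior
#' components (when present) are merged into one mHC and one pHC ROI.
#'
#' @param assignment an `axis_assignment` from [select_axis_components()].
#' @param threshold_sd spatial threshold in map-SD units (default 2; 0
#'   makes the ROIs tile the whole mask).
#' @return object of class `axis_roi_set`: list with `masks` (named list
#'   `aHC`/`mHC`/`pHC` of voxel index vectors, in the grid space the
#'   components carry) and `provenance` (data.frame of contributing
#'   components and the threshold used).
#' @export
assemble_rois <- function(assignment, threshold_sd = 2) {
  stopifnot(inherits(assignment, "axis_assignment"))
  comps <- attr(assignment, "components")
  lab_map <- c(anterior = "aHC", middle = "mHC", posterior = "pHC")
  need <- c("anterior", "middle", "posterior")
  if (!all(need %in% assignment$label))
    stopf("assignment must cover all three labels; missing: %s",
          paste(setdiff(need, assignment$label), collapse = ", "))
  Vg <- max(vapply(comps, function(cp) max(cp$grid_index), numeric(1)))
  best_w <- rep(0, Vg); best_lab <- rep(NA_character_, Vg)
  prov <- list()
  for (r in seq_len(nrow(assignment))) {
    for (side in c("left", "right")) {
      ci <- assignment[[side]][r]
      m <- comps[[ci]]$map
      gi <- comps[[ci]]$grid_index
      thr <- threshold_sd * stats::sd(m)
      sel <- which(abs(m) >= thr)
      w <- abs(m[sel])
      gsel <- gi[sel]
      upd <- w > best_w[gsel]
      best_w[gsel[upd]] <- w[upd]
      best_lab[gsel[upd]] <- lab_map[[assignment$label[r]]]
      prov[[length(prov) + 1L]] <-
        data.frame(label = lab_map[[assignment$label[r]]], component = ci,
                   hemisphere = side, center_y = assignment$y_center[r],
                   threshold_sd = threshold_sd, n_voxels = length(sel))
    }
  }
  masks <- lapply(c(aHC = "aHC", mHC = "mHC", pHC = "pHC"), function(lb) {
    idx <- which(!is.na(best_lab) & best_lab == lb)
    if (!length(idx)) stopf("ROI %s is empty after thresholding", lb)
    idx
  })
  structure(list(masks = masks, provenance = do.call(rbind, prov)),
            class = "axis_roi_set")
}
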