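# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number, got %s", deparse(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Voxel coordinates (in voxel units, 1-based) for a 3-D grid, rows aligned
# with R's linear array indexing (first dimension fastest).
#' Voxel coordinate table for a 3-D grid
#'
#' Returns an integer matrix with one row per voxel of an `nx x ny x nz`
#' grid and columns `x`, `y`, `z` (1-based voxel indices), ordered to match
#' R's linear array indexing. The second (`y`) dimension is the convention
#' for the longitudinal axis throughout the package.
#'
#' @param grid integer vector of length 3, grid dimensions.
#' @return integer matrix, `prod(grid)` rows by 3 columns.
#' @export
grid_coords <- function(grid) {
  stopifnot(length(grid) == 3L, all(grid >= 1))
  out <- arrayInd(seq_len(prod(grid)), .dim = as.integer(grid))
  colnames(out) <- c("x", "y", "z")
  out
}

# Pearson correlation of each column of `x` (T x V) with vector `g`,
# returning 0 for zero-variance columns (callers count these for QC).
.col_cor <- function(x, g) {
  xt <- sweep(x, 2L, colMeans(x))
  gt <- g - mean(g)
  sg <- sqrt(sum(gt^2))
  sx <- sqrt(colSums(xt^2))
  num <- as.vector(crossprod(xt, gt))
  r <- numeric(length(sx))
  ok <- sx > 0 & sg > 0
  r[ok] <- num[ok] / (sx[ok] * sg)
  attr(r, "n_zero_var") <- sum(!ok)
  r
}

# Fisher z with the clipping rule used throughout: |r| capped at 1 - 1e-7
# before atanh so noiseless (r = +-1) inputs stay finite.
fisher_z <- function(r, clip = 1e-7) atanh(pmin(pmax(r, -1 + clip), 1 - clip))
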