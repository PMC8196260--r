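# Synthetic cohort generator: voxel time series with planted axis networks,
# behavioral/nuisance cohort tables, PET time-activity curves, and a
# machine-readable ground-truth record used by all recovery tests.

#' Generator settings for a synthetic axis cohort
#'
#' Builds the configuration consumed by [gen_cohort()]. The defaults state
#' the world the generator emulates: a 20 x 24 x 20 voxel grid whose second
#' (`y`) dimension is the hippocampal longitudinal axis, three bilateral
#' seed ROIs of 82/283/157 voxels ordered anterior -> posterior along that
#' axis, 170 volumes at TR = 2 s, and three latent network time courses
#' ("anterior" A, "posterior" P, "shared" S) drawn as smoothed Gaussian
#' processes. Anterior-seed voxels load on A, posterior-seed voxels on P,
#' middle-seed voxels on a subject-specific normalized A/P mixture, and all
#' seeds carry the shared course S. Three disjoint extra-hippocampal voxel
#' sets ("networks") carry A, P and S respectively, scaled by per-subject
#' adherence weights. Behavioral columns are stated linear functions of the
#' adherence weights plus Gaussian noise.
#'
#' Voxel noise SDs decrease anterior -> posterior and seed signal
#' amplitudes decrease with them, which together reproduce the empirically
#' observed anterior < middle < posterior ordering of seed-ROI temporal SNR.
#' Effect amplitudes are calibration knobs (no published values exist for
#' the latent generative process); they are fixed here once.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param grid 3-vector of grid dimensions; axis is dimension 2.
#' @param vox_mm voxel edge lengths in mm (used by cluster extraction).
#' @param n_timepoints volumes per subject.
#' @param tr repetition time, seconds.
#' @param seed_sizes bilateral voxel counts for the aHC/mHC/pHC seed ROIs.
#' @param network_sizes voxel counts of the planted anterior/posterior/shared
#'   networks outside the seeds.
#' @param seed_amp latent-course amplitude of each seed's own course.
#' @param shared_amp amplitude of the shared course S inside every seed.
#' @param network_amp amplitude multiplying the subject adherence weight in
#'   each network voxel set.
#' @param noise_sd_seed iid Gaussian voxel noise SD per seed ROI.
#' @param noise_sd_network,noise_sd_background voxel noise SDs elsewhere.
#' @param baseline additive signal baseline (gives the ROI signal a mean, so
#'   temporal SNR mean/SD is well defined).
#' @param gain_range range of per-voxel signal gains (uniform), drawn once
#'   per cohort and shared across subjects; voxel-level loading
#'   heterogeneity akin to partial-volume variation, without which spatial
#'   ICA on piecewise-constant maps is rotation-degenerate.
#' @param weight_sd SD of the subject adherence weights around 1.
#' @param coupling named couplings (correlation scale) of behavior to
#'   adherence weights: `memory_shared`, `memory_posterior`, `d2dr_shared`.
#' @param bp_mean,bp_sd mean and SD of true binding potential across subjects.
#' @param r1,k2 reference-tissue kinetic parameters for TAC generation
#'   (unitless R1; k2 per minute).
#' @param tac_noise_sd relative Gaussian frame noise for TACs (0 = none).
#' @param missing_rate missing-completely-at-random rate for trial scores.
#' @param ability_scale logit-scale slope linking the latent memory score to
#'   trial success probability.
#' @param smooth_sd temporal smoothing (in volumes) of the latent courses.
#' @return an object of class `axis_config` (a validated list).
#' @seealso [gen_cohort()], [gen_memory_trials()], [gen_tacs()]
#' @export
axis_config <- function(n_subjects = 40,
                        grid = c(20L, 24L, 20L),
                        vox_mm = c(3, 3, 3),
                        n_timepoints = 170L,
                        tr = 2,
                        seed_sizes = c(aHC = 82L, mHC = 283L, pHC = 157L),
                        network_sizes = c(anterior = 200L, posterior = 200L,
                                          shared = 150L),
                        seed_amp = c(aHC = 1.1, mHC = 0.95, pHC = 0.7),
                        shared_amp = 0.5,
                        network_amp = c(anterior = 1, posterior = 1, shared = 1),
                        noise_sd_seed = c(aHC = 3, mHC = 2, pHC = 1.5),
                        noise_sd_network = 1,
                        noise_sd_background = 1,
                        baseline = 1000,
                        gain_range = c(0.5, 1.5),
                        weight_sd = 0.25,
                        coupling = c(memory_shared = 0.5, memory_posterior = 0.3,
                                     d2dr_shared = 0.4),
                        bp_mean = 0.3, bp_sd = 0.05,
                        r1 = 1, k2 = 0.1,
                        tac_noise_sd = 0,
                        missing_rate = 0,
                        ability_scale = 0.8,
                        smooth_sd = 3) {
  cfg <- list(n_subjects = as.integer(n_subjects), grid = as.integer(grid),
              vox_mm = vox_mm, n_timepoints = as.integer(n_timepoints), tr = tr,
              seed_sizes = seed_sizes, network_sizes = network_sizes,
              seed_amp = seed_amp, shared_amp = shared_amp,
              network_amp = network_amp, noise_sd_seed = noise_sd_seed,
              noise_sd_network = noise_sd_network,
              noise_sd_background = noise_sd_background, baseline = baseline,
              gain_range = gain_range, weight_sd = weight_sd,
              coupling = coupling,
              bp_mean = bp_mean, bp_sd = bp_sd, r1 = r1, k2 = k2,
              tac_noise_sd = tac_noise_sd, missing_rate = missing_rate,
              ability_scale = ability_scale, smooth_sd = smooth_sd)
  class(cfg) <- "axis_config"
  validate_axis_config(cfg)
  cfg
}

validate_axis_config <- function(cfg) {
  if (cfg$n_subjects < 3L)
    stopf("n_subjects must be >= 3, got %d", cfg$n_subjects)
  if (length(cfg$grid) != 3L || any(cfg$grid < 4L))
    stopf("grid must be three dimensions, each >= 4")
  if (cfg$n_timepoints < 3L)
    stopf("n_timepoints must be >= 3, got %d", cfg$n_timepoints)
  if (any(cfg$seed_sizes < 1L))
    stopf("seed_sizes must be positive (empty seed masks are not allowed)")
  if (any(cfg$network_sizes < 1L))
    stopf("network_sizes must be positive (empty network masks are not allowed)")
  sds <- c(cfg$noise_sd_seed, noise_sd_network = cfg$noise_sd_network,
           noise_sd_background = cfg$noise_sd_background,
           weight_sd = cfg$weight_sd, bp_sd = cfg$bp_sd,
           tac_noise_sd = cfg$tac_noise_sd)
  bad <- names(sds)[sds < 0]
  if (length(bad))
    stopf("negative SDs are not allowed: %s", paste(bad, collapse = ", "))
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stopf("missing_rate must lie in [0, 1], got %g", cfg$missing_rate)
  if (cfg$bp_mean < 0) stopf("bp_mean must be >= 0, got %g", cfg$bp_mean)
  if (length(cfg$gain_range) != 2L || any(cfg$gain_range <= 0) ||
      diff(cfg$gain_range) < 0)
    stopf("gain_range must be a positive increasing pair")
  invisible(cfg)
}

# --- mask layout ------------------------------------------------------------

# Deterministic layout of seed ROIs (inside a central "hippocampal" slab of
# each hemisphere, ordered along y) and the three planted network voxel sets
# (outside the slab, in the matching y bands). All sets are disjoint.
build_masks <- function(grid, seed_sizes, network_sizes) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  coords <- grid_coords(grid)
  xl <- 1:floor(nx / 2)
  xr <- (floor(nx / 2) + 1):nx
  mid_band <- function(v) {
    q <- floor(length(v) / 4)
    v[(q + 1):(length(v) - q)]
  }
  hip_x <- list(left = mid_band(xl), right = mid_band(xr))
  hip_z <- mid_band(1:nz)
  y_bands <- list(aHC = max(1, ceiling(0.05 * ny)):floor(0.30 * ny),
                  mHC = ceiling(0.35 * ny):floor(0.60 * ny),
                  pHC = ceiling(0.65 * ny):floor(0.95 * ny))

  pick <- function(xs, ys, zs, n) {
    idx <- which(coords[, "x"] %in% xs & coords[, "y"] %in% ys &
                   coords[, "z"] %in% zs)
    if (length(idx) < n)
      stopf("grid too small: need %d voxels in band, have %d", n, length(idx))
    ord <- order(coords[idx, "y"], coords[idx, "z"], coords[idx, "x"])
    idx[ord][seq_len(n)]
  }

  seeds <- list(); seeds_hemi <- list(left = list(), right = list())
  for (s in c("aHC", "mHC", "pHC")) {
    n_tot <- seed_sizes[[s]]
    nl <- ceiling(n_tot / 2); nr <- n_tot - nl
    li <- pick(hip_x$left, y_bands[[s]], hip_z, nl)
    ri <- pick(hip_x$right, y_bands[[s]], hip_z, nr)
    seeds_hemi$left[[s]] <- li
    seeds_hemi$right[[s]] <- ri
    seeds[[s]] <- sort(c(li, ri))
  }

  out_z <- setdiff(1:nz, hip_z)
  nets <- list(
    anterior = pick(1:nx, y_bands$aHC, out_z, network_sizes[["anterior"]]),
    shared = pick(1:nx, y_bands$mHC, out_z, network_sizes[["shared"]]),
    posterior = pick(1:nx, y_bands$pHC, out_z, network_sizes[["posterior"]]))

  all_idx <- c(unlist(seeds), unlist(nets))
  if (anyDuplicated(all_idx))
    stopf("internal error: mask sets overlap")
  list(seeds = seeds, seeds_hemi = seeds_hemi, networks = nets,
       background = setdiff(seq_len(prod(grid)), all_idx),
       hippocampus = sort(unlist(seeds)), y_bands = y_bands)
}

# Smoothed, standardized Gaussian-process time course.
.gp_course <- function(n_t, smooth_sd) {
  x <- stats::rnorm(n_t + 6 * ceiling(smooth_sd))
  if (smooth_sd > 0) {
    k <- stats::dnorm(seq(-3 * smooth_sd, 3 * smooth_sd), sd = smooth_sd)
    x <- stats::filter(x, k / sum(k), sides = 2)
    x <- x[!is.na(x)]
  }
  x <- x[seq_len(n_t)]
  as.vector(scale(x))
}

# --- main generator ---------------------------------------------------------

#' Generate a seeded synthetic cohort
#'
#' Produces subject voxel time series with planted axis networks, a cohort
#' table (sex, mean FD, per-trial memory scores, latent memory and D2DR
#' columns, ICV, ROI volumes, perfusion), one PET TAC pair per subject, and
#' a [`truth_record`] holding every planted parameter a recovery test needs.
#' Identical `(config, seed)` reproduces the cohort bit for bit.
#'
#' @param config an [axis_config()].
#' @param seed integer RNG seed.
#' @param keep_series if `FALSE`, drop the voxel series (cohort table, TACs
#'   and truth only) to save memory.
#' @return an object of class `synthetic_cohort`: list with elements
#'   `series` (list of T x V matrices, one per subject; `attr(,"grid")` set),
#'   `cohort` (data.frame), `tacs` (list of `(target, reference)` pairs),
#'   and `truth` (class `truth_record`).
#' @export
gen_cohort <- function(config = axis_config(), seed = 1L, keep_series = TRUE) {
  stopifnot(inherits(config, "axis_config"))
  validate_axis_config(config)
  with_seed(seed, {
    n <- config$n_subjects
    V <- prod(config$grid)
    Tt <- config$n_timepoints
    masks <- build_masks(config$grid, config$seed_sizes, config$network_sizes)

    # subject adherence weights and the latent behavior model
    w_ant <- stats::rnorm(n, 1, config$weight_sd)
    w_post <- stats::rnorm(n, 1, config$weight_sd)
    w_shared <- stats::rnorm(n, 1, config$weight_sd)
    mix <- stats::rbeta(n, 2, 2)  # middle-seed anterior fraction
    zs <- function(w) if (config$weight_sd > 0) (w - 1) / config$weight_sd
      else rep(0, n)
    cms <- config$coupling[["memory_shared"]]
    cmp <- config$coupling[["memory_posterior"]]
    cds <- config$coupling[["d2dr_shared"]]
    res_m <- sqrt(max(0, 1 - cms^2 - cmp^2))
    res_d <- sqrt(max(0, 1 - cds^2))
    memory_z <- cms * zs(w_shared) + cmp * zs(w_post) + res_m * stats::rnorm(n)
    d2dr_z <- cds * zs(w_shared) + res_d * stats::rnorm(n)
    bp_true <- pmax(0, config$bp_mean + config$bp_sd * d2dr_z)

    # per-voxel signal gains (shared across subjects) and noise SDs
    gains <- stats::runif(V, config$gain_range[1], config$gain_range[2])
    sigma <- rep(config$noise_sd_background, V)
    sigma[masks$seeds$aHC] <- config$noise_sd_seed[["aHC"]]
    sigma[masks$seeds$mHC] <- config$noise_sd_seed[["mHC"]]
    sigma[masks$seeds$pHC] <- config$noise_sd_seed[["pHC"]]
    for (nm in names(masks$networks))
      sigma[masks$networks[[nm]]] <- config$noise_sd_network

    loadings_for <- function(w_a, w_p, w_s, m) {
      B <- matrix(0, V, 3)
      nrm <- sqrt(m^2 + (1 - m)^2)
      B[masks$seeds$aHC, 1] <- config$seed_amp[["aHC"]]
      B[masks$seeds$mHC, 1] <- config$seed_amp[["mHC"]] * m / nrm
      B[masks$seeds$mHC, 2] <- config$seed_amp[["mHC"]] * (1 - m) / nrm
      B[masks$seeds$pHC, 2] <- config$seed_amp[["pHC"]]
      B[unlist(masks$seeds), 3] <- config$shared_amp
      B[masks$networks$anterior, 1] <- config$network_amp[["anterior"]] * w_a
      B[masks$networks$posterior, 2] <- config$network_amp[["posterior"]] * w_p
      B[masks$networks$shared, 3] <- config$network_amp[["shared"]] * w_s
      B * gains
    }

    series <- if (keep_series) vector("list", n) else NULL
    for (i in seq_len(n)) {
      FF <- cbind(.gp_course(Tt, config$smooth_sd),
                  .gp_course(Tt, config$smooth_sd),
                  .gp_course(Tt, config$smooth_sd))
      B <- loadings_for(w_ant[i], w_post[i], w_shared[i], mix[i])
      eps <- matrix(stats::rnorm(Tt * V), Tt, V) *
        matrix(sigma, Tt, V, byrow = TRUE)
      dat <- FF %*% t(B) + eps + config$baseline
      if (keep_series) {
        attr(dat, "grid") <- config$grid
        series[[i]] <- dat
      }
    }

    trials <- gen_memory_trials(
      memory_config(n_subjects = n,
                    ability = config$ability_scale * memory_z,
                    missing_rate = config$missing_rate),
      seed = floor(stats::runif(1, 1, 2^30)))
    tac_seeds <- floor(stats::runif(n, 1, 2^30))

    # nuisance / volumetric / perfusion columns (means echo typical cohort
    # values; SDs are desk-scale choices)
    sex <- factor(ifelse(stats::runif(n) < 0.54, "M", "F"), levels = c("F", "M"))
    mean_fd <- pmin(pmax(stats::rnorm(n, 0.19, 0.09), 0.05), 0.45)
    icv <- stats::rnorm(n, 1.5e6, 1.2e5)
    z_icv <- as.vector(scale(icv))
    base_vol <- c(aHC = 522, mHC = 2178, pHC = 1228)
    vol_sd <- c(aHC = 79, mHC = 257, pHC = 146)
    vols <- sapply(c("aHC", "mHC", "pHC"), function(r)
      base_vol[[r]] + 0.5 * vol_sd[[r]] * z_icv +
        sqrt(0.75) * vol_sd[[r]] * stats::rnorm(n))
    perf_mean <- c(aHC = 40.31, mHC = 42.91, pHC = 41.84)
    perf <- sapply(c("aHC", "mHC", "pHC"), function(r)
      perf_mean[[r]] + 3 * stats::rnorm(n))

    cohort <- data.frame(subject = sprintf("s%03d", seq_len(n)), sex = sex,
                         mean_fd = mean_fd, stringsAsFactors = FALSE)
    cohort <- cbind(cohort, trials$scores)
    cohort$memory <- 50 + 10 * memory_z
    cohort$d2dr <- bp_true
    cohort$icv <- icv
    cohort$vol_aHC <- vols[, "aHC"]; cohort$vol_mHC <- vols[, "mHC"]
    cohort$vol_pHC <- vols[, "pHC"]
    cohort$perf_aHC <- perf[, "aHC"]; cohort$perf_mHC <- perf[, "mHC"]
    cohort$perf_pHC <- perf[, "pHC"]

    tacs <- lapply(seq_len(n), function(i)
      gen_tacs(bp_true[i], r1 = config$r1, k2 = config$k2,
               noise_sd = config$tac_noise_sd,
               seed = tac_seeds[i]))

    truth <- make_truth_record(config, masks,
                               weights = data.frame(w_ant = w_ant,
                                                    w_post = w_post,
                                                    w_shared = w_shared,
                                                    mix = mix),
                               memory_z = memory_z, d2dr_z = d2dr_z,
                               bp_true = bp_true, sigma = sigma,
                               gains = gains, trial_truth = trials$truth)

    structure(list(series = series, cohort = cohort, tacs = tacs,
                   truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

# Ground-truth record: planted parameters plus analytically expected
# (population-level, at mean weights) seed-connectivity z-maps and their
# anterior-minus-posterior contrast, used by recovery tests.
make_truth_record <- function(config, masks, weights, memory_z, d2dr_z,
                              bp_true, sigma, gains, trial_truth) {
  V <- prod(config$grid)
  B0 <- matrix(0, V, 3)
  nrm <- sqrt(0.5)  # mixture norm at population mix = 0.5
  B0[masks$seeds$aHC, 1] <- config$seed_amp[["aHC"]]
  B0[masks$seeds$mHC, 1] <- config$seed_amp[["mHC"]] * 0.5 / nrm
  B0[masks$seeds$mHC, 2] <- config$seed_amp[["mHC"]] * 0.5 / nrm
  B0[masks$seeds$pHC, 2] <- config$seed_amp[["pHC"]]
  B0[unlist(masks$seeds), 3] <- config$shared_amp
  B0[masks$networks$anterior, 1] <- config$network_amp[["anterior"]]
  B0[masks$networks$posterior, 2] <- config$network_amp[["posterior"]]
  B0[masks$networks$shared, 3] <- config$network_amp[["shared"]]
  B0 <- B0 * gains

  zmaps <- sapply(c("aHC", "mHC", "pHC"), function(s) {
    idx <- masks$seeds[[s]]
    g <- colMeans(B0[idx, , drop = FALSE])  # seed-mean course coefficients
    var_g <- sum(g^2) + sigma[idx[1]]^2 / length(idx)
    cov <- as.vector(B0 %*% g)
    cov[idx] <- cov[idx] + sigma[idx]^2 / length(idx)
    var_v <- rowSums(B0^2) + sigma^2
    r <- ifelse(var_v > 0 & var_g > 0, cov / sqrt(var_v * var_g), 0)
    fisher_z(r)
  })
  contrast <- zmaps[, "aHC"] - zmaps[, "pHC"]
  contrast <- contrast / sqrt(sum(contrast^2))

  structure(list(weights = weights, coupling = config$coupling,
                 memory_z = memory_z, d2dr_z = d2dr_z, bp_true = bp_true,
                 masks = masks, noise_sd = sigma, gains = gains,
                 expected_zmaps = zmaps, contrast_map = contrast,
                 trial_truth = trial_truth, grid = config$grid,
                 vox_mm = config$vox_mm),
            class = "truth_record")
}

# --- memory trials ----------------------------------------------------------

#' Settings for the episodic-memory trial generator
#'
#' Defaults mirror the three-task battery: word recall (16 items, 2 trials,
#' maximum 32), number-word recall (8 items, 2 trials, maximum 16), and
#' object-location recall (12 items, 2 trials, maximum 24).
#'
#' @param n_subjects number of subjects.
#' @param items named per-trial item counts.
#' @param trials named trial counts per task.
#' @param ability per-subject latent ability on the logit scale (scalar or
#'   length-`n_subjects`); 0 is average.
#' @param p_base baseline success probability at ability 0.
#' @param missing_rate missing-completely-at-random rate in [0, 1].
#' @return a list of class `memory_config`.
#' @export
memory_config <- function(n_subjects,
                          items = c(word = 16L, numword = 8L, objloc = 12L),
                          trials = c(word = 2L, numword = 2L, objloc = 2L),
                          ability = 0, p_base = 0.6, missing_rate = 0) {
  if (missing_rate < 0 || missing_rate > 1)
    stopf("missing_rate must lie in [0, 1], got %g", missing_rate)
  if (any(items < 1L) || any(trials < 1L))
    stopf("items and trials must be positive")
  structure(list(n_subjects = as.integer(n_subjects), items = items,
                 trials = trials, ability = ability, p_base = p_base,
                 missing_rate = missing_rate),
            class = "memory_config")
}

#' Generate per-trial episodic-memory task scores
#'
#' Trial scores are binomial draws: subject `i` answers each of a task's
#' items correctly with probability `plogis(qlogis(p_base) + ability_i)`.
#' Task sums are therefore bounded by the task maxima (32/16/24 with the
#' default battery). Optional missingness is applied completely at random.
#'
#' @param config a [memory_config()].
#' @param seed RNG seed.
#' @return list with `scores` (data.frame of trial columns named
#'   `<task>_t<j>`) and `truth` (ability, success probabilities, planted
#'   missing entries).
#' @export
gen_memory_trials <- function(config, seed = 1L) {
  stopifnot(inherits(config, "memory_config"))
  n <- config$n_subjects
  ability <- rep_len(config$ability, n)
  p <- stats::plogis(stats::qlogis(config$p_base) + ability)
  with_seed(seed, {
    cols <- list()
    for (task in names(config$items)) {
      for (j in seq_len(config$trials[[task]])) {
        cols[[sprintf("%s_t%d", task, j)]] <-
          stats::rbinom(n, config$items[[task]], p)
      }
    }
    scores <- as.data.frame(cols)
    n_cells <- n * ncol(scores)
    miss <- which(stats::runif(n_cells) < config$missing_rate)
    if (length(miss)) {
      m <- as.matrix(scores)
      m[miss] <- NA_integer_
      scores <- as.data.frame(m)
    }
    list(scores = scores,
         truth = list(ability = ability, p = p, missing_cells = miss,
                      items = config$items, trials = config$trials))
  })
}

# --- PET time-activity curves ----------------------------------------------

#' Default 18-frame / 55-minute PET frame schedule
#'
#' Frame start/end times in minutes: 4 x 1, 4 x 2, 5 x 3, 4 x 5 and 1 x 8
#' minute frames covering 0-55 min.
#'
#' @return data.frame with columns `start`, `end`, `mid` (minutes).
#' @export
default_frame_schedule <- function() {
  durs <- c(rep(1, 4), rep(2, 4), rep(3, 5), rep(5, 4), 8)
  end <- cumsum(durs)
  data.frame(start = end - durs, end = end, mid = end - durs / 2)
}

#' Construct a time-activity curve
#'
#' @param start,end frame start/end times in minutes (non-overlapping,
#'   strictly increasing).
#' @param activity mean activity concentration per frame (>= 0 for real
#'   tracer data; noisy synthetic frames may dip below zero and are
#'   accepted with a warning).
#' @return object of class `tac`: data.frame with `start`, `end`, `mid`,
#'   `activity`.
#' @export
tac <- function(start, end, activity) {
  if (length(start) != length(end) || length(end) != length(activity))
    stopf("start, end and activity must have equal length")
  if (any(end <= start) || any(diff(start) <= 0) ||
      any(start[-1] < end[-length(end)] - 1e-9))
    stopf("frames must be non-overlapping and strictly increasing")
  out <- data.frame(start = start, end = end, mid = (start + end) / 2,
                    activity = activity)
  class(out) <- c("tac", "data.frame")
  out
}

# Reference-region input: gamma-variate shape typical of a bolus tracer.
.ref_activity <- function(t) 30 * (t / 4)^1.2 * exp(1.2 * (1 - t / 4))

#' Simulate a reference-tissue TAC pair
#'
#' The target region follows the one-tissue reference-tissue kinetic model
#' \deqn{C_t(t) = R_1 C_{ref}(t) + (k_2 - R_1 k_2 / (1 + BP))
#'       \int_0^t C_{ref}(u) e^{-k_2 (t-u)/(1+BP)} du,}
#' evaluated on a fine time grid and averaged within frames. Optional
#' relative Gaussian frame noise is added to both curves.
#'
#' @param bp_true true binding potential (unitless, >= 0).
#' @param r1 delivery ratio R1 (unitless).
#' @param k2 reference efflux constant, per minute.
#' @param ref_curve optional [tac()] supplying the reference activity; by
#'   default a smooth gamma-variate bolus curve is used.
#' @param schedule frame schedule data.frame (`start`, `end` in minutes);
#'   default [default_frame_schedule()].
#' @param noise_sd relative SD of Gaussian frame noise (0 = noiseless).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return list with elements `target` and `reference`, both [tac()]s.
#' @export
gen_tacs <- function(bp_true, r1 = 1, k2 = 0.1, ref_curve = NULL,
                     schedule = default_frame_schedule(), noise_sd = 0,
                     seed = 1L) {
  if (bp_true < 0) stopf("bp_true must be >= 0, got %g", bp_true)
  if (any(diff(schedule$start) <= 0) || any(schedule$end <= schedule$start))
    stopf("frame schedule must be strictly increasing")
  t_end <- max(schedule$end)
  dt <- 0.01
  tg <- seq(0, t_end, by = dt)
  cref <- if (is.null(ref_curve)) {
    .ref_activity(tg)
  } else {
    stopifnot(inherits(ref_curve, "tac"))
    stats::approx(c(0, ref_curve$mid), c(0, ref_curve$activity), xout = tg,
                  rule = 2)$y
  }
  lam <- k2 / (1 + bp_true)
  b <- k2 - r1 * lam
  # exponential-trapezoid recursion for the convolution integral
  conv <- numeric(length(tg))
  ek <- exp(-lam * dt)
  for (i in 2:length(tg))
    conv[i] <- conv[i - 1] * ek + dt * (cref[i] + cref[i - 1] * ek) / 2
  ct <- r1 * cref + b * conv

  frame_mean <- function(v) {
    vapply(seq_len(nrow(schedule)), function(i) {
      sel <- tg >= schedule$start[i] & tg <= schedule$end[i]
      mean(v[sel])
    }, numeric(1))
  }
  tgt <- frame_mean(ct); ref <- frame_mean(cref)
  if (noise_sd > 0) {
    with_seed(seed, {
      tgt <- tgt * (1 + noise_sd * stats::rnorm(length(tgt)))
      ref <- ref * (1 + noise_sd * stats::rnorm(length(ref)))
    })
  }
  list(target = tac(schedule$start, schedule$end, tgt),
       reference = tac(schedule$start, schedule$end, ref))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, grid %s, %d volumes\n",
              x$config$n_subjects, paste(x$config$grid, collapse = "x"),
              x$config$n_timepoints))
  invisible(x)
}
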