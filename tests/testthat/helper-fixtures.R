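# Shared fixtures: desk-scale generator configurations and small utilities.

# Reduced grid keeps module tests fast; seed-size asymmetry mirrors the
# default configuration.
small_cfg <- function(n_subjects = 8, n_timepoints = 60, ...) {
  axis_config(n_subjects = n_subjects, grid = c(10, 12, 10),
              n_timepoints = n_timepoints,
              seed_sizes = c(aHC = 10L, mHC = 20L, pHC = 14L),
              network_sizes = c(anterior = 20L, posterior = 20L,
                                shared = 15L),
              ...)
}

# Larger hippocampus for parcellation tests (ICA needs spatial samples).
parcel_cfg <- function(n_subjects = 12, ...) {
  axis_config(n_subjects = n_subjects, grid = c(18, 20, 18),
              n_timepoints = 100,
              seed_sizes = c(aHC = 100L, mHC = 250L, pHC = 150L),
              network_sizes = c(anterior = 30L, posterior = 30L,
                                shared = 20L),
              ...)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A fake ICA component for selection/assembly tests.
fake_component <- function(map, hemisphere, center_y,
                           grid_index = seq_along(map)) {
  structure(list(map = map / sqrt(sum(map^2)), hemisphere = hemisphere,
                 center_y = center_y, peak_voxel = which.max(abs(map)),
                 grid_index = grid_index),
            class = "ica_component")
}
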