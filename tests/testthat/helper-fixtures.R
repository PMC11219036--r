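# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Small noisy experiment reused across segmentation/tracking/pipeline tests.
small_dataset <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(fov_rows = 300, fov_cols = 300, n_frames = 20,
                      n_cells = 8, stim_frame = 5,
                      pillar_centers = rbind(c(80, 80), c(220, 220)),
                      seed = 7)
    fixture_env$small <- simulate_experiment(cfg)
  }
  fixture_env$small
}

# The full-size default experiment (50 cells, 120 frames): built once and
# shared between the acceptance suite and the segmentation-recovery check.
default_dataset <- function() {
  if (is.null(fixture_env$default)) {
    fixture_env$default <- simulate_experiment(sim_config(seed = 11))
  }
  fixture_env$default
}

# Noise-free, flatfield-free variant for oracle-grade checks.
clean_dataset <- function() {
  if (is.null(fixture_env$clean)) {
    cfg <- sim_config(fov_rows = 300, fov_cols = 300, n_frames = 6,
                      n_cells = 6, stim_frame = 2, noise_sd = 0,
                      flatfield_amplitude = 0,
                      pillar_centers = rbind(c(80, 80), c(220, 220)),
                      seed = 3)
    fixture_env$clean <- simulate_experiment(cfg)
  }
  fixture_env$clean
}

# Binary dilation by a disc of the given radius.
dilate01 <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask * 1,
                  EBImage::makeBrush(2 * radius + 1, "disc")) > 0.5
}

# Match measured cell-frames to ground-truth cells by centroid proximity.
match_to_truth <- function(result, dataset, max_dist = 8) {
  merged <- merge(result$volumes,
                  result$tracks[, c("track_id", "frame", "x_um", "y_um")],
                  by = c("track_id", "frame"))
  truth <- dataset$truth$cells
  merged$cell_id <- NA_integer_
  merged$true_volume_um3 <- NA_real_
  for (k in seq_len(nrow(merged))) {
    tt <- truth[truth$frame == merged$frame[k], , drop = FALSE]
    d <- sqrt((tt$x_um - merged$x_um[k])^2 + (tt$y_um - merged$y_um[k])^2)
    j <- which.min(d)
    if (length(j) && d[j] < max_dist) {
      merged$cell_id[k] <- tt$cell_id[j]
      merged$true_volume_um3[k] <- tt$true_volume_um3[j]
    }
  }
  merged
}

# Footprint crop of one truth cell as a full-frame logical mask.
truth_footprint_mask <- function(dataset, cell_id, frame0) {
  cr <- dataset$truth$footprints[[cell_id]][[frame0 + 1L]]
  m <- matrix(FALSE, dataset$config$fov_rows, dataset$config$fov_cols)
  if (!is.null(cr)) {
    sub <- m[cr$rows, cr$cols, drop = FALSE]
    sub[cr$h > 0] <- TRUE
    m[cr$rows, cr$cols] <- sub
  }
  m
}
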