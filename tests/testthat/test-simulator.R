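# Synthetic experiment generator: schedules, tracks, rendering, bookkeeping.

test_that("volume schedule reproduces the biphasic program", {
  vp <- sim_config()$volume_program
  vp0 <- modifyList(vp, list(fluct_amplitude = 0))
  # baseline is exactly 1 before stimulation
  expect_identical(volume_schedule(c(-300, -10, -0.001), vp0), rep(1, 3))
  # spreading dip: minimum over the dip window sits at 1 - dip_fraction,
  # within the 5-8% loss band
  tt <- seq(0, vp$dip_duration, by = 0.5)
  mn <- min(volume_schedule(tt, vp0))
  expect_gte(mn, 0.92)
  expect_lte(mn, 0.95)
  expect_equal(mn, 1 - vp$dip_fraction, tolerance = 1e-9)
  # saturates at 1 + swell_fraction
  expect_equal(volume_schedule(50 * vp0$swell_tau, vp0), 1.15,
               tolerance = 0.01)
  # monotone in swell_fraction at late times
  late <- vapply(c(0.05, 0.1, 0.15, 0.25), function(s)
    volume_schedule(3000, modifyList(vp0, list(swell_fraction = s))),
    numeric(1))
  expect_true(all(diff(late) > 0))
})

test_that("persistent random walk respects speed, turning and boundaries", {
  # zero speed: fixed point
  p <- simulate_track(10, 0, turn_sd = 0.3, start = c(5, 5), seed = 1)
  expect_true(all(p[, 1] == 5 & p[, 2] == 5))
  # zero turning: collinear, exact 1 um steps at 6 um/min and 10 s frames
  p <- simulate_track(20, 6, turn_sd = 0, dt = 10,
                      arena = c(0, 500, 0, 500), start = c(100, 100),
                      heading0 = pi / 5, seed = 1)
  steps <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  expect_equal(steps, rep(1, 19), tolerance = 1e-12)
  cross <- (p[3:20, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]) -
    (p[3:20, 2] - p[1, 2]) * (p[2, 1] - p[1, 1])
  expect_equal(max(abs(cross)), 0, tolerance = 1e-9)
  # reflection keeps the walk inside the arena
  p <- simulate_track(500, 30, turn_sd = 0.1, dt = 10,
                      arena = c(0, 40, 0, 40), start = c(20, 20), seed = 2)
  expect_true(all(p >= 0 & p <= 40))
  expect_error(simulate_track(5, -1, 0.1), "speed")
})

test_that("rendering follows the dye-exclusion model exactly", {
  cfg <- sim_config(fov_rows = 120, fov_cols = 120, noise_sd = 0,
                    flatfield_amplitude = 0, n_cells = 0,
                    pillar_centers = rbind(c(30, 30)), pillar_radius = 8)
  # empty chamber: darkfield + alpha * h off-pillar, darkfield on pillar
  fr <- render_frame(list(), cfg)
  pil <- pillar_mask_from_config(cfg)
  expect_equal(unique(fr$fxm[!pil]),
               cfg$darkfield_level + cfg$alpha_true * cfg$chamber_height)
  expect_equal(unique(fr$fxm[pil]), cfg$darkfield_level)
  # full-height plug: complete dye exclusion, pillar-equivalent signal
  plug <- matrix(0, 120, 120)
  plug[50:59, 50:59] <- cfg$chamber_height
  fr <- render_frame(list(plug), cfg)
  expect_equal(unique(as.vector(fr$fxm[50:59, 50:59])),
               cfg$darkfield_level)
  # dome: per-pixel inversion recovers the height map to machine precision
  ds <- clean_dataset()
  cr <- ds$truth$footprints[[1]][[1]]
  cfg0 <- ds$config
  rec <- (cfg0$darkfield_level +
            cfg0$alpha_true * cfg0$chamber_height -
            ds$fxm[[1]][cr$rows, cr$cols]) / cfg0$alpha_true
  expect_equal(max(abs(rec - cr$h)), 0, tolerance = 1e-9)
  # over-tall cells are rejected
  tall <- matrix(0, 120, 120); tall[60, 60] <- cfg$chamber_height + 1
  expect_error(render_frame(list(tall), cfg), "chamber_height")
})

test_that("experiments are deterministic with exact volume bookkeeping", {
  ds <- small_dataset()
  ds2 <- simulate_experiment(ds$config)
  expect_identical(ds, ds2)
  # ground truth is the rasterised pixel sum, exactly
  cfg <- ds$config
  for (probe in list(c(1, 1), c(4, 10), c(8, 20))) {
    cr <- ds$truth$footprints[[probe[1]]][[probe[2]]]
    v <- ds$truth$cells$true_volume_um3[
      ds$truth$cells$cell_id == probe[1] &
        ds$truth$cells$frame == probe[2] - 1]
    expect_identical(v, cfg$pixel_size^2 * sum(cr$h))
  }
  # stacks share shape, timestamps strictly increasing at frame_interval
  expect_true(all(vapply(c(ds$fxm, ds$nuclear, ds$cyto),
                         function(m) all(dim(m) == c(300, 300)),
                         logical(1))))
  expect_equal(diff(ds$timestamps),
               rep(cfg$frame_interval, cfg$n_frames - 1))
  # footprints never overlap pillars
  for (i in seq_len(cfg$n_cells)) {
    cr <- ds$truth$footprints[[i]][[10]]
    sub <- ds$pillar_mask[cr$rows, cr$cols]
    expect_false(any(sub & cr$h > 0))
  }
})

test_that("empty experiments produce background-only stacks", {
  cfg <- sim_config(fov_rows = 100, fov_cols = 100, n_frames = 3,
                    n_cells = 0, stim_frame = 1, noise_sd = 0,
                    pillar_centers = NULL, seed = 5)
  ds <- simulate_experiment(cfg)
  expect_identical(nrow(ds$truth$cells), 0L)
  bg <- cfg$darkfield_level +
    ds$flatfield * cfg$alpha_true * cfg$chamber_height
  expect_equal(ds$fxm[[2]], bg, tolerance = 1e-12)
})

test_that("per-frame total true volume matches an independent summation", {
  ds <- small_dataset()
  cfg <- ds$config
  for (f in c(1, 12)) {
    total <- sum(vapply(seq_len(cfg$n_cells), function(i) {
      cr <- ds$truth$footprints[[i]][[f]]
      if (is.null(cr)) 0 else sum(cr$h)
    }, numeric(1))) * cfg$pixel_size^2
    expect_equal(total,
                 sum(ds$truth$cells$true_volume_um3[
                   ds$truth$cells$frame == f - 1]),
                 tolerance = 1e-10)
  }
})

test_that("gradient count simulation histograms densities correctly", {
  cal <- fit_density_calibration(c(1.3419, 1.3467), c(1.045, 1.074))
  edges <- seq(1.040, 1.070, by = 0.003)
  # vanishing spread: every cell lands in the fraction holding the median
  g <- simulate_gradient_counts(1.0555, 1.0555, 1e-9, 500, edges, cal,
                                seed = 1)
  expect_equal(sum(g$count_a > 0), 1)
  expect_equal(g$count_a[g$count_a > 0], 500)
  # identical medians give a near-zero recovered shift
  g2 <- simulate_gradient_counts(1.055, 1.055, 0.003, 20000, edges, cal,
                                 seed = 2)
  prof <- gradient_profile(cbind(g2$count_a, g2$count_b), g2$ri, cal)
  expect_lt(abs(prof$delta_rho), 2e-4)
  expect_error(simulate_gradient_counts(1.05, 1.05, 0, 10, edges, cal), "sd")
  expect_error(simulate_gradient_counts(1.05, 1.05, 0.003, 10,
                                        c(1.05, 1.04), cal),
               "increasing")
})

test_that("coulter run simulation follows the programmed kinetics", {
  # flat kinetics: all medians equal within sampling error
  run <- simulate_coulter_run(swell_fraction = 0, n_timepoints = 6,
                              n_per_timepoint = 4000, seed = 1)
  med <- vapply(run$samples, median, numeric(1))
  expect_lt(diff(range(med)) / med[1], 0.02)
  # single draw per timepoint passes through unchanged
  run1 <- simulate_coulter_run(n_timepoints = 4, n_per_timepoint = 1,
                               seed = 2)
  expect_true(all(lengths(run1$samples) == 1))
})
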