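# Density-gradient and Coulter-counter quantifications.

test_that("two-point density calibration reproduces the anchors exactly", {
  cal <- fit_density_calibration(c(1.3419, 1.3467), c(1.045, 1.074))
  expect_equal(ri_to_density(cal, 1.3419), 1.045, tolerance = 1e-12)
  expect_equal(ri_to_density(cal, 1.3467), 1.074, tolerance = 1e-12)
  # midpoint prediction: linear interpolation arithmetic
  expect_equal(ri_to_density(cal, 1.3443), 1.0595, tolerance = 1e-9)
  # round trip through the inverse is the identity
  d <- c(1.04, 1.055, 1.07)
  expect_equal(ri_to_density(cal, density_to_ri(cal, d)), d,
               tolerance = 1e-12)
  expect_error(fit_density_calibration(c(1.34, 1.34), c(1, 2)), "distinct")
  expect_error(fit_density_calibration(1.34, 1.05))
})

test_that("weighted-median densities interpolate within the median fraction", {
  cal <- fit_density_calibration(c(1.3419, 1.3467), c(1.045, 1.074))
  dens <- seq(1.040, 1.070, by = 0.005)
  ri <- density_to_ri(cal, dens)
  # all counts in one fraction: median is that fraction's density
  ct <- rep(0, 7); ct[4] <- 100
  p1 <- gradient_profile(cbind(ct), ri, cal)
  expect_equal(unname(p1$median_density[1]), dens[4], tolerance = 1e-12)
  # symmetric counts about a central fraction
  ct2 <- c(1, 5, 20, 40, 20, 5, 1)
  p2 <- gradient_profile(cbind(ct2), ri, cal)
  expect_equal(unname(p2$median_density[1]), dens[4], tolerance = 1e-12)
  # adding counts to denser fractions never decreases the median
  meds <- vapply(0:40, function(extra) {
    ct3 <- ct2; ct3[6] <- ct3[6] + extra
    unname(gradient_profile(cbind(ct3), ri, cal)$median_density[1])
  }, numeric(1))
  expect_true(all(diff(meds) >= -1e-12))
  expect_error(gradient_profile(cbind(rep(0, 7)), ri, cal), "all-zero")
  expect_error(gradient_profile(cbind(ct2), rev(ri), cal), "monotonic")
})

test_that("the simulated stimulation shift is recovered at -0.005 g/mL", {
  cal <- fit_density_calibration(c(1.3419, 1.3467), c(1.045, 1.074))
  edges <- seq(1.035, 1.075, by = 0.0025)
  g <- simulate_gradient_counts(1.055, 1.050, sd = 0.003, n_cells = 5000,
                                fraction_edges = edges, calibration = cal,
                                seed = 42)
  prof <- gradient_profile(cbind(g$count_a, g$count_b), g$ri, cal)
  expect_lt(abs(prof$delta_rho - (-0.005)), 2e-4)
  expect_lt(abs(prof$median_density[1] - 1.055), 2e-4)
})

test_that("bin partitioning follows the first-crossing rule", {
  # equal counts in 9 fractions: 3 + 3 + 3
  b <- partition_bins(rep(10, 9), 3)
  expect_identical(b$first_fraction, c(1L, 4L, 7L))
  expect_identical(b$last_fraction, c(3L, 6L, 9L))
  expect_equal(b$count, rep(30, 3))
  # sparse counts, checked against exhaustive search over contiguous
  # 3-partitions: the first-crossing cut must attain the minimum deviation
  # from perfect thirds
  ct <- c(10, 0, 0, 10, 0, 10)
  b2 <- partition_bins(ct, 3)
  expect_equal(sum(b2$count), sum(ct))
  dev_first <- sum(abs(b2$count - sum(ct) / 3))
  best <- Inf
  for (c1 in 1:4) for (c2 in (c1 + 1):5) {
    parts <- c(sum(ct[1:c1]), sum(ct[(c1 + 1):c2]), sum(ct[(c2 + 1):6]))
    best <- min(best, sum(abs(parts - sum(ct) / 3)))
  }
  expect_equal(dev_first, best)
  # bins cover all fractions exactly once
  covered <- unlist(lapply(seq_len(nrow(b2)), function(i)
    b2$first_fraction[i]:b2$last_fraction[i]))
  expect_identical(sort(covered), 1:6)
  # degenerate cases
  expect_error(partition_bins(c(0, 0, 100, 0), 3), "nonempty")
  expect_error(partition_bins(c(5, 5), 3), "fewer fractions")
  expect_error(partition_bins(rep(0, 6), 3), "> 0")
})

test_that("coulter series normalise to the three-point baseline", {
  # stated arithmetic: baseline mean of {500, 502, 498} is 500
  samples <- list(rep(500, 9), rep(502, 9), rep(498, 9), rep(575, 9))
  cs <- coulter_median_series(samples)
  expect_equal(cs$median_fl, c(500, 502, 498, 575))
  expect_equal(cs$norm_median[4], 1.15, tolerance = 1e-12)
  expect_error(coulter_median_series(samples[1:2]), "timepoints")
  # identical distributions stay at 1 within sampling error
  run <- simulate_coulter_run(swell_fraction = 0, n_timepoints = 8,
                              n_per_timepoint = 5000, seed = 3)
  cs2 <- coulter_median_series(run$samples, run$times)
  expect_lt(max(abs(cs2$norm_median - 1)), 0.02)
  # a programmed 15% swell plateaus at 1.15 +/- 0.02
  run3 <- simulate_coulter_run(swell_fraction = 0.15, swell_tau = 240,
                               n_timepoints = 25, n_per_timepoint = 5000,
                               stim_timepoint = 3, seed = 4)
  cs3 <- coulter_median_series(run3$samples, run3$times)
  plateau <- mean(cs3$norm_median[run3$times > 3 * 60 + 5 * 240])
  expect_equal(plateau, 1.15, tolerance = 0.02)
})

test_that("water-content arithmetic matches the printed inputs", {
  # 15% volume gain on a cell that is 65% water: ~23% more water,
  # i.e. just under a quarter
  g <- water_content_gain(0.15, 0.65)
  expect_equal(g, 0.15 / 0.65, tolerance = 1e-12)
  expect_gt(g, 0.20)
  expect_lt(g, 0.25)
})

test_that("exhaustive bin partitioning attains the first-crossing balance", {
  ct <- c(10, 0, 0, 10, 0, 10)
  b_first <- partition_bins(ct, 3)
  b_ex <- partition_bins(ct, 3, method = "exhaustive")
  dev <- function(b) sum(abs(b$count - sum(ct) / 3))
  expect_equal(dev(b_first), dev(b_ex))
  # on unbalanced counts the exhaustive mode can only do as well or better
  set.seed(13)
  for (k in 1:10) {
    ct2 <- rpois(8, 20)
    if (sum(ct2) == 0) next
    expect_gte(dev2 <- sum(abs(partition_bins(ct2, 3)$count - sum(ct2) / 3)),
               sum(abs(partition_bins(ct2, 3, "exhaustive")$count -
                         sum(ct2) / 3)) - 1e-12)
  }
})
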