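# Bulk assays: buoyant-density gradient quantification and Coulter-counter
# median time series.

#' Fit the linear refractive-index to density calibration
#'
#' Percoll-type gradient media have a density linear in refractive index,
#' so two reference solutions of known density define the line; more pairs
#' are fitted by least squares.
#'
#' @param ri Refractive indices (>= 2 distinct values).
#' @param density Densities, g/mL.
#' @return List of class `fxm_density_cal` with `slope` (g/mL per RI unit)
#'   and `intercept` (g/mL).
#' @export
fit_density_calibration <- function(ri, density) {
  stopifnot(length(ri) == length(density), length(ri) >= 2)
  if (length(unique(ri)) < 2) stop("at least 2 distinct RI values required")
  fit <- stats::lm.fit(cbind(1, ri), density)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1])),
            class = "fxm_density_cal")
}

#' Convert refractive index to density
#' @param calibration An `fxm_density_cal`.
#' @param ri Refractive index (vectorised).
#' @return Density, g/mL.
#' @export
ri_to_density <- function(calibration, ri) {
  calibration$slope * ri + calibration$intercept
}

#' Convert density to refractive index (inverse calibration)
#' @param calibration An `fxm_density_cal`.
#' @param density Density, g/mL (vectorised).
#' @return Refractive index.
#' @export
density_to_ri <- function(calibration, density) {
  (density - calibration$intercept) / calibration$slope
}

# Grouped-data weighted median: fraction boundaries are the midpoints
# between adjacent fraction densities (extended symmetrically at the ends),
# and the median interpolates linearly within the median fraction.
weighted_median_density <- function(density, counts) {
  if (sum(counts) <= 0) stop("all-zero counts for a population")
  n <- length(density)
  mid <- (density[-1] + density[-n]) / 2
  lo <- c(density[1] - (mid[1] - density[1]), mid)
  hi <- c(mid, density[n] + (density[n] - mid[n - 1]))
  cum <- cumsum(counts)
  target <- sum(counts) / 2
  k <- which(cum >= target)[1]
  below <- if (k > 1) cum[k - 1] else 0
  lo[k] + (target - below) / counts[k] * (hi[k] - lo[k])
}

#' Build a gradient profile and density-shift statistic
#'
#' Converts per-fraction refractive indices to densities, computes each
#' population's weighted-median density (linear interpolation within the
#' median fraction), and, when two populations are given, the density
#' shift `delta_rho = median(pop 2) - median(pop 1)` (population 2 being
#' the stimulated one in the paired assay).
#'
#' @param counts Matrix or data frame of per-fraction counts, one column
#'   per population.
#' @param ri Per-fraction refractive indices (same length as rows of
#'   `counts`).
#' @param calibration An `fxm_density_cal`.
#' @return List of class `fxm_gradient_profile`: `profile` data frame
#'   (fraction, ri, density, one count column per population),
#'   `median_density` per population, and `delta_rho` (NA with a single
#'   population).
#' @export
gradient_profile <- function(counts, ri, calibration) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(ri))
  if (any(counts < 0)) stop("counts must be >= 0")
  density <- ri_to_density(calibration, ri)
  if (any(diff(density) <= 0))
    stop("densities must be monotonic in fraction order")
  med <- apply(counts, 2, function(ct) weighted_median_density(density, ct))
  delta <- if (ncol(counts) >= 2) med[2] - med[1] else NA_real_
  prof <- data.frame(fraction = seq_along(ri), ri = ri, density = density)
  cn <- colnames(counts)
  if (is.null(cn)) cn <- paste0("count_", seq_len(ncol(counts)))
  for (j in seq_len(ncol(counts))) prof[[cn[j]]] <- counts[, j]
  structure(list(profile = prof, median_density = med, delta_rho = delta),
            class = "fxm_gradient_profile")
}

#' Partition gradient fractions into equal-population bins
#'
#' Cut points are placed where the cumulative count first reaches
#' `k / n_bins` of the total (k = 1 .. n_bins - 1), giving contiguous bins
#' each holding approximately a third (for `n_bins = 3`) of the population.
#'
#' @param counts Per-fraction counts of one population.
#' @param n_bins Number of bins.
#' @param method `"first_crossing"` (default) or `"exhaustive"`, which
#'   searches all contiguous partitions for the minimum total deviation
#'   from perfect 1/n_bins splits (a reference mode for testing).
#' @return Data frame: `bin`, `first_fraction`, `last_fraction`, `count`.
#' @export
partition_bins <- function(counts, n_bins = 3,
                           method = c("first_crossing", "exhaustive")) {
  method <- match.arg(method)
  total <- sum(counts)
  if (total <= 0) stop("total counts must be > 0")
  if (length(counts) < n_bins) stop("fewer fractions than bins")
  cum <- cumsum(counts)
  cuts <- if (method == "first_crossing") {
    vapply(seq_len(n_bins - 1), function(k)
      which(cum >= k * total / n_bins)[1], integer(1))
  } else {
    best <- NULL; best_dev <- Inf
    combos <- utils::combn(length(counts) - 1L, n_bins - 1L)
    for (j in seq_len(ncol(combos))) {
      cc <- combos[, j]
      e <- c(0L, cc, length(counts))
      sums <- cum[e[-1]] - c(0, cum[cc])
      dev <- sum(abs(sums - total / n_bins))
      if (dev < best_dev - 1e-12) { best_dev <- dev; best <- cc }
    }
    best
  }
  edges <- c(0L, cuts, length(counts))
  if (any(diff(edges) < 1))
    stop(sprintf("cannot form %d nonempty bins", n_bins))
  data.frame(bin = seq_len(n_bins),
             first_fraction = edges[-length(edges)] + 1L,
             last_fraction = edges[-1],
             count = vapply(seq_len(n_bins), function(b)
               sum(counts[(edges[b] + 1L):edges[b + 1L]]), numeric(1)))
}

#' Median-volume time series from Coulter samples
#'
#' Extracts the per-timepoint median and normalises it to the mean of the
#' first `baseline_n` medians (the timepoints recorded before the
#' chemoattractant is added).
#'
#' @param samples List of per-timepoint volume samples, fL.
#' @param times Timepoint times, s (default 0, 60, 120, ...).
#' @param baseline_n Number of baseline timepoints (default 3).
#' @return Data frame: `time_s`, `median_fl`, `norm_median`.
#' @export
coulter_median_series <- function(samples, times = NULL, baseline_n = 3) {
  if (length(samples) < baseline_n)
    stop(sprintf("need at least %d timepoints", baseline_n))
  if (is.null(times)) times <- (seq_along(samples) - 1) * 60
  stopifnot(length(times) == length(samples))
  med <- vapply(samples, stats::median, numeric(1))
  base <- mean(med[seq_len(baseline_n)])
  data.frame(time_s = times, median_fl = med, norm_median = med / base)
}

#' Relative water-content gain from a volume increase
#'
#' A cell whose volume rises by `swell_fraction` through water influx gains
#' that entire increment as water, so the relative gain in water content is
#' `swell_fraction / water_fraction` (about 23% for a 15% swell of a cell
#' that is 65% water).
#'
#' @param swell_fraction Fractional volume increase.
#' @param water_fraction Resting water fraction of the cell.
#' @return Fractional increase in water content.
#' @export
water_content_gain <- function(swell_fraction = 0.15, water_fraction = 0.65) {
  stopifnot(water_fraction > 0, water_fraction <= 1, swell_fraction >= 0)
  swell_fraction / water_fraction
}
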