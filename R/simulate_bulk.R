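# Synthetic bulk-assay generators: density-gradient fractionation counts
# and Coulter-counter volume samples.

#' Simulate per-fraction cell counts for two populations on a density gradient
#'
#' Cell densities are drawn from normal distributions and histogrammed into
#' the gradient fractions. Cells falling outside the gradient range are
#' counted in the first/last fraction (as they would collect at the top or
#' bottom of a real tube). Fraction refractive indices are obtained by
#' inverting the linear density calibration at the fraction midpoints.
#'
#' @param median_density_a,median_density_b Population median densities, g/mL.
#' @param sd Density SD, g/mL (> 0).
#' @param n_cells Cells per population.
#' @param fraction_edges Strictly increasing fraction boundaries, g/mL.
#' @param calibration A [fit_density_calibration()] object.
#' @param seed Optional seed.
#' @return Data frame with `fraction`, `ri`, `density` (midpoint),
#'   `count_a`, `count_b`; fraction edges attached as attribute `edges`.
#' @export
simulate_gradient_counts <- function(median_density_a, median_density_b,
                                     sd, n_cells, fraction_edges,
                                     calibration, seed = NULL) {
  if (any(diff(fraction_edges) <= 0))
    stop("fraction_edges must be strictly increasing")
  if (sd <= 0) stop("sd must be > 0")
  draw <- function() {
    bin <- function(med) {
      d <- stats::rnorm(n_cells, med, sd)
      d <- pmin(pmax(d, fraction_edges[1]), fraction_edges[length(fraction_edges)])
      tabulate(findInterval(d, fraction_edges, rightmost.closed = TRUE),
               nbins = length(fraction_edges) - 1)
    }
    list(a = bin(median_density_a), b = bin(median_density_b))
  }
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  mid <- (fraction_edges[-1] + fraction_edges[-length(fraction_edges)]) / 2
  out <- data.frame(fraction = seq_along(mid),
                    ri = density_to_ri(calibration, mid),
                    density = mid,
                    count_a = counts$a, count_b = counts$b)
  attr(out, "edges") <- fraction_edges
  out
}

#' Simulate a Coulter-counter time series
#'
#' Per-cell volumes are lognormal; the population median is flat before the
#' stimulation timepoint and then rises with a saturating exponential to
#' `1 + swell_fraction` times baseline.
#'
#' @param median_fl Baseline median volume, fL.
#' @param cv Coefficient of variation of the volume distribution.
#' @param swell_fraction Fractional plateau volume increase after stimulation.
#' @param swell_tau Swelling time constant, s.
#' @param n_timepoints Number of timepoints.
#' @param n_per_timepoint Cells sampled per timepoint (>= 1).
#' @param stim_timepoint 0-based index of the stimulation timepoint.
#' @param interval Seconds between timepoints.
#' @param seed Optional seed.
#' @return List with `times` (s) and `samples` (list of fL vectors).
#' @export
simulate_coulter_run <- function(median_fl = 330, cv = 0.18,
                                 swell_fraction = 0.15, swell_tau = 240,
                                 n_timepoints = 20, n_per_timepoint = 5000,
                                 stim_timepoint = 3, interval = 60,
                                 seed = NULL) {
  stopifnot(n_per_timepoint >= 1, n_timepoints >= 1)
  times <- (seq_len(n_timepoints) - 1) * interval
  t_rel <- times - stim_timepoint * interval
  med <- median_fl * (1 + swell_fraction *
                        (1 - exp(-pmax(t_rel, 0) / swell_tau)) * (t_rel >= 0))
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function() lapply(med, function(m)
    m * exp(stats::rnorm(n_per_timepoint, 0, sdlog)))
  samples <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(times = times, samples = samples)
}
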