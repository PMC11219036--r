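# Track kinematics: windowed velocity, cumulative distance, angular
# alignment, and replicate-aware population summaries.

#' Windowed track velocity
#'
#' `v_i = |p_{i+tau} - p_{i-tau}| / (t_{i+tau} - t_{i-tau})`, reported in
#' um/min. Undefined (NA) at the first and last `tau` frames. A window of
#' tau = 3 at 10 s frame spacing corresponds to approximately one minute.
#'
#' @param x,y Track coordinates, um.
#' @param times Frame times, s (strictly increasing).
#' @param tau Half-window in frames (>= 1).
#' @return Velocity series, um/min.
#' @export
track_velocity <- function(x, y, times, tau = 3) {
  stopifnot(tau >= 1, length(x) == length(y), length(x) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n > 2 * tau) {
    idx <- (tau + 1):(n - tau)
    d <- sqrt((x[idx + tau] - x[idx - tau])^2 + (y[idx + tau] - y[idx - tau])^2)
    v[idx] <- d / (times[idx + tau] - times[idx - tau]) * 60
  }
  v
}

#' Cumulative distance travelled along a track
#'
#' @param x,y Track coordinates, um.
#' @return Non-decreasing series starting at 0, um.
#' @export
cumulative_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) return(numeric())
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

#' Angular alignment along a track
#'
#' For each position B_i, the anchors are the latest prior position A with
#' at least `distance_offset` um of path travelled between A and B, and the
#' earliest subsequent position C with at least `distance_offset` um
#' between B and C. The angle between BA and BC,
#' `atan2(|BA x BC|, BA . BC)` in `[0, pi]`, is mapped affinely to
#' `2 * (angle / pi) - 1`, so +1 means the track continues perfectly
#' straight (BA and BC antiparallel) and -1 a complete reversal. Frames
#' without both anchors, or with a zero-length anchor vector, are NA.
#'
#' @param x,y Track coordinates, um.
#' @param distance_offset Path-length separation of the anchors, um.
#' @return Alignment series in `[-1, 1]` (NA where undefined).
#' @export
angular_alignment <- function(x, y, distance_offset = 10) {
  stopifnot(length(x) == length(y), distance_offset > 0)
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  cd <- cumulative_distance(x, y)
  for (i in seq_len(n)) {
    # latest j < i with cd[i] - cd[j] >= offset
    a <- findInterval(cd[i] - distance_offset, cd)
    if (a < 1 || a >= i) next
    # earliest j > i with cd[j] - cd[i] >= offset
    cc <- findInterval(cd[i] + distance_offset, cd, left.open = TRUE) + 1L
    if (cc > n || cc <= i) next
    ba <- c(x[a] - x[i], y[a] - y[i])
    bc <- c(x[cc] - x[i], y[cc] - y[i])
    la <- sqrt(sum(ba^2)); lc <- sqrt(sum(bc^2))
    if (la == 0 || lc == 0) next
    cross <- abs(ba[1] * bc[2] - ba[2] * bc[1])
    dot <- sum(ba * bc)
    ang <- atan2(cross, dot)
    out[i] <- 2 * (ang / pi) - 1
  }
  out
}

#' Replicate-aware population summary
#'
#' At each timepoint the median across cells is computed within each
#' replicate, and the mean, SD and normal-approximation 95% CI are taken
#' across replicate medians. Replicates with no finite value at a
#' timepoint are omitted there; with a single replicate the SD and CI are
#' undefined (NA).
#'
#' @param data Data frame with columns `replicate`, `time_s`, `value`
#'   (one row per cell per timepoint).
#' @return Data frame: `time_s`, `mean_of_medians`, `sd`, `ci95_lo`,
#'   `ci95_hi`, `n_replicates`, `n_cells`.
#' @export
population_summary <- function(data) {
  stopifnot(all(c("replicate", "time_s", "value") %in% names(data)))
  if (!nrow(data)) {
    return(data.frame(time_s = numeric(), mean_of_medians = numeric(),
                      sd = numeric(), ci95_lo = numeric(),
                      ci95_hi = numeric(), n_replicates = integer(),
                      n_cells = integer()))
  }
  data <- data[is.finite(data$value), , drop = FALSE]
  times <- sort(unique(data$time_s))
  out <- lapply(times, function(tt) {
    d <- data[data$time_s == tt, , drop = FALSE]
    med <- tapply(d$value, d$replicate, stats::median)
    med <- med[is.finite(med)]
    nrep <- length(med)
    m <- mean(med)
    s <- if (nrep >= 2) stats::sd(med) else NA_real_
    half <- if (nrep >= 2) stats::qnorm(0.975) * s / sqrt(nrep) else NA_real_
    data.frame(time_s = tt, mean_of_medians = m, sd = s,
               ci95_lo = m - half, ci95_hi = m + half,
               n_replicates = nrep, n_cells = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
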