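# Per-frame illumination correction.
#
# The chamber ceiling is flat, so background (cell- and pillar-free) pixels
# sample the illumination surface directly. Background points are placed on
# a sinusoidal path -- which concentrates samples near the top and bottom of
# the field, where interpolants are otherwise least constrained -- a
# multiquadric radial basis interpolant is fitted to their raw intensities,
# and the raw frame is corrected as (raw - darkfield)/(field - darkfield).

#' Place background sample points on a sinusoidal path
#'
#' `n_points` columns are spaced uniformly across the frame; the row follows
#' `centre + (H/2 - margin) * sin(2 * pi * n_periods * j / n_points)`. Any
#' point landing on the exclusion mask (cells, pillars) is moved to the
#' nearest non-excluded pixel within 20 px, or dropped.
#'
#' @param shape `c(rows, cols)` of the frame.
#' @param exclusion Logical matrix of pixels to avoid (or NULL).
#' @param n_points Number of points.
#' @param n_periods Sine periods across the frame.
#' @param margin Border margin, px.
#' @param min_spacing Minimum pairwise distance between returned points,
#'   px. The sine path is locally dense near its crests; near-duplicate
#'   centres under the wide multiquadric kernel make the fit
#'   ill-conditioned, so redundant points are thinned out.
#' @return Integer matrix with columns `row`, `col` (at least 3 rows).
#' @export
sample_background_points <- function(shape, exclusion = NULL,
                                     n_points = 200, n_periods = 4,
                                     margin = 10, min_spacing = 8) {
  H <- shape[1]; W <- shape[2]
  if (!is.null(exclusion)) stopifnot(all(dim(exclusion) == shape))
  j <- seq_len(n_points) - 1
  col <- round(margin + 1 + (W - 2 * margin - 1) * j / (n_points - 1))
  row <- round((H + 1) / 2 + (H / 2 - margin) *
                 sin(2 * pi * n_periods * j / n_points))
  col <- pmin(pmax(col, 1L), W)
  row <- pmin(pmax(row, 1L), H)
  pts <- cbind(row = row, col = col)
  if (!is.null(exclusion)) {
    keep <- logical(n_points)
    for (k in seq_len(n_points)) {
      r <- pts[k, 1]; c <- pts[k, 2]
      if (!exclusion[r, c]) { keep[k] <- TRUE; next }
      rw <- max(1, r - 20):min(H, r + 20)
      cw <- max(1, c - 20):min(W, c + 20)
      sub <- exclusion[rw, cw, drop = FALSE]
      free <- which(!sub, arr.ind = TRUE)
      if (!nrow(free)) next
      d2 <- (rw[free[, 1]] - r)^2 + (cw[free[, 2]] - c)^2
      b <- which.min(d2)
      if (d2[b] <= 400) {
        pts[k, ] <- c(rw[free[b, 1]], cw[free[b, 2]])
        keep[k] <- TRUE
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  pts <- unique(pts)
  if (min_spacing > 0 && nrow(pts) > 1) {
    keep <- rep(FALSE, nrow(pts))
    keep[1] <- TRUE
    for (k in 2:nrow(pts)) {
      kept <- pts[keep, , drop = FALSE]
      d2 <- (kept[, 1] - pts[k, 1])^2 + (kept[, 2] - pts[k, 2])^2
      if (min(d2) >= min_spacing^2) keep[k] <- TRUE
    }
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("background unsampleable")
  pts
}

#' Fit a multiquadric interpolant to scattered background samples
#'
#' The field is `s(p) = sum_j w_j * sqrt(||p - p_j||^2 + eps^2) + a0 +
#' a1 * row + a2 * col`: a multiquadric radial basis augmented with a
#' linear polynomial under the usual moment constraints
#' (`sum w = sum w * row = sum w * col = 0`). The augmentation reproduces
#' constant and linearly ramped backgrounds exactly and pins down the
#' far-field behaviour of the kernel, which otherwise diverges outside the
#' convex hull of the sample points. The kernel block carries a small
#' ridge `lambda`, keeping the system well-posed when point relocation
#' produces near-duplicates. The default shape parameter `eps` is the mean
#' nearest-neighbour spacing of the points.
#'
#' @param points Matrix with columns (row, col) in px.
#' @param values Intensities at the points.
#' @param eps Kernel shape parameter, px (default: mean NN spacing).
#' @param lambda Ridge regularisation of the kernel block.
#' @return Object of class `fxm_bg_field`.
#' @export
fit_background_field <- function(points, values, eps = NULL, lambda = 1e-8) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("at least 3 background points required")
  stopifnot(length(values) == n)
  D <- as.matrix(stats::dist(points))
  if (is.null(eps) || !length(eps)) {
    diag(D) <- Inf
    eps <- mean(apply(D, 1, min))
    diag(D) <- 0
    if (!is.finite(eps) || eps <= 0) eps <- 1
  }
  A <- sqrt(D^2 + eps^2) + diag(lambda, n)
  P <- cbind(1, points[, 1], points[, 2])
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(M, c(values, 0, 0, 0)),
                  error = function(e) stop("singular kernel system: ",
                                           conditionMessage(e)))
  structure(list(points = points, weights = sol[seq_len(n)],
                 poly = sol[n + 1:3], eps = eps, lambda = lambda),
            class = "fxm_bg_field")
}

#' Evaluate a background field at arbitrary pixel locations
#'
#' @param object An `fxm_bg_field`.
#' @param newdata Matrix with columns (row, col) in px.
#' @param ... Unused.
#' @return Numeric vector of field values.
#' @export
predict.fxm_bg_field <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  d2 <- outer(newdata[, 1], object$points[, 1], "-")^2 +
    outer(newdata[, 2], object$points[, 2], "-")^2
  as.numeric(sqrt(d2 + object$eps^2) %*% object$weights) +
    object$poly[1] + object$poly[2] * newdata[, 1] +
    object$poly[3] * newdata[, 2]
}

#' Evaluate a background field over a full frame
#'
#' The field is evaluated exactly on a coarse grid (`grid_step` px) and
#' interpolated bilinearly in between; multiquadric surfaces of background
#' illumination are smooth at this scale.
#'
#' @param field An `fxm_bg_field`.
#' @param nrow,ncol Frame dimensions.
#' @param grid_step Coarse-grid spacing in px (1 = exact everywhere).
#' @return Numeric matrix `nrow x ncol`.
#' @export
evaluate_field <- function(field, nrow, ncol, grid_step = 4) {
  rg <- unique(c(seq(1, nrow, by = grid_step), nrow))
  cg <- unique(c(seq(1, ncol, by = grid_step), ncol))
  grid <- cbind(rep(rg, times = length(cg)), rep(cg, each = length(rg)))
  vals <- matrix(predict(field, grid), length(rg), length(cg))
  if (grid_step <= 1) return(vals)
  Wr <- interp_weights(rg, nrow)
  Wc <- interp_weights(cg, ncol)
  Wr %*% vals %*% t(Wc)
}

#' Flatfield-correct a raw frame
#'
#' `corrected = (raw - darkfield) / (field - darkfield)`. Background pixels
#' come out near 1 and pillar pixels near 0; the correction is invariant to
#' a common gain on raw and darkfield.
#'
#' @param raw Raw frame matrix.
#' @param darkfield Camera offset (matrix or scalar).
#' @param field Either an `fxm_bg_field` or a pre-evaluated field matrix.
#' @param grid_step Passed to [evaluate_field()] when `field` is a model.
#' @return Corrected frame matrix.
#' @export
correct_frame <- function(raw, darkfield, field, grid_step = 4) {
  f <- if (inherits(field, "fxm_bg_field")) {
    evaluate_field(field, nrow(raw), ncol(raw), grid_step)
  } else field
  if (is.matrix(darkfield)) stopifnot(all(dim(darkfield) == dim(raw)))
  den <- f - darkfield
  if (any(den <= 0)) stop("darkfield exceeds background model")
  (raw - darkfield) / den
}
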