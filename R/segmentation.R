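# Foreground and instance segmentation.
#
# Cells exclude the fluorescent dye, so their rims are the strongest
# intensity gradients in the FxM channel. The foreground is recovered by
# denoising, Scharr edge enhancement, thresholding the (log-normally
# distributed) edge magnitudes one standard deviation above the log-mean,
# sealing and flood-filling the enclosed areas, and finally splitting the
# foreground into instances by growing from nuclear seeds.

#' Segmentation parameters
#'
#' @param denoise_sigma Gaussian denoising SD, px (0 disables). The
#'   default 0.5 px suppresses pixel-scale noise while barely spreading
#'   the cell-rim gradient, keeping detected footprints tight.
#' @param threshold_k Edge threshold in SDs above the mean of the
#'   log-magnitudes (default 1).
#' @param closing_radius Morphological closing radius applied to the edge
#'   mask before flood fill, px.
#' @param min_component_area Minimum foreground component area, px.
#' @param footprint_dilation_radius Final dilation of the foreground, px.
#'   Deliberate slight over-segmentation: pixels just outside the cell carry
#'   near-zero excluded signal but capture scattered light, which keeps
#'   whole-cell volumes accurate.
#' @param seed_smooth_sigma Gaussian smoothing of the nuclear channel before
#'   seed thresholding, px.
#' @param seed_min_area,seed_max_area Area gates for nuclear seeds, px.
#' @return List of class `fxm_seg_params`.
#' @export
seg_params <- function(denoise_sigma = 0.5, threshold_k = 1,
                       closing_radius = 1, min_component_area = 60,
                       footprint_dilation_radius = 1,
                       seed_smooth_sigma = 2,
                       seed_min_area = 20, seed_max_area = 2000) {
  stopifnot(denoise_sigma >= 0, closing_radius >= 0,
            footprint_dilation_radius >= 0, seed_smooth_sigma >= 0,
            min_component_area >= 1, seed_min_area <= seed_max_area)
  structure(list(denoise_sigma = denoise_sigma, threshold_k = threshold_k,
                 closing_radius = closing_radius,
                 min_component_area = min_component_area,
                 footprint_dilation_radius = footprint_dilation_radius,
                 seed_smooth_sigma = seed_smooth_sigma,
                 seed_min_area = seed_min_area,
                 seed_max_area = seed_max_area),
            class = "fxm_seg_params")
}

#' Denoise an intensity image
#'
#' Gaussian smoothing with replicated borders; `sigma = 0` is the identity.
#' The smoothing is mean-preserving away from rounding error.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Gaussian SD in px.
#' @return Smoothed matrix, same shape.
#' @export
denoise <- function(image, sigma = 1) {
  stopifnot(is.matrix(image))
  if (sigma <= 0) return(image)
  m <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
  matrix(m, nrow(image), ncol(image))
}

#' Scharr gradient magnitude
#'
#' Horizontal and vertical 3x3 Scharr convolutions (weights 3, 10, 3,
#' normalised by 16) with mirrored borders; returns the per-pixel gradient
#' magnitude.
#'
#' @param image 2-D numeric matrix.
#' @return Non-negative matrix of gradient magnitudes.
#' @export
edge_magnitude <- function(image) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image too small for a 3x3 kernel")
  # reflect-101 padding by one pixel
  P <- image[c(2L, seq_len(nr), nr - 1L), c(2L, seq_len(nc), nc - 1L)]
  sub <- function(dr, dc) P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  gx <- (3 * (sub(-1L, 1L) - sub(-1L, -1L)) +
           10 * (sub(0L, 1L) - sub(0L, -1L)) +
           3 * (sub(1L, 1L) - sub(1L, -1L))) / 16
  gy <- (3 * (sub(1L, -1L) - sub(-1L, -1L)) +
           10 * (sub(1L, 0L) - sub(-1L, 0L)) +
           3 * (sub(1L, 1L) - sub(-1L, 1L))) / 16
  sqrt(gx^2 + gy^2)
}

#' Threshold edge magnitudes into a foreground mask
#'
#' The threshold is `exp(mu + k * sigma)` with `mu`, `sigma` the mean and SD
#' of log-magnitudes over strictly positive pixels (edge magnitudes are
#' log-normally distributed on noisy images). Edge pixels are closed
#' morphologically, the background is identified by flood fill from the
#' image border, and its complement -- the edges plus everything they
#' enclose -- is the foreground. Small components are removed, the result
#' is dilated by `footprint_dilation_radius`, and pillar pixels are forced
#' to background.
#'
#' @param magnitude Non-negative gradient-magnitude matrix.
#' @param params [seg_params()].
#' @param pillar_mask Optional logical matrix of pillar pixels.
#' @return Logical foreground mask.
#' @export
threshold_foreground <- function(magnitude, params = seg_params(),
                                 pillar_mask = NULL) {
  stopifnot(is.matrix(magnitude), all(magnitude >= 0))
  # Gradients below 1% of the frame's peak magnitude count as zero: on an
  # integer detector they would quantise away, and including such
  # blur-tail residues in the log statistics makes sigma meaningless.
  floor_tol <- max(magnitude) * 0.01
  pos <- magnitude[magnitude > floor_tol]
  if (!length(pos)) return(matrix(FALSE, nrow(magnitude), ncol(magnitude)))
  if (length(pos) < 100) stop("degenerate edge distribution")
  lp <- log(pos)
  theta <- exp(mean(lp) + params$threshold_k * stats::sd(lp))
  edge <- magnitude >= theta
  if (params$closing_radius > 0)
    edge <- EBImage::closing(edge * 1, disc_brush(params$closing_radius)) > 0.5
  # Background flood fill is 4-connected (the dual of the 8-connected
  # foreground): an 8-connected fill would leak through the diagonal
  # joints of thin closed edge rings.
  notedge <- !edge
  lab <- EBImage::bwlabel(notedge * 1)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                            lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  if (!length(border_labels))
    stop("background flood-fill seed unavailable")
  fg <- !(matrix(lab %in% border_labels, nrow(lab), ncol(lab)))
  if (mean(fg) > 0.8) stop("background flood-fill seed unavailable")
  comp <- label8(fg)
  if (max(comp) > 0) {
    areas <- tabulate(comp[comp > 0], nbins = max(comp))
    keep <- which(areas >= params$min_component_area)
    fg <- matrix(comp %in% keep, nrow(comp), ncol(comp))
  }
  fg <- dilate_mask(fg, params$footprint_dilation_radius)
  if (!is.null(pillar_mask)) fg[pillar_mask] <- FALSE
  fg
}

#' Detect nuclear seed points
#'
#' Gaussian smoothing, Otsu threshold, 8-connected components filtered to
#' the configured area range; returns component centroids. An empty result
#' is allowed.
#'
#' @param nuclear 2-D nuclear-channel matrix.
#' @param params [seg_params()].
#' @return Data frame with `seed_id`, `row`, `col` (1-based px), `area`.
#' @export
detect_seeds <- function(nuclear, params = seg_params()) {
  stopifnot(is.matrix(nuclear))
  g <- denoise(nuclear, params$seed_smooth_sigma)
  rng <- range(g)
  empty <- data.frame(seed_id = integer(), row = numeric(), col = numeric(),
                      area = integer())
  if (diff(rng) <= 0) return(empty)
  g01 <- (g - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(g01), range = c(0, 1))
  lab <- label8(g01 > th)
  cent <- label_centroids(lab)
  cent <- cent[cent$area >= params$seed_min_area &
                 cent$area <= params$seed_max_area, , drop = FALSE]
  if (!nrow(cent)) return(empty)
  data.frame(seed_id = seq_len(nrow(cent)), row = cent$row, col = cent$col,
             area = cent$area)
}

#' Split the foreground into labelled instances from seed points
#'
#' Labels grow geodesically from the seeds within the foreground mask
#' (equivalent to a watershed on the negative distance-to-seed relief for a
#' binary mask), so the boundary between two seeds in one component lies on
#' their equidistant line. Components containing no seed are left unlabelled
#' but remain part of the foreground; seeds outside the mask are dropped
#' with a warning.
#'
#' @param mask Logical foreground mask.
#' @param seeds Data frame with `row`, `col` (1-based px) and optionally
#'   `label` (positive integers; defaults to the row number).
#' @return List with `labels` (integer matrix, 0 = background/unseeded) and
#'   `unseeded` (logical mask of foreground components without any seed).
#' @export
split_instances <- function(mask, seeds) {
  stopifnot(is.matrix(mask))
  lab0 <- matrix(0L, nrow(mask), ncol(mask))
  if (is.null(seeds) || !nrow(seeds)) {
    return(list(labels = lab0, unseeded = mask))
  }
  if (is.null(seeds$label)) seeds$label <- seq_len(nrow(seeds))
  if (any(seeds$label <= 0)) stop("seed labels must be positive")
  r <- pmin(pmax(round(seeds$row), 1L), nrow(mask))
  c <- pmin(pmax(round(seeds$col), 1L), ncol(mask))
  inside <- mask[cbind(r, c)]
  if (any(!inside))
    warning(sprintf("%d seed(s) outside the foreground mask dropped",
                    sum(!inside)))
  r <- r[inside]; c <- c[inside]; lbl <- as.integer(seeds$label[inside])
  if (!length(r)) return(list(labels = lab0, unseeded = mask))
  seedimg <- lab0
  seedimg[cbind(r, c)] <- lbl
  res <- EBImage::propagate(matrix(0, nrow(mask), ncol(mask)),
                            seeds = seedimg, mask = mask * 1, lambda = 1e8)
  labels <- matrix(as.integer(round(res)), nrow(mask), ncol(mask))
  labels[!mask] <- 0L
  unseeded <- mask & labels == 0L
  list(labels = labels, unseeded = unseeded)
}
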