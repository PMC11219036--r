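# Dye-exclusion volumetry.
#
# A cell of height h(x, y) in a chamber of height h_chamber displaces dye,
# reducing the corrected FxM signal below the local background Imax. The
# excluded volume is
#
#     V = (pixel_size^2 / alpha) * sum_{(x,y) in A} (Imax - I(x, y))
#
# where alpha = (Imax - Imin) / h_chamber converts corrected intensity to
# dye-column height; Imin is the signal at the pillars (zero dye column)
# and, for calibration, Imax is the frame-level background median. The
# per-cell Imax is the median over an annulus 2-10 px outside the cell
# border, avoiding other cells and pillars. Note the pixel-area factor:
# the intensity sum has units of intensity, and alpha of intensity per um,
# so the sum/alpha is a height integral that must be multiplied by the
# pixel footprint to yield um^3.

#' Frame-level intensity-to-height calibration
#'
#' `alpha = (median background - median pillar) / chamber_height`.
#'
#' @param corrected Flatfield-corrected frame.
#' @param pillar_mask Logical mask of pillar pixels (nonempty).
#' @param background_mask Logical mask of cell- and pillar-free pixels.
#' @param chamber_height Chamber height, um.
#' @return List with `alpha` (corrected units per um), `i_background`,
#'   `i_pillar`.
#' @export
alpha_calibration <- function(corrected, pillar_mask, background_mask,
                              chamber_height) {
  stopifnot(chamber_height > 0)
  if (!any(pillar_mask)) stop("pillar mask is empty")
  if (!any(background_mask)) stop("background mask is empty")
  i_bg <- stats::median(corrected[background_mask])
  i_pil <- stats::median(corrected[pillar_mask])
  alpha <- (i_bg - i_pil) / chamber_height
  if (alpha <= 0) stop("inverted calibration")
  list(alpha = alpha, i_background = i_bg, i_pillar = i_pil)
}

#' Local background (Imax) of one cell
#'
#' Median corrected intensity over the annulus of pixels whose distance to
#' the cell footprint lies in `[inner, outer]` px, excluding all labelled
#' pixels and pillars. Cells touching the frame border are flagged and get
#' no Imax; an annulus below `min_pixels` is an error ("locality
#' occluded"), which the pipeline records per cell-frame rather than
#' failing the run.
#'
#' @param corrected Corrected frame.
#' @param labels Integer label matrix.
#' @param cell_id Label of the cell of interest.
#' @param pillar_mask Optional logical pillar mask.
#' @param inner,outer Annulus distance bounds, px. Distances are measured
#'   from the footprint eroded by `erode_by`, so that when labels carry a
#'   deliberate dilation the annulus is anchored at the pre-dilation cell
#'   border.
#' @param erode_by Erosion radius applied before measuring distances, px.
#' @param min_pixels Minimum annulus size.
#' @return List with `imax`, `n_annulus`, `edge_touching`.
#' @export
local_background <- function(corrected, labels, cell_id, pillar_mask = NULL,
                             inner = 2, outer = 10, erode_by = 0,
                             min_pixels = 30) {
  cellpix <- which(labels == cell_id)
  if (!length(cellpix)) stop("cell_id not present in labels")
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- (cellpix - 1L) %% nr + 1L
  cols <- (cellpix - 1L) %/% nr + 1L
  if (any(rows == 1L | rows == nr | cols == 1L | cols == nc)) {
    return(list(imax = NA_real_, n_annulus = 0L, edge_touching = TRUE))
  }
  pad <- ceiling(outer) + 1L
  r0 <- max(1L, min(rows) - pad); r1 <- min(nr, max(rows) + pad)
  c0 <- max(1L, min(cols) - pad); c1 <- min(nc, max(cols) + pad)
  sub_lab <- labels[r0:r1, c0:c1, drop = FALSE]
  cellmask <- sub_lab == cell_id
  core <- if (erode_by > 0) erode_mask(cellmask, erode_by) else cellmask
  if (!any(core)) core <- cellmask
  D <- EBImage::distmap(1 - core)
  D <- matrix(D, nrow(core), ncol(core))
  annulus <- D >= inner & D <= outer & sub_lab == 0L
  if (!is.null(pillar_mask))
    annulus <- annulus & !pillar_mask[r0:r1, c0:c1, drop = FALSE]
  n_ann <- sum(annulus)
  if (n_ann < min_pixels) stop("locality occluded")
  sub_img <- corrected[r0:r1, c0:c1, drop = FALSE]
  list(imax = stats::median(sub_img[annulus]), n_annulus = n_ann,
       edge_touching = FALSE)
}

#' Excluded volume of one cell
#'
#' `V = (pixel_size^2 / alpha) * sum over footprint of (Imax - I)`. Values
#' are not clamped: under noise an empty footprint may integrate slightly
#' negative, and the rolling median of the trace suppresses such outliers.
#'
#' @param corrected Corrected frame.
#' @param footprint Logical matrix or pixel index vector of footprint A.
#' @param imax Local background (corrected units).
#' @param alpha Calibration, corrected units per um.
#' @param pixel_size Pixel size, um.
#' @return Volume in um^3.
#' @export
cell_volume <- function(corrected, footprint, imax, alpha, pixel_size) {
  stopifnot(alpha > 0)
  pix <- if (is.logical(footprint)) which(footprint) else footprint
  if (!length(pix)) stop("empty footprint")
  pixel_size^2 * sum(imax - corrected[pix]) / alpha
}

#' Assemble a per-cell volume trace
#'
#' The baseline is the median volume over the two-minute window preceding
#' stimulation; normalised volume is volume/baseline; the rolling median
#' uses a centred window that shrinks at the trace ends.
#'
#' @param volumes Per-frame volumes, um^3 (NA allowed).
#' @param times Frame times, s.
#' @param stim_time Stimulation time, s.
#' @param window Rolling-median window, frames (default 7, about one
#'   minute at 10 s spacing).
#' @param baseline_window Baseline window length before stimulation, s.
#' @return List with `baseline` and a data frame (`time_s`, `volume_um3`,
#'   `volume_norm`, `volume_rollmed_um3`).
#' @export
build_volume_trace <- function(volumes, times, stim_time, window = 7,
                               baseline_window = 120) {
  stopifnot(length(volumes) == length(times))
  base_idx <- which(times >= stim_time - baseline_window & times < stim_time &
                      !is.na(volumes))
  if (!length(base_idx)) stop("baseline undefined")
  baseline <- stats::median(volumes[base_idx])
  hw <- window %/% 2
  n <- length(volumes)
  rollmed <- vapply(seq_len(n), function(i) {
    w <- volumes[max(1, i - hw):min(n, i + hw)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
  list(baseline = baseline,
       trace = data.frame(time_s = times, volume_um3 = volumes,
                          volume_norm = volumes / baseline,
                          volume_rollmed_um3 = rollmed))
}
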