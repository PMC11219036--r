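# QC outputs: label stacks and segmentation overlays.

#' Write per-frame label images as a 16-bit TIFF stack
#'
#' Labels are stored as 16-bit unsigned values (0 = background); a label
#' above 65535 is an error.
#'
#' @param labels A label matrix or list of label matrices.
#' @param file Output TIFF path.
#' @return `file`, invisibly.
#' @export
write_label_stack <- function(labels, file) {
  if (is.matrix(labels)) labels <- list(labels)
  mx <- max(vapply(labels, max, numeric(1)))
  if (mx > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lapply(labels, function(l) l / 65535),
                  file, bits.per.sample = 16)
  invisible(file)
}

#' Read a label stack written by [write_label_stack()]
#'
#' @param file TIFF path.
#' @return List of integer label matrices.
#' @export
read_label_stack <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Write a segmentation overlay image
#'
#' Renders the intensity frame in grey with label boundaries marked, as a
#' quick segmentation-quality check. Requires the `png` package.
#'
#' @param image Intensity frame.
#' @param labels Integer label matrix.
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
write_qc_overlay <- function(image, labels, file) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for QC overlays")
  g <- image - min(image)
  g <- g / max(g, 1e-12)
  edge <- labels > 0 &
    (labels != rbind(labels[-1, ], labels[nrow(labels), ]) |
       labels != cbind(labels[, -1], labels[, ncol(labels)]))
  rgb <- array(g, dim = c(nrow(g), ncol(g), 3))
  rgb[, , 1][edge] <- 0
  rgb[, , 2][edge] <- 1
  rgb[, , 3][edge] <- 1
  png::writePNG(rgb, file)
  invisible(file)
}
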