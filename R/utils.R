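# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulator calls do not perturb the session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' 8-connected component labelling
#'
#' EBImage's `bwlabel()` uses 4-connectivity; diagonal neighbours are merged
#' here with a union-find pass over label adjacencies.
#' @noRd
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n == 0L) return(lab)
  dpair <- function(l, dr, dc) {
    nr <- nrow(l); nc <- ncol(l)
    r1 <- if (dr > 0) 1:(nr - 1) else 2:nr
    r2 <- if (dr > 0) 2:nr else 1:(nr - 1)
    a <- l[r1, 1:(nc - 1), drop = FALSE]
    b <- l[r2, 2:nc, drop = FALSE]
    keep <- a > 0L & b > 0L & a != b
    cbind(a[keep], b[keep])
  }
  pairs <- unique(rbind(dpair(lab, 1L, 1L), dpair(lab, -1L, 1L)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  map <- c(0L, as.integer(dense))
  matrix(map[lab + 1L], nrow(lab), ncol(lab))
}

#' Disc structuring element of integer radius
#' @noRd
disc_brush <- function(radius) {
  sz <- 2L * as.integer(radius) + 1L
  if (sz < 3L) sz <- 3L
  EBImage::makeBrush(sz, shape = "disc")
}

#' Binary dilation/erosion wrappers returning logical matrices
#' @noRd
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask * 1, disc_brush(radius)) > 0.5
}

#' @noRd
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::erode(mask * 1, disc_brush(radius)) > 0.5
}

#' Per-label centroids and areas of an integer label matrix
#'
#' Centroids in 1-based (row, col) pixel units.
#' @noRd
label_centroids <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area = integer()))
  }
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  out <- data.frame(
    label = as.integer(sort(unique(labs))),
    row = as.numeric(tapply(rows, labs, mean)),
    col = as.numeric(tapply(cols, labs, mean)),
    area = as.integer(tapply(rows, labs, length))
  )
  rownames(out) <- NULL
  out
}

#' Linear interpolation weight matrix
#'
#' Rows of the returned `n x length(nodes)` matrix hold the two bilinear
#' weights mapping values at `nodes` (sorted, within 1..n) onto 1..n.
#' @noRd
interp_weights <- function(nodes, n) {
  m <- length(nodes)
  W <- matrix(0, n, m)
  pos <- seq_len(n)
  k <- findInterval(pos, nodes, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k >= m] <- m - 1L
  lo <- nodes[k]; hi <- nodes[k + 1L]
  w <- (pos - lo) / (hi - lo)
  w[w < 0] <- 0; w[w > 1] <- 1
  W[cbind(pos, k)] <- 1 - w
  W[cbind(pos, k + 1L)] <- W[cbind(pos, k + 1L)] + w
  W
}

#' Stable hash of an R object via its canonical YAML serialisation
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(yaml::as.yaml(x, precision = 15), f)
  unname(tools::md5sum(f))
}

#' Border-touching test for a logical mask
#' @noRd
touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}
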