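# Frame-to-frame linking of per-frame detections into cell tracks.

#' Link per-frame detections into tracks
#'
#' Detections in consecutive frames are matched by centroid distance among
#' pairs closer than `max_disp`. The default `"greedy"` mode accepts pairs
#' in order of increasing distance (ties broken by smaller detection index,
#' then smaller track index); `"exact"` mode solves the
#' minimum-total-distance assignment (maximising the number of links first).
#' Unmatched detections start new tracks; a track unmatched for more than
#' `memory` consecutive frames is closed. Gap frames are simply absent from
#' the output (no interpolation).
#'
#' @param detections List (one element per frame) of data frames or
#'   matrices with columns `x`, `y` in um; an optional `label` column is
#'   carried through (defaults to the detection index within the frame).
#' @param times Frame times in s (default `0, 1, 2, ...`).
#' @param max_disp Maximum link displacement, um.
#' @param memory Frames a track may go undetected before it is closed.
#' @param method `"greedy"` or `"exact"`.
#' @return Track table: `track_id`, `frame` (0-based), `time_s`, `x_um`,
#'   `y_um`, `label`, sorted by (track_id, frame).
#' @export
link_tracks <- function(detections, times = NULL, max_disp = 15,
                        memory = 2, method = c("greedy", "exact")) {
  method <- match.arg(method)
  stopifnot(max_disp > 0, memory >= 0)
  nf <- length(detections)
  if (is.null(times)) times <- seq_len(nf) - 1
  stopifnot(length(times) == nf)

  as_det <- function(d) {
    if (is.null(d)) return(data.frame(x = numeric(), y = numeric(),
                                      label = integer()))
    d <- as.data.frame(d)
    if (is.null(d$label)) d$label <- seq_len(nrow(d))
    d[, c("x", "y", "label")]
  }

  rows <- list()
  # active track state
  act_id <- integer(); act_x <- numeric(); act_y <- numeric()
  act_miss <- integer()
  next_id <- 1L

  for (f in seq_len(nf)) {
    det <- as_det(detections[[f]])
    nd <- nrow(det); nt <- length(act_id)
    match_track <- rep(NA_integer_, nd)   # index into active tracks
    if (nd > 0 && nt > 0) {
      dx <- outer(act_x, det$x, "-"); dy <- outer(act_y, det$y, "-")
      D <- sqrt(dx^2 + dy^2)
      if (method == "greedy") {
        cand <- which(D <= max_disp, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(D[cand], cand[, 2], cand[, 1])
          used_t <- rep(FALSE, nt); used_d <- rep(FALSE, nd)
          for (k in ord) {
            ti <- cand[k, 1]; di <- cand[k, 2]
            if (!used_t[ti] && !used_d[di]) {
              used_t[ti] <- TRUE; used_d[di] <- TRUE
              match_track[di] <- ti
            }
          }
        }
      } else {
        BIG <- 1e7
        C <- D
        C[C > max_disp] <- BIG
        asg <- solve_assignment(C, BIG)
        for (ti in seq_len(nt)) {
          di <- asg[ti]
          if (!is.na(di) && D[ti, di] <= max_disp) match_track[di] <- ti
        }
      }
    }
    # update matched tracks / spawn new ones
    ids <- integer(nd)
    for (di in seq_len(nd)) {
      ti <- match_track[di]
      if (!is.na(ti)) {
        ids[di] <- act_id[ti]
        act_x[ti] <- det$x[di]; act_y[ti] <- det$y[di]; act_miss[ti] <- -1L
      } else {
        ids[di] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, det$x[di]); act_y <- c(act_y, det$y[di])
        act_miss <- c(act_miss, -1L)
        next_id <- next_id + 1L
      }
    }
    if (nd > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        track_id = ids, frame = f - 1L, time_s = times[f],
        x_um = det$x, y_um = det$y, label = det$label)
    }
    if (length(act_id)) {
      act_miss <- act_miss + 1L
      keep <- act_miss <= memory
      act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
      act_miss <- act_miss[keep]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), time_s = numeric(),
               x_um = numeric(), y_um = numeric(), label = integer())
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square/rectangular assignment problem on a finite cost
#' matrix in O(n^3). Rows in excess of columns (or vice versa) and pairs at
#' the sentinel cost `big` are reported as unmatched.
#'
#' @param cost Numeric matrix (rows assigned to columns), finite entries;
#'   use `big` for forbidden pairs.
#' @param big Sentinel cost marking forbidden pairs.
#' @return Integer vector: for each row, the assigned column or NA.
#' @export
solve_assignment <- function(cost, big = 1e7) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  C <- matrix(big, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  # Potentials-based Hungarian; column index 0 is a virtual column.
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)     # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)   # way[j+1] = predecessor column of column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- C[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= nr && j <= nc && C[i, j] < big) ans[i] <- j
  }
  ans
}
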