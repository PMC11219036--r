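# Synthetic FxM experiment generator.
#
# Emulates time lapses of dye-excluding cells migrating in a shallow
# microfluidic chamber: a multiplicative illumination (flatfield) surface,
# an additive camera offset (darkfield), opaque support pillars, a
# persistent-random-walk motility program that switches at stimulation,
# and a biphasic volume program (spreading dip, then saturating swelling,
# with minute-scale fluctuations). Every rendered cell carries pixel-exact
# ground truth, so the analysis modules can be validated by recovery.

#' Configuration for a synthetic FxM experiment
#'
#' Defaults describe a resting-then-stimulated neutrophil experiment in a
#' 6 um chamber imaged every 10 s: quiescent cells before stimulation, a
#' motile persistent random walk afterwards, a spreading-induced volume dip
#' of 6% over the first two minutes, and swelling that saturates 15% above
#' baseline with a ~4 min time constant so the population reaches its
#' swollen plateau within ~20 min of stimulation.
#'
#' @param fov_rows,fov_cols Field of view in pixels.
#' @param pixel_size Pixel size, um/px.
#' @param chamber_height Chamber height, um.
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames.
#' @param stim_frame 0-based frame index at which the chemoattractant is
#'   released; stimulation time is `stim_frame * frame_interval` seconds.
#' @param darkfield_level Camera offset, intensity units.
#' @param flatfield_amplitude Peak fractional deviation of the multiplicative
#'   illumination surface from 1.
#' @param alpha_true Intensity units per um of dye column.
#' @param noise_sd Additive Gaussian noise on the FxM channel, intensity
#'   units. The default is 1% of the full dye column signal.
#' @param n_cells Number of cells.
#' @param pillar_centers Two-column matrix of pillar centres, (row, col) px.
#' @param pillar_radius Pillar radius, px.
#' @param motility List with `speed_pre`, `speed_post` (um/min) and
#'   `turn_sd` (radians per frame step).
#' @param volume_program List with `V0_median` (um^3), `V0_cv`,
#'   `dip_fraction`, `dip_duration` (s), `swell_fraction`, `swell_tau` (s),
#'   `fluct_amplitude`, `fluct_period` (s).
#' @param dome_aspect Cell shape parameter: peak height / footprint radius
#'   of the dome before ceiling clipping.
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical datasets.
#' @return A validated list of class `fxm_sim_config`.
#' @export
sim_config <- function(fov_rows = 600L, fov_cols = 600L,
                       pixel_size = 0.65, chamber_height = 6,
                       frame_interval = 10, n_frames = 120L,
                       stim_frame = 30L,
                       darkfield_level = 100, flatfield_amplitude = 0.2,
                       alpha_true = 100, noise_sd = 6,
                       n_cells = 50L,
                       pillar_centers = rbind(c(150, 150), c(150, 450),
                                              c(450, 150), c(450, 450)),
                       pillar_radius = 15,
                       motility = list(speed_pre = 0.5, speed_post = 12,
                                       turn_sd = 0.2),
                       volume_program = list(V0_median = 350, V0_cv = 0.12,
                                             dip_fraction = 0.06,
                                             dip_duration = 120,
                                             swell_fraction = 0.15,
                                             swell_tau = 240,
                                             fluct_amplitude = 0.02,
                                             fluct_period = 60),
                       dome_aspect = 0.67,
                       seed = 1L) {
  cfg <- list(fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols),
              pixel_size = pixel_size, chamber_height = chamber_height,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              stim_frame = as.integer(stim_frame),
              darkfield_level = darkfield_level,
              flatfield_amplitude = flatfield_amplitude,
              alpha_true = alpha_true, noise_sd = noise_sd,
              n_cells = as.integer(n_cells),
              pillar_centers = pillar_centers, pillar_radius = pillar_radius,
              motility = motility, volume_program = volume_program,
              dome_aspect = dome_aspect, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "fxm_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$chamber_height > 0, cfg$pixel_size > 0,
            cfg$n_frames >= 1, cfg$frame_interval > 0,
            cfg$alpha_true > 0, cfg$noise_sd >= 0,
            cfg$flatfield_amplitude >= 0, cfg$n_cells >= 0,
            cfg$dome_aspect > 0)
  vp <- cfg$volume_program
  if (vp$dip_fraction < 0 || vp$dip_fraction >= 1)
    stop("dip_fraction must be in [0, 1)")
  if (vp$swell_fraction < 0) stop("swell_fraction must be >= 0")
  if (cfg$motility$speed_pre < 0 || cfg$motility$speed_post < 0)
    stop("speeds must be >= 0")
  invisible(cfg)
}

#' Multiplicative volume factor of the biphasic volume program
#'
#' Before stimulation the factor is 1 plus a sinusoidal fluctuation term.
#' From stimulation the factor dips by `dip_fraction` (half-sine over
#' `dip_duration`, modelling spreading-induced volume loss) and then rises
#' with time constant `swell_tau` to saturate at `1 + swell_fraction`.
#'
#' @param t_rel Time relative to stimulation, s (vectorised).
#' @param program Volume program list, see [sim_config()].
#' @param phase Phase of the fluctuation term, radians.
#' @return Dimensionless multiplicative factor, same length as `t_rel`.
#' @export
volume_schedule <- function(t_rel, program, phase = 0) {
  stopifnot(program$dip_fraction >= 0, program$dip_fraction < 1,
            program$swell_fraction >= 0)
  base <- rep(1, length(t_rel))
  post <- t_rel >= 0
  if (any(post)) {
    tp <- t_rel[post]
    dip <- ifelse(tp < program$dip_duration,
                  program$dip_fraction * sin(pi * tp / program$dip_duration),
                  0)
    swell <- program$swell_fraction *
      (1 - exp(-pmax(tp - program$dip_duration, 0) / program$swell_tau))
    base[post] <- 1 - dip + swell
  }
  fluct <- if (program$fluct_amplitude > 0) {
    program$fluct_amplitude * sin(2 * pi * t_rel / program$fluct_period + phase)
  } else 0
  base + fluct
}

#' Simulate a persistent random walk track
#'
#' Headings perform a wrapped Gaussian random walk with step standard
#' deviation `turn_sd`; step length is `speed * dt`. Positions reflect at
#' the arena boundary.
#'
#' @param n_frames Number of positions to generate.
#' @param speed_schedule Speed per frame, um/min (length 1 or `n_frames`).
#' @param turn_sd Heading increment SD, radians per step.
#' @param arena Extent `c(xmin, xmax, ymin, ymax)` in um.
#' @param dt Frame interval, s.
#' @param start Starting position `c(x, y)` um; default arena centre.
#' @param heading0 Initial heading, radians; default drawn uniformly.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return `n_frames x 2` matrix of (x, y) positions in um.
#' @export
simulate_track <- function(n_frames, speed_schedule, turn_sd,
                           arena = c(0, 500, 0, 500), dt = 10,
                           start = NULL, heading0 = NULL, seed = NULL) {
  stopifnot(n_frames >= 1)
  speed <- rep_len(speed_schedule, n_frames)
  if (any(speed < 0)) stop("speeds must be >= 0")
  run <- function() {
    if (is.null(start)) start <- c(mean(arena[1:2]), mean(arena[3:4]))
    h <- if (is.null(heading0)) stats::runif(1, 0, 2 * pi) else heading0
    pos <- matrix(NA_real_, n_frames, 2)
    pos[1, ] <- start
    if (n_frames > 1) {
      for (k in 2:n_frames) {
        if (turn_sd > 0) h <- h + stats::rnorm(1, 0, turn_sd)
        step <- speed[k - 1] * dt / 60
        p <- pos[k - 1, ] + step * c(cos(h), sin(h))
        refl <- reflect_point(p, h, arena)
        pos[k, ] <- refl$p
        h <- refl$h
      }
    }
    colnames(pos) <- c("x", "y")
    pos
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Reflect a point (and its heading) into the arena.
reflect_point <- function(p, h, arena) {
  for (iter in 1:10) {
    moved <- FALSE
    if (p[1] < arena[1]) { p[1] <- 2 * arena[1] - p[1]; h <- pi - h; moved <- TRUE }
    if (p[1] > arena[2]) { p[1] <- 2 * arena[2] - p[1]; h <- pi - h; moved <- TRUE }
    if (p[2] < arena[3]) { p[2] <- 2 * arena[3] - p[2]; h <- -h; moved <- TRUE }
    if (p[2] > arena[4]) { p[2] <- 2 * arena[4] - p[2]; h <- -h; moved <- TRUE }
    if (!moved) break
  }
  list(p = p, h = h)
}

# Volume of a ceiling-clipped dome h(r) = h_peak * (1 - (r/R)^2)^1.5 with
# h_peak = aspect * R, clipped at h_chamber. Closed form.
dome_volume <- function(R, aspect, h_chamber) {
  h_peak <- aspect * R
  if (h_peak <= h_chamber) return(0.4 * pi * aspect * R^3)
  q <- (h_chamber / h_peak)^(2 / 3)
  pi * R^2 * ((1 - q) * h_chamber + 0.4 * h_peak * q^2.5)
}

# Footprint radius achieving a target volume, by 1-D root finding
# (relative tolerance 1e-6).
dome_radius <- function(volume, aspect, h_chamber) {
  upper <- max((volume / (0.4 * pi * aspect))^(1 / 3) * 3,
               sqrt(volume / (pi * h_chamber)) * 3, 1)
  stats::uniroot(function(R) dome_volume(R, aspect, h_chamber) - volume,
                 lower = 1e-6, upper = upper,
                 tol = 1e-6 * upper)$root
}

# Rasterise a dome cell onto the pixel grid. Returns a crop
# (row/col index vectors plus the height matrix in um), or NULL if the
# footprint misses the FOV entirely. Pixel (r, c) sits at physical
# coordinates x = (c-1)*ps, y = (r-1)*ps.
rasterize_dome <- function(x_um, y_um, R, aspect, h_chamber, pixel_size,
                           fov_rows, fov_cols) {
  ps <- pixel_size
  r0 <- max(1L, floor(y_um / ps) - ceiling(R / ps))
  r1 <- min(fov_rows, ceiling(y_um / ps) + ceiling(R / ps) + 2L)
  c0 <- max(1L, floor(x_um / ps) - ceiling(R / ps))
  c1 <- min(fov_cols, ceiling(x_um / ps) + ceiling(R / ps) + 2L)
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  yy <- (rows - 1) * ps - y_um
  xx <- (cols - 1) * ps - x_um
  rr2 <- outer(yy^2, xx^2, "+")
  u2 <- rr2 / R^2
  h <- aspect * R * pmax(0, 1 - u2)^1.5
  h <- pmin(h, h_chamber)
  if (!any(h > 0)) return(NULL)
  list(rows = rows, cols = cols, h = matrix(h, length(rows), length(cols)))
}

#' Pillar mask for a simulation configuration
#' @param config A [sim_config()] object.
#' @return Logical matrix, TRUE over pillars.
#' @export
pillar_mask_from_config <- function(config) {
  m <- matrix(FALSE, config$fov_rows, config$fov_cols)
  pc <- config$pillar_centers
  if (is.null(pc) || !nrow(pc)) return(m)
  rows <- matrix(seq_len(config$fov_rows), config$fov_rows, config$fov_cols)
  cols <- matrix(seq_len(config$fov_cols), config$fov_rows, config$fov_cols,
                 byrow = TRUE)
  for (k in seq_len(nrow(pc))) {
    m <- m | ((rows - pc[k, 1])^2 + (cols - pc[k, 2])^2 <=
                config$pillar_radius^2)
  }
  m
}

# Smooth random illumination surface: a sum of three low-frequency 2-D
# cosine modes, rescaled so the peak fractional deviation from 1 equals
# flatfield_amplitude. Must be called inside a seeded RNG scope.
make_flatfield <- function(config) {
  nr <- config$fov_rows; nc <- config$fov_cols
  if (config$flatfield_amplitude <= 0) return(matrix(1, nr, nc))
  r <- (seq_len(nr) - 1) / nr
  c <- (seq_len(nc) - 1) / nc
  S <- matrix(0, nr, nc)
  for (k in 1:3) {
    fr <- stats::runif(1, 0.3, 1.2) * sample(c(-1, 1), 1)
    fc <- stats::runif(1, 0.3, 1.2) * sample(c(-1, 1), 1)
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    S <- S + amp * (cos(2 * pi * fr * r + ph[1]) %o%
                      cos(2 * pi * fc * c + ph[2]))
  }
  1 + config$flatfield_amplitude * S / max(abs(S))
}

#' Render one multi-channel FxM frame
#'
#' The FxM channel follows the dye-exclusion imaging model: signal =
#' darkfield + flatfield x alpha x (remaining dye column height), with a dye
#' column of zero over pillars, plus additive Gaussian noise. The nuclear
#' channel carries one Gaussian spot per cell at the height-weighted
#' centroid; the cytoplasmic channel is the filled footprint at constant
#' brightness.
#'
#' @param height_maps List of cell height maps: either full-frame matrices
#'   (um) or crops as produced internally (`list(rows, cols, h)`).
#' @param config A [sim_config()] object.
#' @param flatfield Illumination surface matrix; default all-ones.
#' @param seed Optional seed for the noise draws.
#' @return List with `fxm`, `nuclear`, `cyto` matrices and `height` (the
#'   composed, ceiling-clipped cell height map).
#' @export
render_frame <- function(height_maps, config, flatfield = NULL, seed = NULL) {
  nr <- config$fov_rows; nc <- config$fov_cols
  if (is.null(flatfield)) flatfield <- matrix(1, nr, nc)
  H <- matrix(0, nr, nc)
  centroids <- NULL
  for (hm in height_maps) {
    if (is.matrix(hm)) hm <- full_to_crop(hm)
    if (is.null(hm)) next
    if (max(hm$h) > config$chamber_height + 1e-9)
      stop("cell height exceeds chamber_height")
    H[hm$rows, hm$cols] <- H[hm$rows, hm$cols] + hm$h
    w <- hm$h / sum(hm$h)
    centroids <- rbind(centroids,
                       c(sum(rowSums(w) * hm$rows), sum(colSums(w) * hm$cols)))
  }
  Hc <- pmin(H, config$chamber_height)
  pil <- pillar_mask_from_config(config)
  column <- config$chamber_height - Hc
  column[pil] <- 0
  draw <- function() {
    fxm <- config$darkfield_level + flatfield * config$alpha_true * column
    if (config$noise_sd > 0)
      fxm <- fxm + stats::rnorm(nr * nc, 0, config$noise_sd)
    nuc <- matrix(10, nr, nc)
    if (!is.null(centroids)) {
      for (k in seq_len(nrow(centroids))) {
        sp <- gaussian_spot(centroids[k, 1], centroids[k, 2], 3, nr, nc)
        if (!is.null(sp)) nuc[sp$rows, sp$cols] <- nuc[sp$rows, sp$cols] +
            200 * sp$g
      }
    }
    nuc <- nuc + stats::rnorm(nr * nc, 0, 2)
    cyto <- 10 + 150 * (H > 0) + stats::rnorm(nr * nc, 0, 2)
    list(fxm = matrix(fxm, nr, nc), nuclear = nuc,
         cyto = matrix(cyto, nr, nc), height = Hc)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

full_to_crop <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  rows <- min(idx[, 1]):max(idx[, 1])
  cols <- min(idx[, 2]):max(idx[, 2])
  list(rows = rows, cols = cols, h = m[rows, cols, drop = FALSE])
}

gaussian_spot <- function(row, col, sd, nr, nc, extent = 4) {
  r0 <- max(1L, floor(row - extent * sd)); r1 <- min(nr, ceiling(row + extent * sd))
  c0 <- max(1L, floor(col - extent * sd)); c1 <- min(nc, ceiling(col + extent * sd))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  g <- exp(-outer((rows - row)^2, (cols - col)^2, "+") / (2 * sd^2))
  list(rows = rows, cols = cols, g = g)
}

#' Simulate a full synthetic FxM experiment
#'
#' Composes the motility and volume programs, rasterises every cell on
#' every frame, renders the three imaging channels, and records pixel-exact
#' ground truth (the true volume of a cell-frame is defined as
#' `pixel_size^2` times the sum of its rasterised height map). Cells repel
#' each other and the pillars during the walk so footprints stay disjoint.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `fxm_dataset`: channel stacks (lists of
#'   matrices), `darkfield`, `pillar_mask`, `flatfield`, `timestamps`,
#'   `config`, and `truth` (a per-cell-frame data frame plus footprint
#'   crops).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  nr <- config$fov_rows; nc <- config$fov_cols
  ps <- config$pixel_size
  n <- config$n_cells
  nf <- config$n_frames
  stim_time <- config$stim_frame * config$frame_interval
  timestamps <- (seq_len(nf) - 1) * config$frame_interval
  vp <- config$volume_program

  with_seed(config$seed, {
    FF <- make_flatfield(config)
    DF <- matrix(config$darkfield_level, nr, nc)
    pil <- pillar_mask_from_config(config)

    V0 <- if (n > 0) {
      sdlog <- sqrt(log(1 + vp$V0_cv^2))
      vp$V0_median * exp(stats::rnorm(n, 0, sdlog))
    } else numeric()
    phase <- if (n > 0) stats::runif(n, 0, 2 * pi) else numeric()

    # conservative per-cell footprint radius at maximal volume
    Rmax <- vapply(V0, function(v)
      dome_radius(v * (1 + vp$swell_fraction + vp$fluct_amplitude + 0.02),
                  config$dome_aspect, config$chamber_height), numeric(1))

    extent_x <- (nc - 1) * ps; extent_y <- (nr - 1) * ps
    pil_xy <- if (!is.null(config$pillar_centers) &&
                  nrow(config$pillar_centers)) {
      cbind((config$pillar_centers[, 2] - 1) * ps,
            (config$pillar_centers[, 1] - 1) * ps)
    } else matrix(numeric(), 0, 2)
    pil_r_um <- config$pillar_radius * ps

    ok_place <- function(p, others, R, Rothers) {
      if (nrow(pil_xy) &&
          any(sqrt((pil_xy[, 1] - p[1])^2 + (pil_xy[, 2] - p[2])^2) <
                pil_r_um + R + 1)) return(FALSE)
      if (!is.null(others) && nrow(others) &&
          any(sqrt((others[, 1] - p[1])^2 + (others[, 2] - p[2])^2) <
                R + Rothers + 1.5)) return(FALSE)
      TRUE
    }

    # initial placement by rejection sampling
    pos <- matrix(NA_real_, n, 2)
    if (n > 0) {
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in 1:2000) {
          p <- c(stats::runif(1, Rmax[i] + 2, extent_x - Rmax[i] - 2),
                 stats::runif(1, Rmax[i] + 2, extent_y - Rmax[i] - 2))
          prev <- if (i > 1) pos[1:(i - 1), , drop = FALSE] else NULL
          if (ok_place(p, prev, Rmax[i], if (i > 1) Rmax[1:(i - 1)] else numeric())) {
            pos[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) stop("cells denser than packable in FOV")
      }
    }

    # joint persistent random walk with mutual and pillar avoidance
    heading <- if (n > 0) stats::runif(n, 0, 2 * pi) else numeric()
    xs <- matrix(NA_real_, nf, max(n, 1))
    ys <- matrix(NA_real_, nf, max(n, 1))
    if (n > 0) { xs[1, 1:n] <- pos[, 1]; ys[1, 1:n] <- pos[, 2] }
    mo <- config$motility
    if (nf > 1 && n > 0) {
      for (f in 2:nf) {
        speed <- if ((f - 2) < config$stim_frame) mo$speed_pre else mo$speed_post
        step <- speed * config$frame_interval / 60
        for (i in seq_len(n)) {
          if (mo$turn_sd > 0)
            heading[i] <- heading[i] + stats::rnorm(1, 0, mo$turn_sd)
          p <- pos[i, ] + step * c(cos(heading[i]), sin(heading[i]))
          refl <- reflect_point(p, heading[i],
                                c(Rmax[i] + 1, extent_x - Rmax[i] - 1,
                                  Rmax[i] + 1, extent_y - Rmax[i] - 1))
          p <- refl$p
          others <- pos[-i, , drop = FALSE]
          if (ok_place(p, others, Rmax[i], Rmax[-i])) {
            pos[i, ] <- p; heading[i] <- refl$h
          } else {
            heading[i] <- stats::runif(1, 0, 2 * pi)
          }
        }
        xs[f, 1:n] <- pos[, 1]; ys[f, 1:n] <- pos[, 2]
      }
    }

    # volumes, rasterisation, rendering
    fxm <- vector("list", nf); nuclear <- vector("list", nf)
    cyto <- vector("list", nf)
    footprints <- if (n > 0) {
      lapply(seq_len(n), function(i) vector("list", nf))
    } else list()
    truth_rows <- vector("list", nf)
    for (f in seq_len(nf)) {
      t_rel <- timestamps[f] - stim_time
      crops <- list()
      rec <- NULL
      for (i in seq_len(n)) {
        Vtarget <- V0[i] * volume_schedule(t_rel, vp, phase[i])
        R <- dome_radius(Vtarget, config$dome_aspect, config$chamber_height)
        cr <- rasterize_dome(xs[f, i], ys[f, i], R, config$dome_aspect,
                             config$chamber_height, ps, nr, nc)
        footprints[[i]][[f]] <- cr
        crops[[length(crops) + 1]] <- cr
        vtrue <- if (is.null(cr)) 0 else ps^2 * sum(cr$h)
        rec <- rbind(rec, c(i, f - 1, xs[f, i], ys[f, i], vtrue))
      }
      fr <- render_frame(crops[!vapply(crops, is.null, logical(1))],
                         config, flatfield = FF)
      fxm[[f]] <- fr$fxm; nuclear[[f]] <- fr$nuclear; cyto[[f]] <- fr$cyto
      truth_rows[[f]] <- rec
    }
    truth <- do.call(rbind, truth_rows)
    cells <- if (is.null(truth)) {
      data.frame(cell_id = integer(), frame = integer(), x_um = numeric(),
                 y_um = numeric(), true_volume_um3 = numeric())
    } else {
      data.frame(cell_id = as.integer(truth[, 1]),
                 frame = as.integer(truth[, 2]),
                 x_um = truth[, 3], y_um = truth[, 4],
                 true_volume_um3 = truth[, 5])
    }
    structure(list(
      fxm = fxm, nuclear = nuclear, cyto = cyto,
      darkfield = DF, pillar_mask = pil, flatfield = FF,
      timestamps = timestamps, stim_time = stim_time, config = config,
      truth = list(cells = cells, footprints = footprints,
                   flatfield = FF, darkfield = DF, pillar_mask = pil)),
      class = "fxm_dataset")
  })
}

#' @export
print.fxm_dataset <- function(x, ...) {
  cat(sprintf("fxm_dataset: %d frames of %dx%d px, %d cells, stim at %g s\n",
              length(x$fxm), x$config$fov_rows, x$config$fov_cols,
              x$config$n_cells, x$stim_time))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one multi-page 16-bit TIFF per channel (intensities divided by a
#' per-run scale recorded in `config.yaml`), darkfield / pillar-mask /
#' flatfield TIFFs, a `timestamps.csv` (frame, time_s) and a
#' `ground_truth.csv` (cell_id, frame, x_um, y_um, true_volume_um3).
#'
#' @param dataset An `fxm_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(vapply(dataset$fxm, max, numeric(1)),
               vapply(dataset$nuclear, max, numeric(1)),
               vapply(dataset$cyto, max, numeric(1)),
               max(dataset$darkfield), 1) * 1.01
  # rare below-zero noise excursions clip at 0, as on a real detector
  wstack <- function(stack, file)
    tiff::writeTIFF(lapply(stack, function(m) pmax(m, 0) / scale),
                    file.path(dir, file), bits.per.sample = 16)
  wstack(dataset$fxm, "fxm.tif")
  wstack(dataset$nuclear, "nuclear.tif")
  wstack(dataset$cyto, "cyto.tif")
  tiff::writeTIFF(dataset$darkfield / scale, file.path(dir, "darkfield.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(dataset$pillar_mask * 1, file.path(dir, "pillar_mask.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(dataset$flatfield / max(dataset$flatfield) ,
                  file.path(dir, "flatfield.tif"), bits.per.sample = 16)
  utils::write.csv(data.frame(frame = seq_along(dataset$timestamps) - 1L,
                              time_s = dataset$timestamps),
                   file.path(dir, "timestamps.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  meta <- list(pixel_size = dataset$config$pixel_size,
               chamber_height = dataset$config$chamber_height,
               stim_time = dataset$stim_time,
               frame_interval = dataset$config$frame_interval,
               n_frames = dataset$config$n_frames,
               io_scale = scale,
               seed = dataset$config$seed)
  writeLines(yaml::as.yaml(meta), file.path(dir, "config.yaml"))
  invisible(dir)
}
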