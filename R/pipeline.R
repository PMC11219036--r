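# Pipeline orchestration: configuration, dataset I/O, the full
# segment -> link -> correct -> calibrate -> measure -> summarise run,
# and CSV/manifest output.

#' Analysis-stage parameters for the FxM pipeline
#'
#' @param seg [seg_params()].
#' @param link List: `max_disp` (um), `memory` (frames), `method`.
#'   Defaults suit neutrophil speeds of up to ~20 um/min at 10 s frames
#'   (under 3.5 um per frame of displacement).
#' @param flatfield List: `n_points`, `n_periods`, `margin` (px), `eps`,
#'   `lambda`, `grid_step` (px), `exclusion_dilation` (px; cells and
#'   pillars are dilated by this much before background sampling), and
#'   `sample_sigma` (px; the illumination surface is smooth, so sample
#'   values are read from a more strongly smoothed copy of the frame,
#'   which keeps sample noise out of the interpolant).
#' @param volumetry List: `annulus_inner`, `annulus_outer` (px),
#'   `min_annulus` (px), `rolling_window` (frames), `baseline_window` (s).
#' @param motility List: `tau` (frames), `distance_offset` (um).
#' @return List of class `fxm_pipeline_params`.
#' @export
pipeline_params <- function(seg = seg_params(),
                            link = list(max_disp = 15, memory = 2,
                                        method = "greedy"),
                            flatfield = list(n_points = 200, n_periods = 4,
                                             margin = 10, eps = NULL,
                                             lambda = 1e-8, grid_step = 4,
                                             exclusion_dilation = 3,
                                             sample_sigma = 2),
                            volumetry = list(annulus_inner = 2,
                                             annulus_outer = 10,
                                             min_annulus = 30,
                                             rolling_window = 7,
                                             baseline_window = 120),
                            motility = list(tau = 3, distance_offset = 10)) {
  structure(list(seg = seg, link = link, flatfield = flatfield,
                 volumetry = volumetry, motility = motility),
            class = "fxm_pipeline_params")
}

#' Convert a synthetic dataset to an analysis-ready frameset
#'
#' @param dataset An `fxm_dataset` from [simulate_experiment()].
#' @return List of class `fxm_frameset` with channel stacks, masks,
#'   timestamps and physical metadata.
#' @export
as_frameset <- function(dataset) {
  stopifnot(inherits(dataset, "fxm_dataset"))
  structure(list(fxm = dataset$fxm, nuclear = dataset$nuclear,
                 cyto = dataset$cyto, darkfield = dataset$darkfield,
                 pillar_mask = dataset$pillar_mask,
                 timestamps = dataset$timestamps,
                 pixel_size = dataset$config$pixel_size,
                 chamber_height = dataset$config$chamber_height,
                 stim_time = dataset$stim_time,
                 seed = dataset$config$seed),
            class = "fxm_frameset")
}

#' Load a dataset directory into a frameset
#'
#' Reads the channel stacks, darkfield, pillar mask, timestamps and
#' physical metadata written by [write_dataset()] (or arranged in the same
#' layout). Image values are promoted to double and rescaled by the
#' recorded intensity scale. Physical coordinates attach at pixel centres:
#' `x = col * pixel_size`, `y = row * pixel_size`, 0-based, y increasing
#' downward.
#'
#' @param dir Dataset directory.
#' @return An `fxm_frameset`.
#' @export
load_frameset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing channel or file: ", f)
    p
  }
  meta <- yaml::read_yaml(need("config.yaml"))
  scale <- if (is.null(meta$io_scale)) 1 else meta$io_scale
  rstack <- function(f) {
    pages <- tiff::readTIFF(need(f), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) matrix(as.numeric(m) * scale,
                                     nrow(m), ncol(m)))
  }
  fxm <- rstack("fxm.tif"); nuclear <- rstack("nuclear.tif")
  cyto <- rstack("cyto.tif")
  dims <- lapply(c(fxm, nuclear, cyto), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("channel stacks differ in shape")
  if (length(nuclear) != length(fxm) || length(cyto) != length(fxm))
    stop("channel stacks differ in frame count")
  df <- tiff::readTIFF(need("darkfield.tif"))
  darkfield <- matrix(as.numeric(df) * scale, nrow(df), ncol(df))
  pm <- tiff::readTIFF(need("pillar_mask.tif"))
  pillar <- matrix(as.numeric(pm) > 0.5, nrow(pm), ncol(pm))
  ts <- utils::read.csv(need("timestamps.csv"))
  if (nrow(ts) != length(fxm))
    stop(sprintf("timestamps (%d) do not match frame count (%d)",
                 nrow(ts), length(fxm)))
  if (any(is.na(ts$time_s)))
    stop("missing timestamp for frame ",
         paste(ts$frame[is.na(ts$time_s)], collapse = ", "))
  if (any(diff(ts$time_s) <= 0)) stop("timestamps are not strictly increasing")
  structure(list(fxm = fxm, nuclear = nuclear, cyto = cyto,
                 darkfield = darkfield, pillar_mask = pillar,
                 timestamps = ts$time_s,
                 pixel_size = meta$pixel_size,
                 chamber_height = meta$chamber_height,
                 stim_time = meta$stim_time,
                 seed = meta$seed),
            class = "fxm_frameset")
}

#' Run the full FxM analysis pipeline
#'
#' Per frame: denoise, Scharr edge magnitudes, log-normal threshold with
#' border flood fill into a foreground mask, nuclear seed detection.
#' Seeds are linked in time, labelled instances are grown from the tracked
#' seeds inside the foreground, the frame is flatfield-corrected with a
#' multiquadric background model, the pillar/background medians calibrate
#' alpha, and each cell-frame yields a local background, footprint area and
#' excluded volume. Volume traces are normalised to the pre-stimulation
#' baseline; velocities and angular alignment are computed per track, and
#' population summaries per timepoint. Per-cell-frame failures (occluded
#' locality, edge-touching cells) are recorded, not fatal.
#'
#' @param frameset An `fxm_frameset`.
#' @param params [pipeline_params()].
#' @param output_dir Optional directory to write the result tables to.
#' @param replicate Replicate identifier used in population summaries.
#' @param verbose Print per-stage progress.
#' @return Object of class `fxm_result`: `tracks`, `volumes`, `motility`,
#'   `summary_volume`, `summary_velocity`, `calibration`, `manifest`.
#' @export
run_pipeline <- function(frameset, params = pipeline_params(),
                         output_dir = NULL, replicate = "r1",
                         verbose = FALSE) {
  stopifnot(inherits(frameset, "fxm_frameset"))
  t_start <- proc.time()[["elapsed"]]
  nf <- length(frameset$fxm)
  ps <- frameset$pixel_size
  times <- frameset$timestamps
  if (!any(times >= frameset$stim_time - params$volumetry$baseline_window &
             times < frameset$stim_time))
    stop("baseline undefined")
  say <- function(...) if (verbose) message(sprintf(...))

  say("segmenting %d frames", nf)
  fgs <- vector("list", nf)
  seeds <- vector("list", nf)
  dens <- vector("list", nf)
  for (f in seq_len(nf)) {
    dens[[f]] <- denoise(frameset$fxm[[f]], params$seg$denoise_sigma)
    mag <- edge_magnitude(dens[[f]])
    fgs[[f]] <- threshold_foreground(mag, params$seg, frameset$pillar_mask)
    seeds[[f]] <- detect_seeds(frameset$nuclear[[f]], params$seg)
  }

  say("linking")
  detections <- lapply(seeds, function(s)
    data.frame(x = (s$col - 1) * ps, y = (s$row - 1) * ps,
               label = s$seed_id))
  tracks <- link_tracks(detections, times = times,
                        max_disp = params$link$max_disp,
                        memory = params$link$memory,
                        method = params$link$method)

  say("instances, flatfield, volumes")
  pil_dil <- dilate_mask(frameset$pillar_mask,
                         params$flatfield$exclusion_dilation)
  pil_core <- erode_mask(frameset$pillar_mask, 2)
  if (!any(pil_core)) pil_core <- frameset$pillar_mask
  cal_rows <- vector("list", nf)
  vol_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr_tracks <- tracks[tracks$frame == f - 1L, , drop = FALSE]
    sd_f <- seeds[[f]]
    lab <- matrix(0L, nrow(frameset$fxm[[f]]), ncol(frameset$fxm[[f]]))
    if (nrow(fr_tracks)) {
      seed_df <- data.frame(row = sd_f$row[fr_tracks$label],
                            col = sd_f$col[fr_tracks$label],
                            label = fr_tracks$track_id)
      lab <- suppressWarnings(split_instances(fgs[[f]], seed_df))$labels
    }
    excl <- dilate_mask(fgs[[f]], params$flatfield$exclusion_dilation) |
      pil_dil
    pts <- sample_background_points(dim(frameset$fxm[[f]]), excl,
                                    n_points = params$flatfield$n_points,
                                    n_periods = params$flatfield$n_periods,
                                    margin = params$flatfield$margin)
    ffsrc <- if (params$flatfield$sample_sigma > params$seg$denoise_sigma) {
      denoise(frameset$fxm[[f]], params$flatfield$sample_sigma)
    } else dens[[f]]
    fld <- fit_background_field(pts, ffsrc[pts],
                                eps = params$flatfield$eps,
                                lambda = params$flatfield$lambda)
    corrected <- correct_frame(frameset$fxm[[f]], frameset$darkfield, fld,
                               grid_step = params$flatfield$grid_step)
    bg_mask <- !excl
    cal <- alpha_calibration(corrected, pil_core, bg_mask,
                             frameset$chamber_height)
    cal_rows[[f]] <- data.frame(frame = f - 1L, alpha = cal$alpha,
                                i_background = cal$i_background,
                                i_pillar = cal$i_pillar)
    if (nrow(fr_tracks)) {
      rows <- lapply(seq_len(nrow(fr_tracks)), function(k) {
        id <- fr_tracks$track_id[k]
        pix <- which(lab == id)
        if (!length(pix))
          return(data.frame(track_id = id, frame = f - 1L,
                            time_s = times[f], area_um2 = NA_real_,
                            imax = NA_real_, volume_um3 = NA_real_,
                            edge_touching = NA))
        lb <- tryCatch(
          local_background(corrected, lab, id, frameset$pillar_mask,
                           inner = params$volumetry$annulus_inner,
                           outer = params$volumetry$annulus_outer,
                           erode_by = params$seg$footprint_dilation_radius,
                           min_pixels = params$volumetry$min_annulus),
          error = function(e) list(imax = NA_real_, n_annulus = 0L,
                                   edge_touching = FALSE))
        v <- if (is.na(lb$imax)) NA_real_ else
          cell_volume(corrected, pix, lb$imax, cal$alpha, ps)
        data.frame(track_id = id, frame = f - 1L, time_s = times[f],
                   area_um2 = length(pix) * ps^2, imax = lb$imax,
                   volume_um3 = v, edge_touching = lb$edge_touching)
      })
      vol_rows[[f]] <- do.call(rbind, rows)
    }
  }
  calibration <- do.call(rbind, cal_rows)
  volumes <- if (length(vol_rows)) do.call(rbind, vol_rows[
    !vapply(vol_rows, is.null, logical(1))]) else NULL
  if (is.null(volumes))
    volumes <- data.frame(track_id = integer(), frame = integer(),
                          time_s = numeric(), area_um2 = numeric(),
                          imax = numeric(), volume_um3 = numeric(),
                          edge_touching = logical())

  say("traces and motility")
  volumes <- volumes[order(volumes$track_id, volumes$frame), , drop = FALSE]
  volumes$volume_norm <- NA_real_
  volumes$volume_rollmed_um3 <- NA_real_
  for (id in unique(volumes$track_id)) {
    sel <- which(volumes$track_id == id)
    tr <- tryCatch(
      build_volume_trace(volumes$volume_um3[sel], volumes$time_s[sel],
                         frameset$stim_time,
                         window = params$volumetry$rolling_window,
                         baseline_window = params$volumetry$baseline_window),
      error = function(e) NULL)
    if (!is.null(tr) && tr$baseline > 0) {
      volumes$volume_norm[sel] <- tr$trace$volume_norm
      volumes$volume_rollmed_um3[sel] <- tr$trace$volume_rollmed_um3
    }
  }
  volumes <- volumes[, c("track_id", "frame", "time_s", "area_um2", "imax",
                         "volume_um3", "volume_norm", "volume_rollmed_um3",
                         "edge_touching")]

  mot_rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    v <- track_velocity(tr$x_um, tr$y_um, tr$time_s,
                        tau = params$motility$tau)
    al <- angular_alignment(tr$x_um, tr$y_um,
                            distance_offset = params$motility$distance_offset)
    data.frame(track_id = tr$track_id, frame = tr$frame, time_s = tr$time_s,
               velocity_um_min = v, alignment = al,
               cumdist_um = cumulative_distance(tr$x_um, tr$y_um))
  })
  motility <- if (length(mot_rows)) do.call(rbind, mot_rows) else
    data.frame(track_id = integer(), frame = integer(), time_s = numeric(),
               velocity_um_min = numeric(), alignment = numeric(),
               cumdist_um = numeric())
  rownames(motility) <- NULL
  motility <- motility[order(motility$track_id, motility$frame), ,
                       drop = FALSE]

  summary_volume <- population_summary(data.frame(
    replicate = replicate, time_s = volumes$time_s,
    value = volumes$volume_norm))
  summary_velocity <- population_summary(data.frame(
    replicate = replicate, time_s = motility$time_s,
    value = motility$velocity_um_min))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fxmtools")),
    seed = frameset$seed,
    config_hash = config_hash(list(params = unclass(params),
                                   pixel_size = ps,
                                   chamber_height = frameset$chamber_height,
                                   stim_time = frameset$stim_time,
                                   n_frames = nf)),
    n_frames = nf,
    n_detections = sum(vapply(seeds, nrow, integer(1))),
    n_tracks = length(unique(tracks$track_id)),
    n_cell_frames = nrow(volumes),
    n_volumes_ok = sum(!is.na(volumes$volume_um3)),
    elapsed_s = round(proc.time()[["elapsed"]] - t_start, 2))

  result <- structure(list(tracks = tracks, volumes = volumes,
                           motility = motility,
                           summary_volume = summary_volume,
                           summary_velocity = summary_velocity,
                           calibration = calibration, manifest = manifest,
                           params = params),
                      class = "fxm_result")
  if (!is.null(output_dir)) write_result(result, output_dir)
  result
}

#' @export
print.fxm_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("fxm_result: %d frames, %d tracks, %d cell-frames ",
                     "(%d volumes), %.1f s\n"),
              m$n_frames, m$n_tracks, m$n_cell_frames, m$n_volumes_ok,
              m$elapsed_s))
  invisible(x)
}

#' Write pipeline result tables to a directory
#'
#' Writes `tracks.csv`, `volumes.csv`, `motility.csv`, `summary_volume.csv`,
#' `summary_velocity.csv`, `calibration.csv` and `manifest.yaml`. Missing
#' values are written as empty fields.
#'
#' @param result An `fxm_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE, na = "")
  w(result$tracks, "tracks.csv")
  w(result$volumes, "volumes.csv")
  w(result$motility, "motility.csv")
  w(result$summary_volume, "summary_volume.csv")
  w(result$summary_velocity, "summary_velocity.csv")
  w(result$calibration, "calibration.csv")
  writeLines(yaml::as.yaml(result$manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
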