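#' Per-trajectory motion report
#'
#' Computes the full set of motion statistics for one trajectory:
#' positional clustering (transitions, reversibility rate, cluster
#' betweenness), step/velocity summaries, overall diffusion coefficient,
#' and -- when a budding annotation is available -- windowed diffusion
#' coefficients and the hovering window. Without a budding annotation the
#' bud-related columns are `NA` and a warning is issued.
#'
#' @param traj a [trajectory()].
#' @param bud_time budding time in seconds, or `NULL`.
#' @param bud_site `c(x, y)` bud site in um, or `NULL`.
#' @param fit_lags lags for MSD fits.
#' @param seed seed for the k-means restarts.
#' @param ... passed to [windowed_diffusion()] and [detect_hovering()]
#'   (e.g. `window`, `mobility_window`).
#' @return One-row data frame with columns `n`, `duration_s`, `tau`,
#'   `R_rev`, `J4`, `mean_step_um`, `mean_velocity_um_s`, `D_um2_s`,
#'   `D_before`, `D_during`, `D_after`, `D_reduction`, `hovering`,
#'   `H_start_s`, `H_stop_s`, `T_hov_s`, `mean_bud_distance_um`.
#' @export
motion_report <- function(traj, bud_time = NULL, bud_site = NULL,
                          fit_lags = 1:4, seed = 1, ...) {
  n <- nrow(traj)
  cl <- cluster_positions(traj, k = 2, seed = seed)
  sv <- steps_and_velocities(traj)
  D_all <- tryCatch(
    diffusion_coefficient(msd(traj, max_lag = max(fit_lags)), fit_lags)$D,
    error = function(e) NA_real_)
  out <- data.frame(
    n = n, duration_s = traj$t[n] - traj$t[1],
    tau = cl$tau, R_rev = cl$R_rev, J4 = cl$J4,
    mean_step_um = mean(sv$step), mean_velocity_um_s = mean(sv$velocity),
    D_um2_s = D_all,
    D_before = NA_real_, D_during = NA_real_, D_after = NA_real_,
    D_reduction = NA_real_, hovering = NA,
    H_start_s = NA_real_, H_stop_s = NA_real_, T_hov_s = NA_real_,
    mean_bud_distance_um = NA_real_)
  extra <- list(...)
  if (is.null(bud_time)) {
    warning("no budding annotation: hovering and windowed diffusion omitted")
    return(out)
  }
  wd <- tryCatch(do.call(windowed_diffusion,
                         c(list(traj, bud_time, fit_lags = fit_lags),
                           extra[names(extra) %in% c("window", "min_points")])),
                 error = function(e) NULL)
  if (!is.null(wd)) {
    out$D_before <- wd$D_before; out$D_during <- wd$D_during
    out$D_after <- wd$D_after; out$D_reduction <- wd$reduction
  }
  hv <- tryCatch(do.call(detect_hovering,
                         c(list(traj, bud_time),
                           extra[names(extra) %in%
                                   c("mobility_window", "min_drop",
                                     "min_segment")])),
                 error = function(e) NULL)
  if (!is.null(hv)) {
    out$hovering <- hv$hovering
    out$H_start_s <- hv$H_start; out$H_stop_s <- hv$H_stop
    out$T_hov_s <- hv$T_hov
  }
  if (!is.null(bud_site)) {
    out$mean_bud_distance_um <- mean(bud_distance_series(traj, bud_site)$distance)
  }
  out
}

#' Run the full pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> detect -> segment -> link -> motion-report.
#' Every stage output is written to `out_dir` so later stages can be
#' re-run from cached results, and a machine-readable provenance record
#' (configuration, seed, package versions) accompanies the report.
#'
#' @param config a [sim_config()] describing the dataset.
#' @param det_params a [detection_params()].
#' @param seg_params a [segmentation_params()].
#' @param out_dir report directory (created if needed).
#' @param max_disp linking radius, um per frame.
#' @param fit_lags lags for MSD fits.
#' @param min_track_length tracks shorter than this (e.g. one-frame
#'   orphans from a missed detection) are written to `tracks.csv` but
#'   excluded from the motion report.
#' @param ... passed on to [motion_report()].
#' @return List with `spots`, `cells` (per-frame per-cell counts),
#'   `fraction` (P-body fraction time course), `tracks`, `report`
#'   (per-track motion statistics), `truth`, `paths`.
#' @export
run_pipeline <- function(config, det_params, seg_params, out_dir,
                         max_disp = 2, fit_lags = 1:4,
                         min_track_length = 5, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ds <- generate_dataset(config, out_dir = file.path(out_dir, "data"))

  stage <- function(msg) message("[pbtrack] ", msg)
  fail <- function(stage_name, e) {
    stop(sprintf("stage '%s' failed: %s", stage_name, conditionMessage(e)),
         call. = FALSE)
  }

  stage("detecting spots")
  spots <- tryCatch(
    detect_spots_movie(ds$frames, det_params,
                       pixel_size = config$pixel_size, dt = config$dt),
    error = function(e) fail("detect", e))
  write.csv(spots, file.path(out_dir, "spots.csv"), row.names = FALSE)

  stage("segmenting cells")
  counts <- tryCatch({
    do.call(rbind, lapply(seq_along(ds$stacks), function(i) {
      labels <- segment_cells(ds$stacks[[i]], seg_params)
      sp <- assign_spots_to_cells(labels, spots[spots$frame == i - 1L, ])
      cc <- cell_spot_counts(labels, sp)
      if (nrow(cc) == 0) {
        cc <- data.frame(cell_id = NA_integer_, area_px = NA_integer_,
                         cx_px = NA_real_, cy_px = NA_real_,
                         n_spots = NA_integer_)
      }
      cbind(frame = i - 1L, cc)
    }))
  }, error = function(e) fail("segment", e))
  write.csv(counts, file.path(out_dir, "cells.csv"), row.names = FALSE)
  fraction <- pb_fraction_timecourse(counts, dt = config$dt)
  write.csv(fraction, file.path(out_dir, "pb_fraction.csv"),
            row.names = FALSE)

  stage("linking trajectories")
  tracks <- tryCatch(link_spots(spots, max_disp = max_disp, dt = config$dt),
                     error = function(e) fail("link", e))
  tracks_df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frame, t_s = tr$t,
               x_um = tr$x, y_um = tr$y)
  }))
  write.csv(tracks_df, file.path(out_dir, "tracks.csv"), row.names = FALSE)

  stage("motion statistics")
  long_enough <- which(vapply(tracks, nrow, 1L) >= min_track_length)
  report <- tryCatch({
    do.call(rbind, lapply(long_enough, function(i) {
      tr <- tracks[[i]]
      # match track to the nearest ground-truth budding annotation (by
      # mean position); real data would use a manual annotation CSV here
      bud <- nearest_bud(tr, ds$truth$buds, ds$truth$cells, config)
      rep_i <- suppressWarnings(motion_report(
        tr, bud_time = bud$bud_time_s, bud_site = bud$bud_site,
        fit_lags = fit_lags, ...))
      cbind(track_id = i, cell_id = bud$cell_id, rep_i)
    }))
  }, error = function(e) fail("motion", e))
  write.csv(report, file.path(out_dir, "motion_report.csv"),
            row.names = FALSE)

  prov <- list(
    config = unclass(config),
    parameters = list(detection = unclass(det_params),
                      segmentation = unclass(seg_params),
                      max_disp = max_disp, fit_lags = fit_lags),
    versions = list(pbtrack = as.character(utils::packageVersion("pbtrack")),
                    R = R.version.string),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(spots = spots, cells = counts, fraction = fraction, tracks = tracks,
       report = report, truth = ds$truth,
       paths = list(dir = out_dir))
}

# nearest mother (by mean track position) and its budding annotation
nearest_bud <- function(tr, buds, cells, config) {
  mothers <- unique(cells[cells$type == "mother",
                          c("cell_id", "cx", "cy")])
  if (nrow(mothers) == 0) {
    return(list(cell_id = NA_integer_, bud_time_s = NULL, bud_site = NULL))
  }
  d <- sqrt((mothers$cx - mean(tr$x))^2 + (mothers$cy - mean(tr$y))^2)
  k <- mothers$cell_id[which.min(d)]
  b <- buds[buds$cell_id == k, ]
  list(cell_id = k, bud_time_s = b$bud_time * config$dt,
       bud_site = c(b$bud_x, b$bud_y))
}

#' Read trajectories from a CSV file
#'
#' Expected columns: `track_id`, `frame`, `t_s`, `x_um`, `y_um` (the
#' format written by [run_pipeline()] and `generate_dataset()`).
#'
#' @param path CSV file.
#' @return Named list of [trajectory()] objects.
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("track_id", "t_s", "x_um", "y_um") %in% names(df)))
  lapply(split(df, df$track_id), as_trajectory, source = "csv")
}
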