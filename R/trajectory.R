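#' Construct a trajectory
#'
#' A trajectory is an ordered (t, x, y) sequence for one granule in physical
#' units (seconds, micrometres), stored as a data frame of class
#' `pb_trajectory` with columns `frame`, `t`, `x`, `y` and optionally
#' `regime`.
#'
#' @param t observation times, seconds, strictly increasing.
#' @param x,y positions, micrometres.
#' @param frame integer frame indices (0-based); defaults to `0:(n-1)`.
#' @param regime optional per-point motion regime label.
#' @param source provenance of the coordinates: spot linking, simulator
#'   ground truth, or an imported CSV.
#' @return A `pb_trajectory` data frame.
#' @examples
#' tr <- trajectory(t = c(0, 10, 20), x = c(0, 0.1, 0.2), y = c(0, 0, 0))
#' steps_and_velocities(tr)
#' @export
trajectory <- function(t, x, y, frame = seq_along(t) - 1L, regime = NULL,
                       source = c("csv", "linked", "ground_truth")) {
  source <- match.arg(source)
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(frame) == n)
  if (n >= 2 && any(diff(t) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(frame = as.integer(frame), t = as.numeric(t),
                    x = as.numeric(x), y = as.numeric(y))
  if (!is.null(regime)) out$regime <- as.character(regime)
  class(out) <- c("pb_trajectory", "data.frame")
  attr(out, "source") <- source
  out
}

#' Coerce a data frame to a trajectory
#'
#' @param df data frame with columns `t` (or `t_s`), `x` (or `x_um`),
#'   `y` (or `y_um`) and optionally `frame` and `regime`.
#' @inheritParams trajectory
#' @return A `pb_trajectory` data frame.
#' @export
as_trajectory <- function(df, source = "csv") {
  pick <- function(a, b) if (a %in% names(df)) df[[a]] else df[[b]]
  trajectory(t = pick("t", "t_s"), x = pick("x", "x_um"),
             y = pick("y", "y_um"),
             frame = if ("frame" %in% names(df)) df$frame
                     else seq_len(nrow(df)) - 1L,
             regime = if ("regime" %in% names(df)) df$regime else NULL,
             source = source)
}

# uniform frame interval, with tolerance check used by the MSD operations
traj_dt <- function(traj, tol = 1e-6) {
  dts <- diff(traj$t)
  if (length(dts) == 0) return(NA_real_)
  dt <- stats::median(dts)
  attr(dt, "uniform") <- all(abs(dts - dt) <= tol * max(dt, 1))
  dt
}

#' Step sizes and velocities of a trajectory
#'
#' Steps and velocities are computed directly from successive spatial
#' coordinates (no distributional assumption): `step[i] = |r[i+1] - r[i]|`
#' and `velocity[i] = step[i] / dt[i]`.
#'
#' @param traj a [trajectory()].
#' @return A data frame with one row per interval: `t` (start time of the
#'   interval), `step` (um), `velocity` (um/s), `dt` (s). If the sampling is
#'   non-uniform, per-interval `dt` is used and the result carries attribute
#'   `uniform_dt = FALSE`.
#' @examples
#' tr <- trajectory(t = seq(0, 40, 10), x = seq(0, 4, 1), y = rep(0, 5))
#' steps_and_velocities(tr)$velocity  # 0.1 um/s throughout
#' @export
steps_and_velocities <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  dts <- diff(traj$t)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  uniform <- diff(range(dts)) <= 1e-6 * max(dts)
  if (!uniform) {
    warning("non-uniform frame interval; per-interval dt used")
  }
  out <- data.frame(t = traj$t[-n], step = steps, velocity = steps / dts,
                    dt = dts)
  attr(out, "uniform_dt") <- uniform
  out
}

#' Distance from the granule to the bud site over time
#'
#' @param traj a [trajectory()].
#' @param bud_site numeric `c(x, y)` position of the bud site, um (from
#'   ground truth or manual annotation).
#' @return Data frame with columns `t` and `distance` (um).
#' @export
bud_distance_series <- function(traj, bud_site) {
  stopifnot(length(bud_site) == 2, all(is.finite(bud_site)))
  data.frame(t = traj$t,
             distance = sqrt((traj$x - bud_site[1])^2 +
                             (traj$y - bud_site[2])^2))
}

#' Link per-frame spots into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking: candidate links between
#' consecutive frames are sorted by displacement (ties broken by spot index)
#' and accepted greedily while each spot or track is still free; a link is
#' made only if the displacement is at most `max_disp`. Unmatched spots
#' start new trajectories. Suited to sparse scenes (about one granule per
#' cell); no gap closing is attempted.
#'
#' @param spots data frame of detections with columns `frame` (0-based),
#'   `x_um`, `y_um` and optionally `t_s` (otherwise `frame * dt`).
#' @param max_disp maximum displacement per frame interval, um.
#' @param dt seconds per frame, used when `t_s` is absent.
#' @return A list of [trajectory()] objects (source `"linked"`), longest
#'   first; each carries the row indices of `spots` used as attribute
#'   `spot_rows`.
#' @export
link_spots <- function(spots, max_disp = 2, dt = 60) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(spots)))
  if (nrow(spots) == 0) return(list())
  if (!"t_s" %in% names(spots)) spots$t_s <- spots$frame * dt
  o <- order(spots$frame)
  spots <- spots[o, , drop = FALSE]
  spots$.row <- o  # original row indices of the input table

  frames <- sort(unique(spots$frame))
  by_frame <- split(seq_len(nrow(spots)), spots$frame)

  track_of <- integer(nrow(spots))        # track id per spot row
  last_in_track <- integer(0)             # spot row currently ending track
  n_tracks <- 0L

  prev_frame <- NULL
  for (f in frames) {
    idx <- by_frame[[as.character(f)]]
    linked <- rep(FALSE, length(idx))
    if (!is.null(prev_frame) && f == prev_frame + 1) {
      prev_idx <- by_frame[[as.character(prev_frame)]]
      # all candidate pairs within max_disp, greedy by distance then index
      dx <- outer(spots$x_um[prev_idx], spots$x_um[idx], "-")
      dy <- outer(spots$y_um[prev_idx], spots$y_um[idx], "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], cand[, 2], cand[, 1])
        cand <- cand[ord, , drop = FALSE]
        prev_used <- rep(FALSE, length(prev_idx))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (prev_used[i] || linked[j]) next
          tr <- track_of[prev_idx[i]]
          track_of[idx[j]] <- tr
          last_in_track[tr] <- idx[j]
          prev_used[i] <- TRUE
          linked[j] <- TRUE
        }
      }
    }
    for (j in which(!linked)) {
      n_tracks <- n_tracks + 1L
      track_of[idx[j]] <- n_tracks
      last_in_track[n_tracks] <- idx[j]
    }
    prev_frame <- f
  }

  tracks <- split(seq_len(nrow(spots)), track_of)
  tracks <- tracks[order(-lengths(tracks))]
  lapply(tracks, function(rows) {
    tr <- trajectory(t = spots$t_s[rows], x = spots$x_um[rows],
                     y = spots$y_um[rows], frame = spots$frame[rows],
                     source = "linked")
    attr(tr, "spot_rows") <- spots$.row[rows]
    tr
  })
}
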