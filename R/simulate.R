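#' Simulate one granule trajectory
#'
#' Generates a 2D trajectory with the three motion regimes the analysis is
#' built to distinguish:
#'
#' * **free** -- Brownian motion with per-axis increments
#'   `Normal(0, sqrt(2 * D_free * dt))`, reflected at the containing cell
#'   outline;
#' * **corralled** -- during the hover window, a discrete-time
#'   mean-reverting (Ornstein-Uhlenbeck) process around `bud_site` with
#'   one-step autocorrelation `exp(-dt / corral_tau)` and stationary
#'   per-axis standard deviation `corral_sigma` (the exact one-step update,
#'   so the stationary law holds at any `dt`);
#' * **transport** -- from `division_time` on, a deterministic
#'   constant-velocity displacement at `transport_speed` towards
#'   `transport_target` inside the daughter, after which motion is Brownian
#'   again, reflected at the daughter outline.
#'
#' The hover window is `[t_bud + hover_start_offset,
#' t_bud + hover_start_offset + hover_duration]` where
#' `t_bud = bud_time * dt`. A window extending past the end of the
#' trajectory is truncated with a warning.
#'
#' @param config a [sim_config()].
#' @param bud_time frame index (0-based) of bud emergence, or `NULL` for a
#'   trajectory with no hovering.
#' @param bud_site `c(x, y)` bud-site position, um. Required when
#'   `bud_time` is given.
#' @param cell mother outline as `list(center = c(x, y), radius = r)` (um);
#'   default: circle of `config$cell_radius` centred on the bud-site-facing
#'   frame, or on `start`.
#' @param division_time frame index at which directed transport begins, or
#'   `NULL` for no transport.
#' @param daughter daughter outline, same format as `cell`; required when
#'   `division_time` is given.
#' @param start starting position `c(x, y)` um; default: the mother centre.
#' @return A [trajectory()] with a `regime` column
#'   (`"free"`/`"corralled"`/`"transport"`), source `"ground_truth"`.
#' @examples
#' cfg <- sim_config(n_frames = 200, rng_seed = 7)
#' set.seed(cfg$rng_seed)
#' tr <- simulate_trajectory(cfg, bud_time = 150, bud_site = c(2.2, 0),
#'                           cell = list(center = c(0, 0), radius = 2.5))
#' table(tr$regime)
#' @export
simulate_trajectory <- function(config, bud_time = NULL, bud_site = NULL,
                                cell = NULL, division_time = NULL,
                                daughter = NULL, start = NULL) {
  validate_sim_config(config)
  n <- config$n_frames
  dt <- config$dt
  if (!is.null(bud_time)) {
    stopifnot(bud_time >= 0, bud_time < n)
    if (is.null(bud_site)) stop("bud_site required with bud_time",
                                call. = FALSE)
  }
  if (!is.null(division_time) && is.null(daughter)) {
    stop("daughter outline required with division_time", call. = FALSE)
  }
  if (is.null(cell)) {
    ctr <- if (!is.null(start)) start else c(0, 0)
    cell <- list(center = ctr, radius = config$cell_radius)
  }
  if (is.null(start)) start <- cell$center

  # hover window in frame indices
  hover <- rep(FALSE, n)
  if (!is.null(bud_time)) {
    h0 <- bud_time * dt + config$hover_start_offset
    h1 <- h0 + config$hover_duration
    if (h1 > (n - 1) * dt) {
      warning("hover window extends past trajectory end; truncated")
      h1 <- (n - 1) * dt
    }
    tgrid <- (seq_len(n) - 1) * dt
    hover <- tgrid >= h0 & tgrid <= h1
  }

  sd_free <- sqrt(2 * config$D_free * dt)
  rho <- exp(-dt / config$corral_tau)
  sd_ou <- config$corral_sigma * sqrt(1 - rho^2)

  pos <- matrix(NA_real_, n, 2)
  regime <- character(n)
  pos[1, ] <- start
  regime[1] <- if (hover[1]) "corralled" else "free"
  if (hover[1]) {
    pos[1, ] <- bud_site + rnorm(2, 0, config$corral_sigma)
  }

  transporting <- FALSE
  arrived <- FALSE
  target <- if (!is.null(daughter)) daughter$center else NULL

  for (i in seq_len(n - 1L)) {
    p <- pos[i, ]
    f <- i  # 0-based index of the frame being generated is i (frame i)
    if (!is.null(division_time) && !arrived && f >= division_time) {
      transporting <- TRUE
    }
    if (transporting) {
      v <- target - p
      d <- sqrt(sum(v^2))
      stepl <- config$transport_speed * dt
      if (d <= stepl) {
        q <- target
        transporting <- FALSE
        arrived <- TRUE
      } else {
        q <- p + v / d * stepl
      }
      pos[i + 1L, ] <- q
      regime[i + 1L] <- "transport"
      next
    }
    if (hover[i + 1L] && !arrived) {
      q <- bud_site + rho * (p - bud_site) + rnorm(2, 0, sd_ou)
      regime[i + 1L] <- "corralled"
    } else {
      q <- p + rnorm(2, 0, sd_free)
      regime[i + 1L] <- "free"
    }
    bound <- if (arrived) daughter else cell
    pos[i + 1L, ] <- reflect_in_circle(q, bound$center, bound$radius)
  }

  trajectory(t = (seq_len(n) - 1) * dt, x = pos[, 1], y = pos[, 2],
             frame = seq_len(n) - 1L, regime = regime,
             source = "ground_truth")
}

# reflect a point into a circle: fold the radial coordinate across the
# boundary (triangle wave), which handles steps of any size
reflect_in_circle <- function(p, center, radius) {
  v <- p - center
  d <- sqrt(sum(v^2))
  if (d <= radius || d == 0 || !is.finite(radius)) return(p)
  d2 <- d %% (2 * radius)
  if (d2 > radius) d2 <- 2 * radius - d2
  center + v / d * d2
}

#' Render a fluorescence frame
#'
#' Produces `background + sum of spots`, each spot an isotropic 2D Gaussian
#' of width `spot_sigma` pixels integrating to `spot_amplitude` photons,
#' plus noise per `config$noise_model`. Pixels are indexed row-major with
#' the origin at the top-left pixel centre (0-based): position (x, y) in um
#' maps to column `x / pixel_size`, row `y / pixel_size`.
#'
#' @param positions matrix or data frame of spot centres in um, columns
#'   x, y (possibly zero rows).
#' @param config a [sim_config()].
#' @param noise override of `config$noise_model`.
#' @return Numeric matrix (photons) with attribute `centers_px`, the
#'   ground-truth subpixel centres in pixel units.
#' @export
render_fluorescence_frame <- function(positions, config,
                                      noise = config$noise_model) {
  if (config$spot_amplitude <= 0) stop("spot amplitude must be positive",
                                       call. = FALSE)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  img <- matrix(config$background, nr, nc)
  pos <- as.matrix(positions)
  centers_px <- matrix(numeric(0), 0, 2)
  if (nrow(pos) > 0) {
    px <- pos[, 1] / config$pixel_size
    py <- pos[, 2] / config$pixel_size
    if (any(px < 0 | px > nc - 1 | py < 0 | py > nr - 1)) {
      stop("spot position outside image bounds", call. = FALSE)
    }
    centers_px <- cbind(x = px, y = py)
    s <- config$spot_sigma
    amp <- config$spot_amplitude / (2 * pi * s^2)
    half <- ceiling(5 * s)
    for (k in seq_len(nrow(pos))) {
      c0 <- max(0, floor(px[k]) - half); c1 <- min(nc - 1, ceiling(px[k]) + half)
      r0 <- max(0, floor(py[k]) - half); r1 <- min(nr - 1, ceiling(py[k]) + half)
      gx <- exp(-((c0:c1) - px[k])^2 / (2 * s^2))
      gy <- exp(-((r0:r1) - py[k])^2 / (2 * s^2))
      img[(r0:r1) + 1, (c0:c1) + 1] <-
        img[(r0:r1) + 1, (c0:c1) + 1] + amp * outer(gy, gx)
    }
  }
  img <- apply_noise(img, noise, config$gaussian_sd)
  attr(img, "centers_px") <- centers_px
  img
}

apply_noise <- function(img, noise, gaussian_sd) {
  switch(noise,
    none = img,
    poisson = {
      out <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
      out
    },
    gaussian = img + matrix(rnorm(length(img), 0, gaussian_sd),
                            nrow(img), ncol(img)),
    stop("unknown noise model: ", noise, call. = FALSE)
  )
}

#' Render a two-frame bright-field focus stack
#'
#' Emulates the under/over-focus appearance of yeast cells in transmitted
#' light: each cell contributes an interior dome `max(0, 1 - (r/R)^2)`
#' with opposite sign in the two focus frames (bright interior below
#' focus, dark above) plus a bright rim ring common to both frames, so the
#' cell rim has opposite contrast relative to the interior in the two
#' frames while the differential image (frame 1 - frame 2) cancels the
#' rim, peaks inside the cell and vanishes at the outline -- which is what
#' lets touching cells be separated downstream. Touching or overlapping
#' outlines are allowed but flagged via attribute `overlap`.
#'
#' @param cell_outlines list of `list(center = c(x, y), radius = r)` in um.
#' @param config a [sim_config()].
#' @param noise override of `config$noise_model`.
#' @return List of two matrices (photons), class `focus_stack`, with
#'   attribute `overlap` (logical).
#' @export
render_brightfield_stack <- function(cell_outlines, config,
                                     noise = config$noise_model) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  relief <- matrix(0, nr, nc)
  ring <- matrix(0, nr, nc)
  xs <- (seq_len(nc) - 1) * config$pixel_size
  ys <- (seq_len(nr) - 1) * config$pixel_size
  for (cl in cell_outlines) {
    ctr <- cl$center; R <- cl$radius
    if (any(ctr - R < 0) || ctr[1] + R > max(xs) || ctr[2] + R > max(ys)) {
      stop("cell outline outside image bounds", call. = FALSE)
    }
    r <- sqrt(outer((ys - ctr[2])^2, (xs - ctr[1])^2, "+"))
    relief <- relief + pmax(0, 1 - (r / R)^2)
    ring <- ring + exp(-(r - R)^2 / (2 * (0.1 * R)^2))
  }
  overlap <- FALSE
  no <- length(cell_outlines)
  if (no > 1) {
    for (i in seq_len(no - 1)) for (j in (i + 1):no) {
      d <- sqrt(sum((cell_outlines[[i]]$center - cell_outlines[[j]]$center)^2))
      if (d < cell_outlines[[i]]$radius + cell_outlines[[j]]$radius) {
        overlap <- TRUE
      }
    }
  }
  a <- config$bf_background + config$bf_contrast * (relief + 0.3 * ring)
  b <- pmax(config$bf_background + config$bf_contrast * (0.3 * ring - relief), 0)
  stack <- list(apply_noise(a, noise, config$gaussian_sd),
                apply_noise(b, noise, config$gaussian_sd))
  class(stack) <- "focus_stack"
  attr(stack, "overlap") <- overlap
  stack
}
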