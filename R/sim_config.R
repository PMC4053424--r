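#' Simulation configuration
#'
#' Bundles every parameter of the synthetic time-lapse generator. The
#' defaults describe the experimental regime the analysis is designed for:
#' budding-yeast cells imaged as a monolayer at 10 s frame intervals
#' (60 s for the coarse overnight mode), diffraction-limited granules with
#' photon-limited noise, and three motion regimes -- free diffusion inside
#' the mother cell, corralled (mean-reverting) motion around the bud site
#' starting about half an hour before bud emergence, and a single directed
#' mother-to-daughter translocation at division.
#'
#' @param n_frames number of time points.
#' @param dt seconds per frame (10 s fine-scale, 60 s coarse).
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param D_free free diffusion coefficient, um^2/s. The default 5e-4 is
#'   typical of micron-scale RNP granules in crowded cytoplasm and
#'   reproduces compact positional clusters at 60 s sampling; fine-scale
#'   confinement studies typically override it (e.g. 0.01).
#' @param corral_sigma stationary per-axis standard deviation of the
#'   confined (corralled) motion around the bud site, um.
#' @param corral_tau relaxation time of the confined motion, s.
#' @param hover_start_offset onset of hovering relative to budding time,
#'   seconds; negative means before the bud is visible. Default 1980 s
#'   before budding (0.55 h).
#' @param hover_duration total hovering time, seconds. Default 2990 s
#'   (0.83 h).
#' @param transport_speed speed of the directed mother-to-daughter
#'   translocation, um/s.
#' @param spot_sigma granule point-spread width, pixels.
#' @param spot_amplitude integrated photon count of one granule.
#' @param background mean background level of fluorescence frames, photons.
#' @param noise_model `"poisson"` (photon noise), `"gaussian"` (additive,
#'   sd = `gaussian_sd`) or `"none"`.
#' @param gaussian_sd read-noise standard deviation when
#'   `noise_model = "gaussian"`.
#' @param bf_background bright-field background level, photons (high, so
#'   relative shot noise is small, as in transmitted light).
#' @param bf_contrast amplitude of the cell contrast in the bright-field
#'   focus frames, photons.
#' @param cell_radius mother cell radius, um.
#' @param daughter_radius final daughter (bud) radius, um.
#' @param n_cells number of mother cells in a generated dataset.
#' @param pb_fate daughter fate(s), recycled over cells: `"transported"`
#'   (the mother P-body moves into the bud at division), `"de_novo"` (the
#'   mother P-body stays; the daughter forms its own after division) or
#'   `"none"` (no P-body reaches the daughter).
#' @param rng_seed integer seed making [generate_dataset()] reproducible.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_frames = 100)
#' cfg$D_free
#' @export
sim_config <- function(n_frames = 600,
                       dt = 10,
                       pixel_size = 0.2,
                       image_shape = c(256, 256),
                       D_free = 5e-4,
                       corral_sigma = 0.2,
                       corral_tau = 20,
                       hover_start_offset = -1980,
                       hover_duration = 2990,
                       transport_speed = 0.3,
                       spot_sigma = 1.5,
                       spot_amplitude = 800,
                       background = 100,
                       noise_model = c("poisson", "gaussian", "none"),
                       gaussian_sd = 10,
                       bf_background = 5000,
                       bf_contrast = 1500,
                       cell_radius = 2.5,
                       daughter_radius = 1.5,
                       n_cells = 4,
                       pb_fate = "transported",
                       rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_frames = as.integer(n_frames), dt = dt, pixel_size = pixel_size,
    image_shape = as.integer(image_shape),
    D_free = D_free, corral_sigma = corral_sigma, corral_tau = corral_tau,
    hover_start_offset = hover_start_offset, hover_duration = hover_duration,
    transport_speed = transport_speed,
    spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
    background = background, noise_model = noise_model,
    gaussian_sd = gaussian_sd,
    bf_background = bf_background, bf_contrast = bf_contrast,
    cell_radius = cell_radius, daughter_radius = daughter_radius,
    n_cells = as.integer(n_cells), pb_fate = pb_fate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_frames >= 1,
    cfg$dt > 0,
    cfg$pixel_size > 0,
    length(cfg$image_shape) == 2, all(cfg$image_shape >= 1),
    cfg$D_free >= 0,
    cfg$corral_sigma > 0,
    cfg$hover_duration > 0,
    cfg$transport_speed > 0,
    cfg$spot_sigma > 0,
    cfg$background >= 0,
    cfg$cell_radius > 0, cfg$daughter_radius > 0,
    all(cfg$pb_fate %in% c("transported", "de_novo", "none"))
  )
  if (cfg$corral_tau <= 0) {
    stop("corral_tau must be positive", call. = FALSE)
  }
  # the field of view must be able to hold at least one cell
  fov_um <- min(cfg$image_shape) * cfg$pixel_size
  if (fov_um < 2 * cfg$cell_radius) {
    stop("image_shape too small to contain a cell of radius ",
         cfg$cell_radius, " um", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic time-lapse configuration\n")
  cat(sprintf("  %d frames at dt = %g s, %dx%d px (%g um/px)\n",
              x$n_frames, x$dt, x$image_shape[1], x$image_shape[2],
              x$pixel_size))
  cat(sprintf("  motion: D_free = %g um^2/s; corral sigma = %g um, tau = %g s\n",
              x$D_free, x$corral_sigma, x$corral_tau))
  cat(sprintf("  hover: onset %+g s from budding, duration %g s; transport %g um/s\n",
              x$hover_start_offset, x$hover_duration, x$transport_speed))
  cat(sprintf("  optics: spot sigma %g px, amplitude %g, background %g, %s noise\n",
              x$spot_sigma, x$spot_amplitude, x$background, x$noise_model))
  invisible(x)
}
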