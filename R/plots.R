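#' Plot a trajectory coloured by time
#'
#' @param x a [trajectory()].
#' @param bud_site optional `c(x, y)` bud site to mark.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pb_trajectory <- function(x, bud_site = NULL, ...) {
  cols <- grDevices::hcl.colors(nrow(x), "viridis")
  graphics::plot(x$x, x$y, type = "l", col = "grey80", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::points(x$x, x$y, col = cols, pch = 16, cex = 0.6)
  if (!is.null(bud_site)) {
    graphics::points(bud_site[1], bud_site[2], pch = 4, cex = 1.5, lwd = 2)
  }
  invisible(x)
}

#' Plot an MSD curve
#'
#' @param x an [msd()] result.
#' @param fit optional [diffusion_coefficient()] result whose line is
#'   overlaid.
#' @param ... passed to [graphics::plot()].
#' @export
plot.msd_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$lag_s, x$msd, pch = 16, xlab = "lag (s)",
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$slope, col = "red3")
  }
  invisible(x)
}

#' Plot a hovering detection
#'
#' Shows the mobility series with the fitted changepoints and the budding
#' time.
#'
#' @param x a [detect_hovering()] result.
#' @param bud_time budding time in seconds (drawn as a dashed line at 0 on
#'   the relative axis when supplied).
#' @param ... passed to [graphics::plot()].
#' @export
plot.hover_window <- function(x, bud_time = NULL, ...) {
  graphics::plot(x$mobility$t, x$mobility$value, type = "l",
                 xlab = "time (s)",
                 ylab = expression(mobility ~ (mu * m^2 / frame)), ...)
  if (!is.null(bud_time)) graphics::abline(v = bud_time, lty = 2)
  if (isTRUE(x$hovering) && !is.null(bud_time)) {
    graphics::abline(v = bud_time + c(x$H_start, x$H_stop), col = "red3")
  }
  invisible(x)
}
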