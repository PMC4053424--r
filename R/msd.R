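#' Time-averaged mean squared displacement
#'
#' `MSD(k * dt) = mean over i of |r[i+k] - r[i]|^2` using all overlapping
#' pairs; requires (approximately) uniform sampling. Lags supported by
#' fewer than 3 pairs are dropped and flagged.
#'
#' @param traj a [trajectory()].
#' @param max_lag maximum lag in frames (default `n - 1`, subject to the
#'   3-pair rule).
#' @return Object of class `msd_curve`: data frame `lag` (frames),
#'   `lag_s` (seconds), `msd` (um^2), `n_pairs`, including the trivial
#'   `lag = 0` row; attribute `dropped_lags` lists lags removed for having
#'   fewer than 3 pairs, attribute `dt` the frame interval.
#' @examples
#' tr <- trajectory(t = seq(0, 90, 10), x = seq(0, 0.9, 0.1), y = rep(0, 10))
#' msd(tr, max_lag = 3)$msd  # (0.1 k)^2, ballistic
#' @export
msd <- function(traj, max_lag = nrow(traj) - 1L) {
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (max_lag >= n) stop("max_lag must be smaller than the track length",
                         call. = FALSE)
  dt <- traj_dt(traj)
  if (!isTRUE(attr(dt, "uniform"))) {
    stop("MSD requires uniform frame intervals", call. = FALSE)
  }
  lags <- 0:max_lag
  vals <- numeric(length(lags)); npairs <- integer(length(lags))
  vals[1] <- 0; npairs[1] <- n
  for (k in seq_len(max_lag)) {
    dx <- traj$x[(1 + k):n] - traj$x[1:(n - k)]
    dy <- traj$y[(1 + k):n] - traj$y[1:(n - k)]
    vals[k + 1] <- mean(dx^2 + dy^2)
    npairs[k + 1] <- n - k
  }
  keep <- npairs >= 3 | lags == 0
  dropped <- lags[!keep]
  out <- data.frame(lag = lags[keep], lag_s = lags[keep] * as.numeric(dt),
                    msd = vals[keep], n_pairs = npairs[keep])
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "dropped_lags") <- dropped
  attr(out, "dt") <- as.numeric(dt)
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Fits a least-squares line with free intercept to MSD over the given
#' lags and returns `D = slope / 4` (2D random walk, `MSD = 4 D t`). The
#' free intercept absorbs static and dynamic localization error. A
#' negative slope is clipped to `D = 0` and flagged; pronounced upward
#' curvature (ballistic contamination) is flagged by comparing a quadratic
#' fit with the line.
#'
#' @param msd_curve an [msd()] result.
#' @param fit_lags lags (in frames) used in the fit.
#' @return Object of class `diffusion_fit`: list `D` (um^2/s), `slope`,
#'   `intercept`, `flags` (character vector, possibly empty), `fit_lags`.
#' @examples
#' tr <- trajectory(t = seq(0, 990, 10),
#'                  x = cumsum(c(0, rnorm(99, 0, sqrt(2 * 0.02 * 10)))),
#'                  y = cumsum(c(0, rnorm(99, 0, sqrt(2 * 0.02 * 10)))))
#' diffusion_coefficient(msd(tr, 10))$D
#' @export
diffusion_coefficient <- function(msd_curve, fit_lags = 1:4) {
  sub <- msd_curve[msd_curve$lag %in% fit_lags, , drop = FALSE]
  if (nrow(sub) < 2) stop("need at least 2 lags in fit range",
                          call. = FALSE)
  fit <- lm(msd ~ lag_s, data = sub)
  slope <- coef(fit)[["lag_s"]]
  flags <- character()
  if (nrow(sub) >= 3) {
    qfit <- lm(msd ~ lag_s + I(lag_s^2), data = sub)
    qc <- coef(qfit)[["I(lag_s^2)"]]
    lin <- coef(qfit)[["lag_s"]]
    tmax <- max(sub$lag_s)
    # quadratic term contributing more than half the linear part at the
    # longest fitted lag indicates non-diffusive (ballistic) scaling
    if (is.finite(qc) && qc * tmax > 0.5 * abs(lin) * 1 &&
        qc * tmax^2 > 0.2 * max(sub$msd)) {
      flags <- c(flags, "curvature")
    }
  }
  D <- slope / 4
  if (D < 0) {
    D <- 0
    flags <- c(flags, "negative_slope")
  }
  structure(list(D = D, slope = slope,
                 intercept = coef(fit)[["(Intercept)"]],
                 flags = flags, fit_lags = fit_lags),
            class = "diffusion_fit")
}

#' Windowed diffusion coefficients around budding
#'
#' Estimates the diffusion coefficient separately in time windows before,
#' during and after budding. By default the "during" window is
#' `bud_time +/- window` seconds (budding spans about 15 minutes either
#' side of bud emergence) and the before/after windows are the
#' `window`-second intervals immediately preceding and following it;
#' explicit `c(start, stop)` intervals (seconds) override the defaults.
#'
#' @param traj a [trajectory()].
#' @param bud_time budding time, seconds.
#' @param window half-width of the during window and width of the flanking
#'   windows, seconds (default 900 s = 15 min).
#' @param before,during,after optional explicit `c(start, stop)` windows.
#' @param fit_lags lags for [diffusion_coefficient()].
#' @param min_points minimum points per window.
#' @return List `D_before`, `D_during`, `D_after` (um^2/s), `windows`,
#'   `fits` (the three `diffusion_fit` objects), `reduction`
#'   (`1 - D_during / D_before`).
#' @export
windowed_diffusion <- function(traj, bud_time, window = 900,
                               before = NULL, during = NULL, after = NULL,
                               fit_lags = 1:4, min_points = 10) {
  if (is.null(during)) during <- c(bud_time - window, bud_time + window)
  if (is.null(before)) before <- c(during[1] - window, during[1])
  if (is.null(after)) after <- c(during[2], during[2] + window)
  one <- function(w, name) {
    keep <- traj$t >= w[1] & traj$t < w[2]
    if (sum(keep) < min_points) {
      stop(sprintf("window '%s' [%g, %g) holds %d < %d points", name,
                   w[1], w[2], sum(keep), min_points), call. = FALSE)
    }
    sub <- trajectory(t = traj$t[keep], x = traj$x[keep], y = traj$y[keep],
                      frame = traj$frame[keep], source = "csv")
    diffusion_coefficient(msd(sub, max_lag = max(fit_lags)), fit_lags)
  }
  fits <- list(before = one(before, "before"), during = one(during, "during"),
               after = one(after, "after"))
  list(D_before = fits$before$D, D_during = fits$during$D,
       D_after = fits$after$D,
       reduction = if (fits$before$D > 0) 1 - fits$during$D / fits$before$D
                   else NA_real_,
       windows = list(before = before, during = during, after = after),
       fits = fits)
}

#' Detect a hovering (confined) episode around budding
#'
#' Builds a time-resolved mobility series (squared frame-to-frame
#' displacement averaged over a centred sliding window) and fits a
#' three-segment piecewise-constant high-low-high model by exhaustive
#' search over changepoint pairs, with the low segment constrained to
#' overlap the budding time. The two changepoints give the start
#' (`H_start`) and end (`H_stop`) of hovering relative to budding and
#' their difference the total hovering time `T_hov`.
#'
#' Squared displacements of a planar random walk are exponentially
#' distributed, so their noise scales with the local mean; the
#' within-segment squared error is therefore minimized on the log of the
#' mobility series, where the noise variance is constant
#' (`trigamma(window)` for the log of a `window`-term mean of
#' exponentials) and changepoint localization is unbiased. A hovering
#' episode is reported only when (i) the fitted mobility drop
#' `1 - low/high` is at least `min_drop` and (ii) the three-segment model
#' beats the constant model by a BIC-type margin,
#' `SSE_1 - SSE_3 > 4 * log(L / window) * trigamma(window) * window`
#' (the factor `window` corrects for the overlap of adjacent sliding
#' windows); otherwise the result is "no hovering".
#'
#' @param traj a [trajectory()] spanning `bud_time` with at least 30
#'   points on each side, uniformly sampled.
#' @param bud_time budding time, seconds.
#' @param mobility_window sliding-window length in points (default 5).
#' @param min_drop minimum relative mobility drop `1 - low/high` for a
#'   hovering call (default 0.2).
#' @param min_segment minimum segment length in mobility points.
#' @return Object of class `hover_window`: list `hovering` (logical),
#'   `H_start`, `H_stop`, `T_hov` (seconds, relative to budding;
#'   `NA` when not hovering), `D_low`, `D_high` (um^2/s converted from the
#'   segment mobilities), `drop`, `evidence` (the penalized SSE reduction,
#'   > 1 supports hovering), `mobility` (data frame `t`, `value`).
#' @export
detect_hovering <- function(traj, bud_time, mobility_window = 5,
                            min_drop = 0.2, min_segment = 15) {
  n <- nrow(traj)
  if (sum(traj$t < bud_time) < 30 || sum(traj$t > bud_time) < 30) {
    stop("track must span bud_time with at least 30 points either side",
         call. = FALSE)
  }
  dt <- traj_dt(traj)
  if (!isTRUE(attr(dt, "uniform"))) {
    stop("hover detection requires uniform frame intervals", call. = FALSE)
  }
  dt <- as.numeric(dt)
  d2 <- diff(traj$x)^2 + diff(traj$y)^2          # squared step sizes
  td <- traj$t[-n]                               # time of each step
  w <- mobility_window
  if (w > 1) {
    m <- stats::filter(d2, rep(1 / w, w), sides = 2)
    ok <- !is.na(m)
    m <- as.numeric(m[ok]); tm <- td[ok]
  } else {
    m <- d2; tm <- td
  }
  L <- length(m)
  if (L < 3 * min_segment) stop("track too short for changepoint search",
                                call. = FALSE)

  ib <- which.min(abs(tm - bud_time))  # mobility index nearest budding
  v <- log(pmax(m, 1e-12))
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  seg_sse <- function(i, j) {          # SSE of v[i..j] around its mean
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # changepoints: low segment = m[(c1+1)..c2]; must overlap ib
  c1_hi <- min(ib - 1, L - 2 * min_segment)
  c1_range <- if (c1_hi >= min_segment) min_segment:c1_hi else integer(0)
  best <- NULL; best_sse <- Inf
  for (c1 in c1_range) {
    c2_lo <- max(c1 + min_segment, ib)
    c2_hi <- L - min_segment
    if (c2_lo > c2_hi) next
    for (c2 in c2_lo:c2_hi) {
      sse <- seg_sse(1, c1) + seg_sse(c1 + 1, c2) + seg_sse(c2 + 1, L)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(c1, c2)
      }
    }
  }
  mobility <- data.frame(t = tm, value = m)
  if (is.null(best)) {
    return(structure(list(hovering = FALSE, H_start = NA_real_,
                          H_stop = NA_real_, T_hov = NA_real_,
                          D_low = NA_real_, D_high = NA_real_,
                          drop = NA_real_, evidence = NA_real_,
                          mobility = mobility),
                     class = "hover_window"))
  }
  c1 <- best[1]; c2 <- best[2]
  mu_low <- mean(m[(c1 + 1):c2])
  mu_high <- mean(m[c(1:c1, (c2 + 1):L)])
  drop <- 1 - mu_low / mu_high
  penalty <- 4 * log(L / w) * trigamma(w) * w
  evidence <- (seg_sse(1, L) - best_sse) / penalty
  hovering <- is.finite(drop) && drop >= min_drop && evidence > 1
  structure(list(
    hovering = hovering,
    H_start = if (hovering) tm[c1 + 1] - bud_time else NA_real_,
    H_stop = if (hovering) tm[c2] - bud_time else NA_real_,
    T_hov = if (hovering) tm[c2] - tm[c1 + 1] else NA_real_,
    D_low = mu_low / (4 * dt), D_high = mu_high / (4 * dt),
    drop = drop, evidence = evidence, mobility = mobility),
    class = "hover_window")
}

#' @export
print.hover_window <- function(x, ...) {
  if (x$hovering) {
    cat(sprintf("hovering: H_start = %+.0f s, H_stop = %+.0f s, T_hov = %.0f s (drop %.0f%%)\n",
                x$H_start, x$H_stop, x$T_hov, 100 * x$drop))
  } else {
    cat("no hovering detected\n")
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] (asymptotic p-value) used to
#' compare motion statistics across granules, cells and strains.
#'
#' @param sample_a,sample_b numeric samples, non-empty.
#' @return List `statistic`, `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    warning("fewer than 3 observations in a sample; p-value unreliable")
  }
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
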