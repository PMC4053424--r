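#' Spot-detection parameters
#'
#' @param binary_threshold constant intensity threshold applied to the
#'   band-pass (DoG) filtered image. This value is specific to an image
#'   set (it depends on illumination and expression level) and therefore
#'   has no default; calibrate it on a few frames, e.g. as a multiple of
#'   the background noise passed through the filter.
#' @param sigma_small,sigma_large standard deviations (pixels) of the two
#'   Gaussian low-pass filters whose difference forms the band-pass.
#'   Defaults 3 and 9.
#' @param min_area,max_area area bounds (pixels^2) for candidate regions.
#' @param score_threshold minimum quality score (fitted peak amplitude over
#'   residual standard deviation) for a detection to be kept.
#' @param score_mode `"residual"` scores a fit by amplitude / residual
#'   standard deviation (a signal-to-noise ratio, the default);
#'   `"sigma"` scores by amplitude / fitted Gaussian width.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(binary_threshold,
                             sigma_small = 3, sigma_large = 9,
                             min_area = 4, max_area = 400,
                             score_threshold = 3,
                             score_mode = c("residual", "sigma")) {
  score_mode <- match.arg(score_mode)
  stopifnot(sigma_small > 0, sigma_small < sigma_large,
            min_area < max_area, binary_threshold >= 0,
            score_threshold >= 0)
  structure(list(binary_threshold = binary_threshold,
                 sigma_small = sigma_small, sigma_large = sigma_large,
                 min_area = min_area, max_area = max_area,
                 score_threshold = score_threshold,
                 score_mode = score_mode),
            class = "detection_params")
}

#' Difference-of-Gaussians band-pass filter
#'
#' Returns `G(sigma_small) * I - G(sigma_large) * I`, the difference of two
#' low-pass filtered copies of the image. This suppresses both pixel noise
#' (below `sigma_small`) and slowly varying background (above
#' `sigma_large`), leaving blob-like features between the two scales.
#'
#' @param frame numeric matrix.
#' @param sigma_small,sigma_large Gaussian standard deviations in pixels,
#'   `sigma_small < sigma_large`.
#' @return Filtered matrix of the same size.
#' @export
dog_filter <- function(frame, sigma_small = 3, sigma_large = 9) {
  stopifnot(is.matrix(frame), sigma_small > 0, sigma_small < sigma_large)
  if (any(!is.finite(frame))) stop("non-finite pixels in frame",
                                   call. = FALSE)
  lo1 <- gaussian_blur(frame, sigma_small)
  lo2 <- gaussian_blur(frame, sigma_large)
  lo1 - lo2
}

# Gaussian blur with replicated (edge-padded) boundary; the normalized
# brush preserves constants, so the DoG of a constant image is zero.
# The image is padded by the kernel half-width before filtering, both to
# realize the replicated boundary and so small frames never violate
# filter2's kernel-size limit.
gaussian_blur <- function(img, sigma) {
  half <- ceiling(3 * sigma)
  size <- 2L * half + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, half), seq_len(nr), rep(nr, half))
  ci <- c(rep(1L, half), seq_len(nc), rep(nc, half))
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, brush)
  matrix(as.numeric(out), nrow(padded), ncol(padded))[half + seq_len(nr),
                                                      half + seq_len(nc)]
}

#' Candidate spot regions from a filtered frame
#'
#' Thresholds the band-pass image into a binary mask and keeps connected
#' components whose area lies in `[min_area, max_area]`.
#'
#' @param filtered output of [dog_filter()].
#' @param params a [detection_params()].
#' @return Data frame with one row per candidate: `label`, `area`,
#'   `cx_px`, `cy_px` (0-based centroid), bounding box `x0, x1, y0, y1`
#'   (0-based, inclusive) and `on_border`. Attribute `labels` holds the
#'   filtered label matrix.
#' @export
segment_candidates <- function(filtered, params) {
  bw <- filtered > params$binary_threshold
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(filtered), ncol(filtered))
  out <- region_table(lab)
  keep <- out$area >= params$min_area & out$area <= params$max_area
  out <- out[keep, , drop = FALSE]
  # relabel surviving regions 1..K
  lab[!(lab %in% out$label)] <- 0L
  if (nrow(out) > 0) {
    lab <- matrix(match(lab, c(0L, out$label)) - 1L, nrow(lab), ncol(lab))
    out$label <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}

# areas, centroids and bounding boxes of a label matrix (0 = background);
# coordinates 0-based, x = column, y = row
region_table <- function(lab) {
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0) {
    return(data.frame(label = integer(), area = integer(),
                      cx_px = numeric(), cy_px = numeric(),
                      x0 = integer(), x1 = integer(),
                      y0 = integer(), y1 = integer(),
                      on_border = logical()))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1) %% nrow(lab)       # 0-based row = y
  cols <- (idx - 1) %/% nrow(lab)      # 0-based col = x
  area <- as.integer(tapply(l, l, length))
  cx <- as.numeric(tapply(cols, l, mean))
  cy <- as.numeric(tapply(rows, l, mean))
  x0 <- as.integer(tapply(cols, l, min)); x1 <- as.integer(tapply(cols, l, max))
  y0 <- as.integer(tapply(rows, l, min)); y1 <- as.integer(tapply(rows, l, max))
  data.frame(label = labels, area = area, cx_px = cx, cy_px = cy,
             x0 = x0, x1 = x1, y0 = y0, y1 = y1,
             on_border = x0 == 0 | y0 == 0 |
               x1 == ncol(lab) - 1 | y1 == nrow(lab) - 1)
}

#' Fit an isotropic Gaussian point-spread model to a candidate region
#'
#' Least-squares fit of
#' `amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2)) + offset`
#' over the candidate's bounding box padded by `2 * sigma_small` pixels.
#' The quality score is the fitted peak amplitude divided by the residual
#' standard deviation of the fit (or by the fitted width when
#' `score_mode = "sigma"`), so only bright, well-localized foci score
#' highly.
#'
#' @param frame original (unfiltered) intensity matrix.
#' @param region one row of [segment_candidates()] output.
#' @param params a [detection_params()].
#' @return One-row data frame: `x_px`, `y_px` (subpixel, 0-based),
#'   `sigma_fit`, `amplitude`, `offset`, `residual_std`, `score`,
#'   `flagged` (non-convergence, width pinned at a bound, or border
#'   region), `on_border`.
#' @export
fit_gaussian_psf <- function(frame, region, params) {
  pad <- ceiling(2 * params$sigma_small)
  c0 <- max(0, region$x0 - pad); c1 <- min(ncol(frame) - 1, region$x1 + pad)
  r0 <- max(0, region$y0 - pad); r1 <- min(nrow(frame) - 1, region$y1 + pad)
  z <- frame[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
  xs <- c0:c1; ys <- r0:r1
  grid <- expand.grid(x = xs, y = ys)
  zz <- as.vector(t(z))  # row-major: matches expand.grid(x within y)

  off0 <- min(zz); a0 <- max(zz) - off0
  if (a0 <= 0) a0 <- 1e-6
  w <- pmax(zz - off0, 0)
  x0 <- sum(grid$x * w) / max(sum(w), 1e-12)
  y0 <- sum(grid$y * w) / max(sum(w), 1e-12)
  s0 <- max(params$sigma_small / 2, 1)

  lo <- c(A = 0, x0 = min(xs) - 1, y0 = min(ys) - 1, s = 0.3,
          off = off0 - 3 * abs(off0) - 1)
  hi <- c(A = 10 * a0 + 1, x0 = max(xs) + 1, y0 = max(ys) + 1,
          s = max(diff(range(xs)), diff(range(ys))) + 1,
          off = max(zz) + 1)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      zz ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + off,
      data = cbind(grid, zz = zz),
      start = list(A = a0, x0 = x0, y0 = y0, s = s0, off = off0),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)

  flagged <- FALSE
  if (is.null(fit)) {
    est <- c(A = a0, x0 = x0, y0 = y0, s = s0, off = off0)
    res_sd <- sd(zz)
    flagged <- TRUE
  } else {
    est <- coef(fit)
    res <- zz - predict(fit)
    dof <- max(length(zz) - 5, 1)
    res_sd <- sqrt(sum(res^2) / dof)
    at_bound <- est["s"] <= lo["s"] + 1e-6 || est["s"] >= hi["s"] - 1e-6
    # a genuine focus must explain a non-trivial share of the window
    # variance; fits to flat noise do not
    sse0 <- sum((zz - mean(zz))^2)
    weak <- sse0 > 0 && (1 - sum(res^2) / sse0) < 0.1
    if (at_bound || weak) flagged <- TRUE
  }
  score <- if (params$score_mode == "residual") {
    if (res_sd > 0) est[["A"]] / res_sd else Inf
  } else {
    est[["A"]] / est[["s"]]
  }
  data.frame(x_px = est[["x0"]], y_px = est[["y0"]],
             sigma_fit = est[["s"]], amplitude = est[["A"]],
             offset = est[["off"]], residual_std = res_sd,
             score = score,
             flagged = flagged || isTRUE(region$on_border),
             on_border = isTRUE(region$on_border))
}

#' Keep well-scoring fits as detections
#'
#' Drops flagged fits (non-converged, width at a bound, border regions)
#' and fits scoring below `score_threshold`; converts positions to
#' physical units.
#'
#' @param fits data frame of [fit_gaussian_psf()] rows.
#' @param score_threshold minimum score; overrides the value in `params`
#'   when given.
#' @param pixel_size um per pixel.
#' @param frame_index 0-based frame index recorded with each spot.
#' @return Spot table: `frame`, `x_px`, `y_px`, `x_um`, `y_um`, `sigma`,
#'   `amplitude`, `score`.
#' @export
score_filter <- function(fits, score_threshold, pixel_size = 0.2,
                         frame_index = 0L) {
  keep <- !fits$flagged & fits$score >= score_threshold
  f <- fits[keep, , drop = FALSE]
  out <- data.frame(frame = rep(as.integer(frame_index), nrow(f)),
                    x_px = f$x_px, y_px = f$y_px,
                    x_um = f$x_px * pixel_size, y_um = f$y_px * pixel_size,
                    sigma = f$sigma_fit, amplitude = f$amplitude,
                    score = f$score)
  rownames(out) <- NULL
  out
}

#' Detect spots in one frame
#'
#' Full detection pipeline: [dog_filter()] band-pass, threshold and size
#' constraints ([segment_candidates()]), Gaussian point-spread fitting
#' ([fit_gaussian_psf()]) and score-based false-positive removal
#' ([score_filter()]).
#'
#' @param frame intensity matrix.
#' @param params a [detection_params()].
#' @param pixel_size um per pixel.
#' @param frame_index 0-based frame index recorded in the output.
#' @return Spot table as in [score_filter()].
#' @examples
#' cfg <- sim_config(n_frames = 1, noise_model = "none")
#' img <- render_fluorescence_frame(rbind(c(10, 10), c(30, 12)), cfg)
#' p <- detection_params(binary_threshold = 4)
#' detect_spots(img, p, pixel_size = cfg$pixel_size)
#' @export
detect_spots <- function(frame, params, pixel_size = 0.2, frame_index = 0L) {
  filtered <- dog_filter(frame, params$sigma_small, params$sigma_large)
  cand <- segment_candidates(filtered, params)
  if (nrow(cand) == 0) {
    return(score_filter(data.frame(x_px = numeric(), y_px = numeric(),
                                   sigma_fit = numeric(),
                                   amplitude = numeric(), offset = numeric(),
                                   residual_std = numeric(),
                                   score = numeric(), flagged = logical(),
                                   on_border = logical()),
                        params$score_threshold, pixel_size, frame_index))
  }
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_gaussian_psf(frame, cand[i, ], params)))
  score_filter(fits, params$score_threshold, pixel_size, frame_index)
}

#' Detect spots in every frame of a movie
#'
#' @param frames list of intensity matrices.
#' @inheritParams detect_spots
#' @param dt seconds per frame; adds a `t_s` column.
#' @return Combined spot table across frames.
#' @export
detect_spots_movie <- function(frames, params, pixel_size = 0.2, dt = 60) {
  out <- do.call(rbind, lapply(seq_along(frames), function(i)
    detect_spots(frames[[i]], params, pixel_size, frame_index = i - 1L)))
  out$t_s <- out$frame * dt
  out
}
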