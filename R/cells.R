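#' Cell-segmentation parameters
#'
#' @param cell_threshold intensity threshold on the (smoothed) magnitude of
#'   the differential-focus image used to seed cell markers; like the spot
#'   threshold it is image-set specific, typically a sizeable fraction of
#'   the expected peak cell contrast.
#' @param focus_frames indices (1-based) of the two focus planes to
#'   difference.
#' @param min_cell_area,max_cell_area area bounds (pixels^2) removing
#'   small debris and large background objects.
#' @param smooth_sigma Gaussian smoothing (pixels) applied to the
#'   differential magnitude before thresholding and watershed.
#' @param mask_fraction foreground mask threshold as a fraction of
#'   `cell_threshold`; the watershed is restricted to this mask.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(cell_threshold,
                                focus_frames = c(1, 2),
                                min_cell_area = 50,
                                max_cell_area = 10000,
                                smooth_sigma = 2,
                                mask_fraction = 0.1) {
  stopifnot(length(focus_frames) == 2, focus_frames[1] != focus_frames[2],
            min_cell_area < max_cell_area, cell_threshold > 0,
            mask_fraction > 0, mask_fraction <= 1)
  structure(list(cell_threshold = cell_threshold,
                 focus_frames = as.integer(focus_frames),
                 min_cell_area = min_cell_area,
                 max_cell_area = max_cell_area,
                 smooth_sigma = smooth_sigma,
                 mask_fraction = mask_fraction),
            class = "segmentation_params")
}

#' Differential image of two focus frames
#'
#' Cells in bright field are nearly invisible in focus but show opposite
#' contrast above and below the focal plane; the signed difference of two
#' focus frames therefore highlights cell bodies against a cancelled
#' background.
#'
#' @param stack a [render_brightfield_stack()] result or list of matrices.
#' @param focus_frames indices (1-based) of the two frames to difference.
#' @return Signed difference matrix `frame_a - frame_b`.
#' @export
differential_focus_image <- function(stack, focus_frames = c(1, 2)) {
  a <- stack[[focus_frames[1]]]
  b <- stack[[focus_frames[2]]]
  if (!all(dim(a) == dim(b))) stop("focus frames differ in shape",
                                   call. = FALSE)
  a - b
}

#' Detect cell markers from a differential-focus image
#'
#' Thresholds the smoothed magnitude of the differential image and keeps
#' connected components within the cell-area bounds; each surviving
#' component becomes a watershed marker.
#'
#' @param diff signed differential image ([differential_focus_image()]).
#' @param params a [segmentation_params()].
#' @return Integer marker label matrix (0 = background) with attribute
#'   `regions` (the [segment_candidates()]-style region table).
#' @export
detect_cell_markers <- function(diff, params) {
  s <- gaussian_blur(abs(diff), params$smooth_sigma)
  bw <- s > params$cell_threshold
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(diff), ncol(diff))
  regions <- region_table(lab)
  keep <- regions$area >= params$min_cell_area &
    regions$area <= params$max_cell_area
  regions <- regions[keep, , drop = FALSE]
  lab[!(lab %in% regions$label)] <- 0L
  if (nrow(regions) > 0) {
    lab <- matrix(match(lab, c(0L, regions$label)) - 1L,
                  nrow(lab), ncol(lab))
    regions$label <- seq_len(nrow(regions))
  }
  rownames(regions) <- NULL
  attr(lab, "regions") <- regions
  lab
}

#' Marker-based watershed segmentation of cells
#'
#' Grows the detected markers over the smoothed differential-focus relief
#' (seeded region growing, the marker-based watershed of cell-image
#' analysis), restricted to a foreground mask
#' `smoothed |diff| > mask_fraction * cell_threshold`, yielding exactly one
#' region per marker.
#'
#' @param diff signed differential image.
#' @param markers marker label matrix from [detect_cell_markers()].
#' @param params a [segmentation_params()].
#' @return A `label_image`: integer matrix (0 background, k > 0 cell k)
#'   with attribute `regions` (per-label area/centroid table).
#' @export
watershed_cells <- function(diff, markers, params) {
  if (max(markers) == 0) {
    lab <- matrix(0L, nrow(diff), ncol(diff))
    attr(lab, "regions") <- region_table(lab)
    class(lab) <- c("label_image", class(lab))
    return(lab)
  }
  s <- gaussian_blur(abs(diff), params$smooth_sigma)
  mask <- s > params$mask_fraction * params$cell_threshold
  ws <- EBImage::propagate(EBImage::Image(s), seeds = markers,
                           mask = mask, lambda = 1e-4)
  lab <- matrix(as.integer(ws), nrow(diff), ncol(diff))
  regions <- region_table(lab)
  rownames(regions) <- NULL
  attr(lab, "regions") <- regions
  class(lab) <- c("label_image", class(lab))
  lab
}

#' Segment cells in a focus stack
#'
#' Convenience composition of [differential_focus_image()],
#' [detect_cell_markers()] and [watershed_cells()].
#'
#' @param stack two-frame focus stack.
#' @param params a [segmentation_params()].
#' @return A `label_image` as from [watershed_cells()].
#' @export
segment_cells <- function(stack, params) {
  diff <- differential_focus_image(stack, params$focus_frames)
  markers <- detect_cell_markers(diff, params)
  watershed_cells(diff, markers, params)
}

#' Assign detected spots to segmented cells
#'
#' Each spot receives the label of the pixel under its rounded centre;
#' spots falling on background get label 0 and are flagged.
#'
#' @param labels a `label_image`.
#' @param spots spot table with `x_px`, `y_px` (0-based subpixel).
#' @return `spots` with added columns `cell_id` and `unassigned`.
#' @export
assign_spots_to_cells <- function(labels, spots) {
  if (nrow(spots) == 0) {
    spots$cell_id <- integer(0); spots$unassigned <- logical(0)
    return(spots)
  }
  r <- pmin(pmax(round(spots$y_px), 0), nrow(labels) - 1) + 1
  c <- pmin(pmax(round(spots$x_px), 0), ncol(labels) - 1) + 1
  spots$cell_id <- labels[cbind(r, c)]
  spots$unassigned <- spots$cell_id == 0
  spots
}

#' Per-cell spot counts for one frame
#'
#' @param labels a `label_image`.
#' @param spots assigned spot table ([assign_spots_to_cells()]).
#' @return Data frame `cell_id`, `area_px`, `cx_px`, `cy_px`, `n_spots`.
#' @export
cell_spot_counts <- function(labels, spots) {
  regions <- attr(labels, "regions")
  n_spots <- vapply(regions$label, function(l)
    sum(spots$cell_id == l), integer(1))
  data.frame(cell_id = regions$label, area_px = regions$area,
             cx_px = regions$cx_px, cy_px = regions$cy_px,
             n_spots = n_spots)
}

#' Fraction of cells containing at least one P-body over time
#'
#' Computes the per-frame fraction of segmented cells that contain one or
#' more detected spots, then averages over non-overlapping time windows
#' (default 20 minutes) to filter frame-to-frame noise.
#'
#' @param counts data frame with one row per (frame, cell): columns
#'   `frame` and `n_spots` (e.g. stacked [cell_spot_counts()] outputs).
#' @param dt seconds per frame.
#' @param window averaging window in minutes.
#' @return Data frame `window_start_min`, `window_end_min`, `fraction`,
#'   `n_frames`; attribute `per_frame` holds the unwindowed series.
#'   Frames with zero cells are skipped with a warning.
#' @export
pb_fraction_timecourse <- function(counts, dt, window = 20) {
  stopifnot(dt > 0, window > 0)
  frames <- sort(unique(counts$frame))
  frac <- vapply(frames, function(f) {
    sub <- counts[counts$frame == f, ]
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$n_spots >= 1)
  }, numeric(1))
  if (anyNA(frac)) {
    warning(sum(is.na(frac)), " frame(s) with zero cells skipped")
  }
  per_frame <- data.frame(frame = frames, t_min = frames * dt / 60,
                          fraction = frac)
  ok <- !is.na(frac)
  bin <- floor(per_frame$t_min[ok] / window)
  agg <- tapply(per_frame$fraction[ok], bin, mean)
  nfr <- tapply(per_frame$fraction[ok], bin, length)
  out <- data.frame(window_start_min = as.numeric(names(agg)) * window,
                    window_end_min = (as.numeric(names(agg)) + 1) * window,
                    fraction = as.numeric(agg),
                    n_frames = as.integer(nfr))
  rownames(out) <- NULL
  attr(out, "per_frame") <- per_frame
  out
}
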