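#' Generate a ground-truthed synthetic dataset
#'
#' Lays out `config$n_cells` mother cells in the field of view, gives each a
#' staggered budding time, bud site and daughter outline, simulates one
#' granule per mother with the fate given by `config$pb_fate` (recycled),
#' and optionally renders the fluorescence movie and bright-field focus
#' stacks and writes everything to disk. Fully reproducible from
#' `config$rng_seed`.
#'
#' Daughter fates:
#' * `"transported"` -- the mother granule hovers at the bud site and is
#'   carried into the daughter at division (wild-type-like);
#' * `"de_novo"` -- the mother granule diffuses freely throughout; the
#'   daughter assembles its own granule after division (mutant-like);
#' * `"none"` -- free diffusion in the mother only, the daughter never
#'   contains a granule.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#'   When given, writes `fluorescence.tif` (one plane per frame, 16-bit),
#'   `brightfield.tif` (two focus planes per frame, 16-bit),
#'   `truth_trajectories.csv`, `truth_cells.csv`, `truth_buds.csv` and
#'   `config.json`.
#' @param render logical; render images (set `FALSE` for trajectory-only
#'   studies, which is much faster).
#' @return List of class `pb_dataset`: `frames` (list of matrices or
#'   `NULL`), `stacks` (list of [render_brightfield_stack()] outputs or
#'   `NULL`), `truth` (list with `trajectories`, `cells`, `buds`),
#'   `config`, and `paths` when written.
#' @examples
#' cfg <- sim_config(n_frames = 20, n_cells = 2, rng_seed = 3)
#' ds <- generate_dataset(cfg, render = FALSE)
#' sapply(ds$truth$trajectories, nrow)
#' @export
generate_dataset <- function(config, out_dir = NULL, render = TRUE) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  n <- config$n_frames
  dt <- config$dt
  shape_um <- rev(config$image_shape) * config$pixel_size  # (x extent, y extent)

  fates <- rep(config$pb_fate, length.out = config$n_cells)
  layout <- scene_layout(config)

  # budding schedule: hover must start at or after t = 0 and division must
  # leave room for post-transport frames
  t_h0 <- max(0, -config$hover_start_offset)
  bud0 <- ceiling(t_h0 / dt) + 1L
  bud1 <- max(bud0, n - ceiling((config$hover_start_offset +
                                  config$hover_duration) / dt) - 5L)
  bud_times <- bud0 + round((seq_len(config$n_cells) - 1) /
                              max(1, config$n_cells - 1) *
                              max(0, bud1 - bud0) * 0.3)
  bud_times <- pmin(pmax(bud_times, 0L), n - 1L)
  division_times <- pmin(
    bud_times + ceiling((config$hover_start_offset + config$hover_duration) / dt),
    n - 1L)

  trajectories <- list()
  buds <- data.frame(cell_id = integer(), bud_time = integer(),
                     division_time = integer(), bud_x = numeric(),
                     bud_y = numeric(), fate = character())
  for (k in seq_len(config$n_cells)) {
    mother <- layout$mothers[[k]]
    u <- layout$directions[[k]]
    bud_site <- mother$center + u * mother$radius
    daughter <- list(center = mother$center +
                       u * (mother$radius + config$daughter_radius),
                     radius = config$daughter_radius)
    fate <- fates[k]
    if (fate == "transported") {
      tr <- simulate_trajectory(config, bud_time = bud_times[k],
                                bud_site = bud_site, cell = mother,
                                division_time = division_times[k],
                                daughter = daughter)
    } else {
      tr <- simulate_trajectory(config, cell = mother)
    }
    attr(tr, "track_id") <- k
    attr(tr, "cell_id") <- k
    attr(tr, "fate") <- fate
    trajectories[[length(trajectories) + 1L]] <- tr
    if (fate == "de_novo" && division_times[k] < n - 1L) {
      cfg2 <- config
      tr2 <- simulate_trajectory(cfg2, cell = daughter)
      keep <- tr2$frame >= division_times[k]
      tr2 <- trajectory(t = tr2$t[keep], x = tr2$x[keep], y = tr2$y[keep],
                        frame = tr2$frame[keep], regime = tr2$regime[keep],
                        source = "ground_truth")
      attr(tr2, "track_id") <- config$n_cells + k
      attr(tr2, "cell_id") <- k
      attr(tr2, "fate") <- "de_novo_daughter"
      trajectories[[length(trajectories) + 1L]] <- tr2
    }
    buds <- rbind(buds, data.frame(
      cell_id = k, bud_time = bud_times[k],
      division_time = division_times[k],
      bud_x = bud_site[1], bud_y = bud_site[2], fate = fate))
  }

  cells <- cell_outline_table(layout, buds, config)

  frames <- stacks <- NULL
  if (render) {
    frames <- vector("list", n)
    stacks <- vector("list", n)
    for (f in seq_len(n) - 1L) {
      pts <- do.call(rbind, lapply(trajectories, function(tr) {
        i <- match(f, tr$frame)
        if (is.na(i)) NULL else c(tr$x[i], tr$y[i])
      }))
      if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
      frames[[f + 1L]] <- render_fluorescence_frame(pts, config)
      stacks[[f + 1L]] <- render_brightfield_stack(
        frame_outlines(cells, f), config)
    }
  }

  truth <- list(trajectories = trajectories, cells = cells, buds = buds)
  out <- structure(list(frames = frames, stacks = stacks, truth = truth,
                        config = config, paths = NULL),
                   class = "pb_dataset")
  if (!is.null(out_dir)) out$paths <- write_dataset(out, out_dir)
  out
}

# grid layout of mother cells with margins; bud directions rotate around
# the compass so daughters never collide
scene_layout <- function(config) {
  nmax <- config$n_cells
  ext_x <- config$image_shape[2] * config$pixel_size
  ext_y <- config$image_shape[1] * config$pixel_size
  pitch <- 2 * (config$cell_radius + 2 * config$daughter_radius) + 1
  ncol_grid <- max(1, floor((ext_x - pitch / 2) / pitch))
  margin <- config$cell_radius + 2 * config$daughter_radius + 0.5
  mothers <- list(); directions <- list()
  for (k in seq_len(nmax)) {
    gx <- (k - 1) %% ncol_grid
    gy <- (k - 1) %/% ncol_grid
    ctr <- c(margin + gx * pitch, margin + gy * pitch)
    if (ctr[2] + margin > ext_y) {
      stop("image_shape too small for n_cells = ", nmax, call. = FALSE)
    }
    ang <- (k - 1) * (2 * pi / max(4, nmax))
    mothers[[k]] <- list(center = ctr, radius = config$cell_radius)
    directions[[k]] <- c(cos(ang), sin(ang))
  }
  list(mothers = mothers, directions = directions)
}

# per-frame outlines: mothers always present; daughters appear at bud_time
# and grow linearly to full radius at division_time
cell_outline_table <- function(layout, buds, config) {
  n <- config$n_frames
  rows <- list()
  for (k in seq_along(layout$mothers)) {
    m <- layout$mothers[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      frame = seq_len(n) - 1L, cell_id = k, type = "mother",
      cx = m$center[1], cy = m$center[2], radius = m$radius)
    b <- buds[buds$cell_id == k, ]
    # daughters bud regardless of granule fate
    if (b$bud_time <= n - 1L) {
      fr <- b$bud_time:(n - 1L)
      grow <- pmin(1, (fr - b$bud_time) /
                     max(1, b$division_time - b$bud_time))
      rad <- config$daughter_radius * (0.4 + 0.6 * grow)
      u <- layout$directions[[k]]
      ctr <- m$center + u * (m$radius + config$daughter_radius)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, cell_id = config$n_cells + k, type = "daughter",
        cx = ctr[1], cy = ctr[2], radius = rad)
    }
  }
  do.call(rbind, rows)
}

# outlines of all cells present in frame f, as a list for the renderer
frame_outlines <- function(cells, f) {
  sub <- cells[cells$frame == f, , drop = FALSE]
  lapply(seq_len(nrow(sub)), function(i)
    list(center = c(sub$cx[i], sub$cy[i]), radius = sub$radius[i],
         cell_id = sub$cell_id[i], type = sub$type[i]))
}

write_dataset <- function(ds, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- list(
    trajectories = file.path(out_dir, "truth_trajectories.csv"),
    cells = file.path(out_dir, "truth_cells.csv"),
    buds = file.path(out_dir, "truth_buds.csv"),
    config = file.path(out_dir, "config.json")
  )
  tr_df <- do.call(rbind, lapply(ds$truth$trajectories, function(tr) {
    data.frame(track_id = attr(tr, "track_id"),
               cell_id = attr(tr, "cell_id"), fate = attr(tr, "fate"),
               frame = tr$frame, t_s = tr$t, x_um = tr$x, y_um = tr$y,
               regime = tr$regime)
  }))
  write.csv(tr_df, paths$trajectories, row.names = FALSE)
  write.csv(ds$truth$cells, paths$cells, row.names = FALSE)
  write.csv(ds$truth$buds, paths$buds, row.names = FALSE)
  cfg <- ds$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  if (!is.null(ds$frames)) {
    paths$fluorescence <- file.path(out_dir, "fluorescence.tif")
    write_movie_tiff(ds$frames, paths$fluorescence)
    paths$brightfield <- file.path(out_dir, "brightfield.tif")
    planes <- unlist(lapply(ds$stacks, function(s) list(s[[1]], s[[2]])),
                     recursive = FALSE)
    write_movie_tiff(planes, paths$brightfield)
  }
  paths
}

#' Write a list of photon-count matrices as a 16-bit multi-frame TIFF
#'
#' Values are clamped to `[0, 65535]` (the CCD dynamic range emulated by
#' the simulator).
#'
#' @param frames list of numeric matrices.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_movie_tiff <- function(frames, path) {
  scaled <- lapply(frames, function(m) pmin(pmax(m, 0), 65535) / 65535)
  ok <- tiff::writeTIFF(scaled, path, bits.per.sample = 16,
                        compression = "none")
  invisible(path)
}

#' Read a multi-frame 16-bit TIFF written by [write_movie_tiff()]
#'
#' @param path TIFF file.
#' @return List of numeric matrices in photon counts.
#' @export
read_movie_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  lapply(planes, function(m) m * 65535)
}
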