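#!/usr/bin/env Rscript
# Command-line front end over the pbtrack package.
#
#   pbtrack simulate --config cfg.json --out dir/ --seed N
#   pbtrack detect   --in movie.tif --params det.json --out spots.csv
#   pbtrack segment  --stack bf.tif --spots spots.csv --params seg.json --out dir/
#   pbtrack motion   --tracks tracks.csv --bud-times buds.csv --out dir/
#   pbtrack run-all  --config cfg.json --det det.json --seg seg.json --out dir/
#
# Config files are JSON objects whose fields are the arguments of
# sim_config(), detection_params() and segmentation_params().

suppressPackageStartupMessages({
  library(pbtrack)
  library(jsonlite)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) {
  stop("usage: pbtrack <simulate|detect|segment|motion|run-all> [options]")
}
verb <- argv[1]
kv <- list()
i <- 2
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  kv[[key]] <- argv[i + 1]
  i <- i + 2
}
need <- function(k) {
  if (is.null(kv[[k]])) stop("missing required option --", k)
  kv[[k]]
}
load_json <- function(path) fromJSON(path, simplifyVector = TRUE)

make_config <- function(path, seed = NULL) {
  fields <- if (is.null(path)) list() else load_json(path)
  if (!is.null(seed)) fields$rng_seed <- as.integer(seed)
  do.call(sim_config, fields)
}

switch(verb,
  simulate = {
    cfg <- make_config(kv$config, kv$seed)
    ds <- generate_dataset(cfg, out_dir = need("out"))
    cat("simulated", cfg$n_frames, "frames,", cfg$n_cells, "cells ->",
        need("out"), "\n")
  },
  detect = {
    frames <- read_movie_tiff(need("in"))
    p <- do.call(detection_params, load_json(need("params")))
    px <- if (is.null(kv[["pixel-size"]])) 0.2 else as.numeric(kv[["pixel-size"]])
    dt <- if (is.null(kv$dt)) 60 else as.numeric(kv$dt)
    spots <- detect_spots_movie(frames, p, pixel_size = px, dt = dt)
    write.csv(spots, need("out"), row.names = FALSE)
    cat(nrow(spots), "spots ->", need("out"), "\n")
  },
  segment = {
    planes <- read_movie_tiff(need("stack"))
    p <- do.call(segmentation_params, load_json(need("params")))
    spots <- read.csv(need("spots"))
    out_dir <- need("out")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    counts <- do.call(rbind, lapply(seq_len(length(planes) %/% 2), function(f) {
      stack <- list(planes[[2 * f - 1]], planes[[2 * f]])
      labels <- segment_cells(stack, p)
      sp <- assign_spots_to_cells(labels, spots[spots$frame == f - 1L, ])
      cbind(frame = f - 1L, cell_spot_counts(labels, sp))
    }))
    write.csv(counts, file.path(out_dir, "cells.csv"), row.names = FALSE)
    dt <- if (is.null(kv$dt)) 60 else as.numeric(kv$dt)
    frac <- pb_fraction_timecourse(counts, dt = dt)
    write.csv(frac, file.path(out_dir, "pb_fraction.csv"), row.names = FALSE)
    cat("per-cell counts and P-body fraction ->", out_dir, "\n")
  },
  motion = {
    tracks <- read_tracks_csv(need("tracks"))
    tracks <- tracks[vapply(tracks, nrow, 1L) >= 5]  # drop orphan stubs
    buds <- if (is.null(kv[["bud-times"]])) NULL else read.csv(kv[["bud-times"]])
    out_dir <- need("out")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- do.call(rbind, lapply(names(tracks), function(id) {
      tr <- tracks[[id]]
      bt <- bs <- NULL
      if (!is.null(buds) && id %in% buds$track_id) {
        row <- buds[buds$track_id == id, ]
        bt <- row$bud_time_s
        bs <- c(row$bud_x, row$bud_y)
      }
      cbind(track_id = id,
            suppressWarnings(motion_report(tr, bud_time = bt, bud_site = bs)))
    }))
    write.csv(report, file.path(out_dir, "motion_report.csv"),
              row.names = FALSE)
    cat("motion report for", length(tracks), "tracks ->", out_dir, "\n")
  },
  "run-all" = {
    cfg <- make_config(kv$config, kv$seed)
    det <- do.call(detection_params, load_json(need("det")))
    seg <- do.call(segmentation_params, load_json(need("seg")))
    res <- run_pipeline(cfg, det, seg, out_dir = need("out"))
    cat("pipeline report ->", need("out"), "\n")
  },
  stop("unknown verb: ", verb)
)
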