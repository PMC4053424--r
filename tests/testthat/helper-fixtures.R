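# shared fixtures: all synthetic, generated in code

# unbounded free-diffusion track (no cell outline in the way)
brownian_track <- function(n, D, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(2 * D * dt)
  trajectory(t = (seq_len(n) - 1) * dt,
             x = cumsum(c(0, rnorm(n - 1, 0, sd))),
             y = cumsum(c(0, rnorm(n - 1, 0, sd))))
}

# straight-line track at constant speed (um/s) along x
ballistic_track <- function(n, speed, dt) {
  trajectory(t = (seq_len(n) - 1) * dt,
             x = speed * dt * (seq_len(n) - 1), y = rep(0, n))
}

# small noiseless config for image tests
quiet_config <- function(...) {
  sim_config(n_frames = 1, noise_model = "none", ...)
}

# the default hover-study conditions at coarse (60 s) sampling: a granule
# in a 2.5 um cell, hovering from 0.5 h before to 0.25 h after budding
hover_config <- function(n_frames = 240) {
  sim_config(n_frames = n_frames, dt = 60, D_free = 0.01,
             corral_sigma = 0.2, corral_tau = 20,
             hover_start_offset = -1800, hover_duration = 2700)
}

hover_cell <- list(center = c(0, 0), radius = 2.5)

# greedy matching of detections to ground truth within tol (px);
# returns c(tp, fp, fn)
match_detections <- function(spots, truth_px, tol = 2) {
  used <- rep(FALSE, nrow(spots))
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth_px))) {
    d <- sqrt((spots$x_px - truth_px[i, 1])^2 +
                (spots$y_px - truth_px[i, 2])^2)
    j <- which(d <= tol & !used)
    if (length(j) > 0) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    } else {
      fn <- fn + 1L
    }
  }
  c(tp = tp, fp = sum(!used), fn = fn)
}
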