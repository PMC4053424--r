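test_that("zero-noise limit gives a constant trajectory", {
  cfg <- sim_config(n_frames = 50, D_free = 0)
  set.seed(1)
  tr <- simulate_trajectory(cfg, cell = list(center = c(5, 5), radius = 3))
  expect_equal(tr$x, rep(5, 50))
  expect_equal(tr$y, rep(5, 50))
  expect_true(all(tr$regime == "free"))
})

test_that("free-diffusion increments follow the generating law", {
  cfg <- sim_config(n_frames = 10000, dt = 10, D_free = 0.01)
  set.seed(101)
  tr <- simulate_trajectory(cfg, cell = list(center = c(0, 0), radius = Inf))
  dx <- diff(tr$x)
  # per-axis mean squared step within 5% of 2 D dt = 0.2 um^2
  expect_lt(abs(mean(dx^2) / (2 * 0.01 * 10) - 1), 0.05)
  # distributional check against the exact increment law
  ks <- suppressWarnings(
    stats::ks.test(dx, "pnorm", 0, sqrt(2 * 0.01 * 10)))
  expect_gt(ks$p.value, 0.01)
})

test_that("corralled regime is stationary around the bud site", {
  # long hover window; skip the first 50 frames of relaxation
  cfg <- sim_config(n_frames = 1600, dt = 10, corral_sigma = 0.2,
                    corral_tau = 20, hover_start_offset = -1000,
                    hover_duration = 14000)
  set.seed(7)
  tr <- simulate_trajectory(cfg, bud_time = 100, bud_site = c(5, 5),
                            cell = list(center = c(5, 5), radius = 50))
  hov <- which(tr$regime == "corralled")
  expect_gt(length(hov), 1000)
  sub <- tr[hov[hov > hov[1] + 50], ]
  expect_lt(abs(sd(sub$x - 5) / 0.2 - 1), 0.15)
  expect_lt(abs(sd(sub$y - 5) / 0.2 - 1), 0.15)
})

test_that("transport displaces at transport_speed and regimes partition", {
  cfg <- sim_config(n_frames = 200, dt = 10, transport_speed = 0.3,
                    hover_start_offset = -300, hover_duration = 600)
  set.seed(3)
  mother <- list(center = c(5, 5), radius = 2.5)
  daughter <- list(center = c(9.5, 5), radius = 1.5)
  tr <- simulate_trajectory(cfg, bud_time = 60, bud_site = c(7.5, 5),
                            cell = mother, division_time = 120,
                            daughter = daughter)
  expect_setequal(unique(tr$regime), c("free", "corralled", "transport"))
  # transport steps move at transport_speed * dt (last one may be shorter)
  ti <- which(tr$regime == "transport")
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)[ti - 1]
  expect_true(all(steps <= 0.3 * 10 + 1e-9))
  expect_equal(steps[-length(steps)], rep(3, length(steps) - 1),
               tolerance = 1e-9)
  # trajectory ends inside the daughter outline
  last <- nrow(tr)
  expect_lt(sqrt((tr$x[last] - 9.5)^2 + (tr$y[last] - 5)^2), 1.5 + 1e-9)
})

test_that("trajectory stays inside its bounding outline", {
  cfg <- sim_config(n_frames = 2000, dt = 10, D_free = 0.05)
  set.seed(11)
  tr <- simulate_trajectory(cfg, cell = list(center = c(5, 5), radius = 2))
  expect_true(all(sqrt((tr$x - 5)^2 + (tr$y - 5)^2) <= 2 + 1e-9))
})

test_that("hover window past trajectory end truncates with warning", {
  cfg <- sim_config(n_frames = 50, dt = 10, hover_start_offset = -100,
                    hover_duration = 5000)
  set.seed(2)
  expect_warning(
    simulate_trajectory(cfg, bud_time = 40, bud_site = c(0, 0),
                        cell = list(center = c(0, 0), radius = 3)),
    "truncated")
})

test_that("non-positive corral_tau is rejected", {
  expect_error(sim_config(corral_tau = 0), "corral_tau")
  expect_error(sim_config(corral_tau = -5), "corral_tau")
})

test_that("fluorescence rendering matches its analytic model", {
  cfg <- quiet_config()
  # zero spots, zero noise: constant background
  img <- render_fluorescence_frame(matrix(numeric(0), 0, 2), cfg)
  expect_equal(img, matrix(cfg$background, 256, 256),
               ignore_attr = TRUE)
  # one spot at a pixel centre: maximum at that pixel; photons conserved
  img <- render_fluorescence_frame(rbind(c(10, 16)), cfg)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(16 / 0.2 + 1, 10 / 0.2 + 1))
  expect_equal(sum(img - cfg$background), cfg$spot_amplitude,
               tolerance = 1e-6)
})

test_that("seeded rendering is deterministic", {
  cfg <- sim_config(n_frames = 1, noise_model = "poisson")
  set.seed(42)
  a <- render_fluorescence_frame(rbind(c(10, 10)), cfg)
  set.seed(42)
  b <- render_fluorescence_frame(rbind(c(10, 10)), cfg)
  expect_identical(a, b)
})

test_that("amplitude must be positive and spots inside bounds", {
  cfg <- quiet_config()
  cfg$spot_amplitude <- 0
  expect_error(render_fluorescence_frame(rbind(c(10, 10)), cfg),
               "amplitude")
  cfg2 <- quiet_config()
  expect_error(render_fluorescence_frame(rbind(c(60, 10)), cfg2),
               "bounds")
})

test_that("bright-field stack: no cells means identical frames", {
  cfg <- quiet_config()
  st <- render_brightfield_stack(list(), cfg)
  expect_equal(st[[1]], st[[2]])
  expect_equal(differential_focus_image(st), matrix(0, 256, 256))
})

test_that("differential image peaks inside the cell outline", {
  cfg <- quiet_config()
  st <- render_brightfield_stack(list(list(center = c(20, 25), radius = 2.5)),
                                 cfg)
  d <- abs(differential_focus_image(st))
  peak <- which(d == max(d), arr.ind = TRUE)  # [row, col] 1-based
  pos_um <- c((peak[1, 2] - 1) * 0.2, (peak[1, 1] - 1) * 0.2)
  expect_lt(sqrt(sum((pos_um - c(20, 25))^2)), 2.5)
})

test_that("touching outlines are flagged as overlapping", {
  cfg <- quiet_config()
  st <- render_brightfield_stack(
    list(list(center = c(15, 15), radius = 2.5),
         list(center = c(19.5, 15), radius = 2.5)), cfg)
  expect_true(attr(st, "overlap"))
})

test_that("generate_dataset is reproducible from its seed", {
  cfg <- sim_config(n_frames = 5, n_cells = 2, image_shape = c(128, 128),
                    hover_start_offset = -20, hover_duration = 40,
                    rng_seed = 99)
  d1 <- withr::with_tempdir({
    suppressWarnings(generate_dataset(cfg, out_dir = "a", render = FALSE))
    readBin(file.path("a", "truth_trajectories.csv"), "raw", 1e6)
  })
  d2 <- withr::with_tempdir({
    suppressWarnings(generate_dataset(cfg, out_dir = "a", render = FALSE))
    readBin(file.path("a", "truth_trajectories.csv"), "raw", 1e6)
  })
  expect_identical(d1, d2)
})

test_that("single-frame dataset is a valid degenerate case", {
  cfg <- sim_config(n_frames = 1, n_cells = 1, image_shape = c(128, 128),
                    hover_start_offset = -20, hover_duration = 40)
  ds <- suppressWarnings(generate_dataset(cfg, render = TRUE))
  expect_length(ds$frames, 1)
  expect_equal(nrow(ds$truth$trajectories[[1]]), 1)
})

test_that("transported granules cross into the daughter exactly once", {
  cfg <- sim_config(n_frames = 120, dt = 60, n_cells = 3,
                    hover_start_offset = -600, hover_duration = 1200,
                    pb_fate = "transported", rng_seed = 5)
  ds <- generate_dataset(cfg, render = FALSE)
  for (k in seq_len(3)) {
    tr <- ds$truth$trajectories[[k]]
    b <- ds$truth$buds[k, ]
    dg <- ds$truth$cells[ds$truth$cells$cell_id == cfg$n_cells + k, ]
    ctr <- c(dg$cx[1], dg$cy[1]); R <- max(dg$radius)
    inside <- sqrt((tr$x - ctr[1])^2 + (tr$y - ctr[2])^2) <= R + 1e-9
    crossings <- sum(diff(inside) == 1)
    expect_equal(crossings, 1)
    expect_true(inside[length(inside)])
  }
})
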