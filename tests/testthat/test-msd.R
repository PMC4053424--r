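test_that("steps and velocities follow directly from coordinates", {
  still <- trajectory(t = seq(0, 40, 10), x = rep(1, 5), y = rep(2, 5))
  sv <- steps_and_velocities(still)
  expect_true(all(sv$step == 0) && all(sv$velocity == 0))
  line <- trajectory(t = seq(0, 40, 10), x = seq(0, 4, 1), y = rep(0, 5))
  sv <- steps_and_velocities(line)
  expect_equal(sv$step, rep(1, 4))
  expect_equal(sv$velocity, rep(0.1, 4))
  # free diffusion: mean squared step within 5% of 4 D dt
  tr <- brownian_track(10000, 0.01, 10, seed = 55)
  expect_lt(abs(mean(steps_and_velocities(tr)$step^2) / 0.4 - 1), 0.05)
})

test_that("non-uniform sampling is flagged and uses per-interval dt", {
  tr <- trajectory(t = c(0, 10, 30, 40), x = c(0, 1, 3, 4), y = rep(0, 4))
  expect_warning(sv <- steps_and_velocities(tr), "non-uniform")
  expect_equal(sv$velocity, c(0.1, 0.1, 0.1))
})

test_that("bud distance series is the plain Euclidean distance", {
  at_site <- trajectory(t = 0:4, x = rep(1, 5), y = rep(1, 5))
  expect_true(all(bud_distance_series(at_site, c(1, 1))$distance == 0))
  ang <- seq(0, 2 * pi, length.out = 10)
  circ <- trajectory(t = 0:9, x = 1 + 2 * cos(ang), y = 3 + 2 * sin(ang))
  expect_equal(bud_distance_series(circ, c(1, 3))$distance, rep(2, 10))
})

test_that("hovering granules sit closer to the bud site than before", {
  cfg <- hover_config()
  set.seed(21)
  tr <- simulate_trajectory(cfg, bud_time = 120, bud_site = c(2.5, 0),
                            cell = hover_cell)
  d <- bud_distance_series(tr, c(2.5, 0))$distance
  hov <- tr$regime == "corralled"
  expect_lt(mean(d[hov]), mean(d[!hov & tr$t < 120 * 60]))
})

test_that("MSD matches closed forms and is time-reversal invariant", {
  still <- trajectory(t = seq(0, 90, 10), x = rep(0, 10), y = rep(0, 10))
  expect_true(all(msd(still, 5)$msd == 0))
  # ballistic: MSD(k dt) = (v k dt)^2
  bal <- ballistic_track(50, 0.1, 10)
  m <- msd(bal, 10)
  expect_equal(m$msd, (0.1 * m$lag_s)^2)
  expect_equal(m$msd[m$lag == 0], 0)
  # reversal invariance
  tr <- brownian_track(300, 0.01, 10, seed = 77)
  rev_tr <- trajectory(t = tr$t, x = rev(tr$x), y = rev(tr$y))
  expect_equal(msd(tr, 20)$msd, msd(rev_tr, 20)$msd)
})

test_that("lags with fewer than 3 pairs are dropped and flagged", {
  tr <- brownian_track(6, 0.01, 10, seed = 1)
  m <- msd(tr, 5)
  expect_false(any(m$lag %in% 4:5))
  expect_equal(attr(m, "dropped_lags"), 4:5)
})

test_that("diffusion coefficient recovers exact and simulated D", {
  # exact line MSD = 4 * 0.02 * t
  curve <- structure(
    data.frame(lag = 0:5, lag_s = seq(0, 50, 10),
               msd = 4 * 0.02 * seq(0, 50, 10), n_pairs = 100),
    class = c("msd_curve", "data.frame"))
  fit <- diffusion_coefficient(curve, fit_lags = 1:4)
  expect_equal(fit$D, 0.02)
  expect_length(fit$flags, 0)
  # ballistic input is flagged by the curvature check
  bal <- msd(ballistic_track(100, 0.1, 10), 6)
  expect_true("curvature" %in% diffusion_coefficient(bal, 1:6)$flags)
  # ensemble of free-diffusion tracks: slope/4 within 10% of D
  set.seed(91)
  Ds <- replicate(50, {
    tr <- brownian_track(600, 0.01, 10)
    diffusion_coefficient(msd(tr, 4), 1:4)$D
  })
  expect_lt(abs(mean(Ds) / 0.01 - 1), 0.10)
})

test_that("D recovery holds across magnitudes", {
  set.seed(13)
  for (D in c(0.001, 0.01, 0.1)) {
    Ds <- replicate(50, {
      tr <- brownian_track(600, D, 10)
      diffusion_coefficient(msd(tr, 4), 1:4)$D
    })
    expect_lt(abs(median(Ds) / D - 1), 0.15)
  }
})

test_that("confined motion plateaus below the free-diffusion line", {
  cfg <- sim_config(n_frames = 2000, dt = 10, corral_sigma = 0.2,
                    corral_tau = 20, hover_start_offset = -0.5 * 10,
                    hover_duration = 1.9e4)
  set.seed(8)
  tr <- simulate_trajectory(cfg, bud_time = 10, bud_site = c(0, 0),
                            cell = list(center = c(0, 0), radius = 50))
  sub <- as_trajectory(tr[tr$regime == "corralled", ][100:1500, ])
  m <- msd(sub, 60)
  # plateau at long lags near 4 sigma^2
  plateau <- mean(m$msd[m$lag >= 40])
  expect_lt(abs(plateau / (4 * 0.2^2) - 1), 0.25)
  # apparent D from the plateau far below the free-diffusion D
  fitD <- diffusion_coefficient(m, fit_lags = 40:60)$D
  expect_lt(fitD, 0.1 * cfg$D_free)
})

test_that("windowed diffusion agrees across windows for homogeneous motion", {
  set.seed(35)
  ratios <- replicate(20, {
    tr <- brownian_track(600, 0.01, 10)
    wd <- windowed_diffusion(tr, bud_time = 3000, window = 900)
    wd$D_during / wd$D_before
  })
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.4)
})

test_that("confined budding window halves the apparent D; controls do not", {
  cfg <- sim_config(n_frames = 600, dt = 10, D_free = 0.01,
                    corral_sigma = 0.2, corral_tau = 20,
                    hover_start_offset = -1500, hover_duration = 3000)
  free_cell <- list(center = c(0, 0), radius = Inf)
  set.seed(42)
  red <- replicate(20, {
    tr <- simulate_trajectory(cfg, bud_time = 300, bud_site = c(0, 0),
                              cell = free_cell)
    windowed_diffusion(tr, bud_time = 3000)$reduction
  })
  expect_gt(mean(red), 0.5)
  # mutant-like: no corral, no significant reduction
  set.seed(43)
  Db <- Dd <- numeric(20)
  for (i in 1:20) {
    tr <- simulate_trajectory(cfg, cell = free_cell)
    wd <- windowed_diffusion(tr, bud_time = 3000)
    Db[i] <- wd$D_before; Dd[i] <- wd$D_during
  }
  expect_gt(ks_compare(Db, Dd)$p_value, 0.05)
})

test_that("windows with too few points are rejected", {
  tr <- brownian_track(50, 0.01, 10, seed = 3)
  expect_error(windowed_diffusion(tr, bud_time = 250, window = 40),
               "points")
})

test_that("KS comparison behaves at its extremes and under the null", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_compare(1:5, 11:15)
  expect_equal(disjoint$statistic, 1)
  # null calibration: p roughly uniform over seeded repeats
  set.seed(101)
  ps <- replicate(200, ks_compare(rnorm(100), rnorm(100))$p_value)
  expect_gt(median(ps), 0.35)
  expect_lt(median(ps), 0.65)
  expect_warning(ks_compare(1:2, 2:3), "fewer than 3")
})
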