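test_that("trajectory generator is deterministic and respects geometry", {
  a <- simulate_trajectory(duration = 60, seed = 11)
  b <- simulate_trajectory(duration = 60, seed = 11)
  expect_identical(a, b)
  c <- simulate_trajectory(duration = 60, seed = 12)
  expect_false(identical(a$x1, c$x1))

  # track positions confined to the annulus
  r <- sqrt(a$x1^2 + a$y1^2)
  expect_true(all(r <= 75 + 1e-9))
  expect_true(all(r >= 60 - 1e-9))
  expect_equal(nrow(a), 60 * 50)
})

test_that("default track behaviour matches the published summary ranges", {
  # per-rat means: travelled distance 29.7-50.28 m, turns 79-158 in ~10 min
  dists <- numeric(5); revs <- integer(5)
  for (s in 1:5) {
    tr <- simulate_trajectory(duration = 600, seed = s)
    dists[s] <- traj_travelled_distance(tr) / 100
    revs[s] <- attr(tr, "n_reversals")
  }
  expect_true(all(dists >= 29.7 & dists <= 50.28))
  expect_true(all(revs >= 79 & revs <= 158))
})

test_that("travelled distance equals the per-sample Euclidean sum oracle", {
  tr <- simulate_trajectory(duration = 30, seed = 4)
  oracle <- 0
  for (i in 2:nrow(tr)) {
    oracle <- oracle + sqrt((tr$x1[i] - tr$x1[i - 1])^2 +
                              (tr$y1[i] - tr$y1[i - 1])^2)
  }
  expect_equal(traj_travelled_distance(tr), oracle, tolerance = 1e-12)
})

test_that("zero mean speed gives a stationary path", {
  tr <- simulate_trajectory(duration = 30, mean_speed = 0, pause_rate = 0,
                            seed = 2)
  expect_lt(traj_travelled_distance(tr), 1e-6)
})

test_that("invalid behaviour parameters error", {
  expect_error(simulate_trajectory(duration = -5), "duration")
  expect_error(simulate_trajectory(sample_rate = 0), "sample_rate")
  expect_error(simulate_trajectory(mean_speed = -1), "mean_speed")
})

test_that("markers are 5 cm apart and define heading", {
  tr <- simulate_trajectory(duration = 30, seed = 6)
  d <- sqrt((tr$x1 - tr$x2)^2 + (tr$y1 - tr$y2)^2)
  expect_equal(d, rep(5, nrow(tr)), tolerance = 1e-9)
  expect_true(all(is.finite(traj_heading(tr))))
})

test_that("spike generation is deterministic and scales with peak rate", {
  ts <- track_session()
  gt1 <- ground_truth("path_integrated", peak_rate = 4)
  gt2 <- ground_truth("path_integrated", peak_rate = 8)
  s1 <- generate_track_spikes(ts$traj, gt1, seed = 9)
  s1b <- generate_track_spikes(ts$traj, gt1, seed = 9)
  s2 <- generate_track_spikes(ts$traj, gt2, seed = 9)
  expect_identical(as.numeric(s1), as.numeric(s1b))
  ratio <- length(s2) / length(s1)
  expect_gt(ratio, 1.6)  # doubling peak rate ~doubles counts (Poisson error)
  expect_lt(ratio, 2.4)
})

test_that("zero peak rate gives an empty spike train", {
  ts <- track_session()
  gt <- ground_truth("path_integrated", peak_rate = 0, baseline_rate = 0)
  expect_length(generate_track_spikes(ts$traj, gt, seed = 1), 0)
  ar <- arena_session()
  gt2 <- ground_truth("slice2d", peak_rate = 0, baseline_rate = 0)
  expect_length(generate_grid_spikes_2d(ar, gt2, seed = 1), 0)
})

test_that("unknown coding model is rejected, slice2d on track warns in 2d", {
  expect_error(ground_truth("martian"))
  ts <- track_session()
  gt <- ground_truth("slice2d")
  expect_warning(generate_grid_spikes_2d(ts$traj, gt, seed = 1), "track")
})

test_that("allocentric generator puts fields at identical positions across laps", {
  # noise-free check on the rate profile itself: rate is a function of
  # track position only
  tr <- circle_trajectory(radius = 75, speed = 10, duration = 200)
  ser <- unwrap_cumulative_angle(tr)
  gt <- ground_truth("allocentric", spacing = 150, peak_rate = 50,
                     baseline_rate = 0)
  sp <- generate_track_spikes(tr, gt, seed = 3)
  lm1 <- lap_position_matrix(sp, ser, min_occupancy_s = 1)
  pr <- allocentric_correlation(lm1)
  expect_gt(pr$mean_r, 0.9)
})

test_that("time-model spikes are periodic in time at the set period", {
  ts <- track_session()
  gt <- ground_truth("time", spacing = 10, field_width = 1, peak_rate = 10)
  sp <- generate_track_spikes(ts$traj, gt, seed = 5)
  prof <- linearize_activity(sp, ts$series, "time")
  ac <- autocorrelation_1d(prof)
  expect_equal(attr(ac, "first_peak_lag"), 10, tolerance = 1.01)
})

test_that("path-integrated spacing 150 on a 471.24 cm track precesses 21.24 cm per lap", {
  # residual by modular arithmetic: 471.2389 mod 150
  expect_equal(track_circumference(75) %% 150, 21.23889804, tolerance = 1e-6)
  tr <- circle_trajectory(radius = 75, speed = 10, duration = 300)
  ser <- unwrap_cumulative_angle(tr)
  gt <- ground_truth("path_integrated", spacing = 150, peak_rate = 40,
                     baseline_rate = 0)
  sp <- generate_track_spikes(tr, gt, seed = 8)
  lm1 <- lap_position_matrix(sp, ser, min_occupancy_s = 1)
  # adjacent laps should correlate best when re-aligned by the residual
  pc <- path_integrated_correlation(lm1, 150)
  al <- allocentric_correlation(lm1)
  expect_gt(pc$mean_r, al$mean_r)
  expect_equal(pc$residual, track_circumference(75) %% 150, tolerance = 1e-9)
})

test_that("LFP generator: length, purity and warnings", {
  tr <- arena_session()
  lfp <- generate_lfp(tr, f0 = 8, noise_sd = 0, seed = 2)
  expect_equal(nrow(lfp), floor(traj_duration(tr) * 1024))
  expect_warning(generate_lfp(tr, f0 = 2, seed = 2), "theta")
  # stationary path, slope irrelevant: instantaneous frequency exactly f0
  still <- simulate_trajectory(duration = 30, mean_speed = 0, pause_rate = 0,
                               seed = 3)
  l2 <- generate_lfp(still, f0 = 8, speed_slope = 0.5, noise_sd = 0, seed = 4)
  th <- lfp_theta(l2)
  expect_equal(th$peak_frequency, 8, tolerance = 0.05)
})

test_that("tuned spike generators match circular statistics oracles", {
  tr <- arena_session()
  # kappa = 0: flat tuning
  sp0 <- generate_tuned_spikes(tr, tuning_spec("head_direction",
                                               concentration = 0,
                                               peak_rate = 5), seed = 4)
  expect_lt(hd_tuning(sp0, tr)$vector_length, 0.1)
  # kappa = 4: Rayleigh vector length I1(4)/I0(4) = 0.8635
  sp4 <- generate_tuned_spikes(tr, tuning_spec("head_direction",
                                               concentration = 4), seed = 5)
  bessel_ratio <- besselI(4, 1) / besselI(4, 0)
  expect_equal(hd_tuning(sp4, tr)$vector_length, bessel_ratio,
               tolerance = 0.06)
  # speed slope recovery within 10%
  spv <- generate_tuned_spikes(tr, tuning_spec("speed", slope = 0.5,
                                               intercept = 1), seed = 6)
  st <- speed_tuning(spv, tr)
  expect_equal(st$slope, 0.5, tolerance = 0.1)
})

test_that("head-direction spec requires a two-marker trajectory", {
  tr <- arena_session()
  tr1 <- tr[, c("t", "x1", "y1")]
  expect_error(generate_tuned_spikes(tr1, tuning_spec("head_direction"),
                                     seed = 1), "marker")
})
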