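C75 <- track_circumference(75)

make_profile <- function(rate, bin = 10, frame = "path_integrated") {
  structure(tibble::tibble(bin_mid = (seq_along(rate) - 0.5) * bin,
                           count = rate, occupancy = 1, rate = rate),
            class = c("gt_linear_profile", "tbl_df", "tbl", "data.frame"),
            frame = frame, bin = bin)
}

test_that("1D autocorrelation: periodic profile, lag 0, constant error", {
  x <- (seq_len(120) - 0.5) * 10
  prof <- make_profile(5 * exp(-((x %% 100) - 50)^2 / 200))
  ac <- autocorrelation_1d(prof)
  expect_equal(ac$r[ac$lag == 0], 1)
  expect_equal(attr(ac, "first_peak_lag"), 100, tolerance = 10.1)
  expect_error(autocorrelation_1d(make_profile(rep(2, 100))), "constant")
})

test_that("autocorrelation peaks are local maxima separated by >= 2 bins", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 51)
  ac <- autocorrelation_1d(linearize_activity(sp, ts$series, "path_integrated"))
  pk <- attr(ac, "peak_lags")
  expect_gte(length(pk), 2)
  expect_true(all(diff(pk) >= 20))          # 2 bins of 10 cm
  expect_true(all(attr(ac, "peak_values") > 0))
})

test_that("Fisher Z transformation matches atanh and round-trips", {
  expect_equal(as.numeric(fisher_z(0)), 0)
  expect_equal(as.numeric(fisher_z(0.6)), 0.6931472, tolerance = 1e-6)
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(fisher_z_inv(as.numeric(fisher_z(r))), r, tolerance = 1e-9)
  expect_error(fisher_z(1.2), "outside")
  z1 <- fisher_z(1)
  expect_true(attr(z1, "clipped"))
  expect_lt(as.numeric(z1), Inf)
})

test_that("path-integration correction: exact-divisor spacing leaves laps unshifted", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 52)
  lm1 <- lap_position_matrix(sp, ts$series)
  al <- allocentric_correlation(lm1)$mean_r
  pc3 <- path_integrated_correlation(lm1, C75 / 3)
  expect_lt(abs(pc3$mean_r - al), 1e-12)
  expect_equal(pc3$residual, 0)
  # field distance below the bin width falls back with a flag
  pc_small <- path_integrated_correlation(lm1, 5)
  expect_false(pc_small$corrected)
  expect_equal(pc_small$mean_r, al)
})

test_that("correction raises the lap correlation for path-integrated cells", {
  wins <- 0
  for (s in 1:5) {
    traj <- simulate_trajectory(duration = 600, seed = 400 + s)
    ser <- unwrap_cumulative_angle(traj)
    sp <- generate_track_spikes(traj,
                                ground_truth("path_integrated", spacing = 150),
                                seed = 500 + s)
    lm1 <- lap_position_matrix(sp, ser)
    fd <- attr(autocorrelation_1d(
      linearize_activity(sp, ser, "path_integrated")), "first_peak_lag")
    al <- allocentric_correlation(lm1)$mean_r
    pc <- path_integrated_correlation(lm1, fd)$mean_r
    if (pc > al) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("split-half control recovers the correction for PI cells", {
  # a persistent walk (few reversals) so the second half spans several laps
  traj <- simulate_trajectory(duration = 600, turn_rate = 1, seed = 61)
  ser <- unwrap_cumulative_angle(traj)
  sp <- generate_track_spikes(traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 53)
  shc <- split_half_control(sp, ser)
  expect_equal(shc$field_distance, 150, tolerance = 10.1)
  expect_gt(shc$corrected_r, shc$allocentric_r)
  # an allocentric cell gains nothing from the correction
  sp_al <- generate_track_spikes(
    traj, ground_truth("allocentric",
                       field_positions = c(40, 170, 320)), seed = 54)
  shc2 <- split_half_control(sp_al, ser)
  expect_lte(shc2$corrected_r, shc2$allocentric_r + 0.05)
})

test_that("jitter null: conservation, determinism and separation", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 54)
  jn <- jitter_null(sp, ts$series, "path_integrated", n = 60, seed = 9)
  jn2 <- jitter_null(sp, ts$series, "path_integrated", n = 60, seed = 9)
  expect_identical(jn$null, jn2$null)
  expect_length(jn$null, 60)
  # strongly periodic cell exceeds its own null threshold
  expect_gt(jn$observed, jn$threshold)
  # jitter preserves spike count
  expect_length(gridtrack:::jitter_train(sp, max(ts$series$t), "interval",
                                         0.01, 0.5), length(sp))
  expect_error(jitter_null(sp, ts$series, "path_integrated", n = 0), "n must")
  expect_error(jitter_null(sp[1], ts$series, "path_integrated"), "2 spikes")
})

test_that("threshold monotonicity: higher percentile flags fewer cells", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 55)
  jn95 <- jitter_null(sp, ts$series, "path_integrated", n = 80,
                      percentile = 95, seed = 3)
  jn99 <- jitter_null(sp, ts$series, "path_integrated", n = 80,
                      percentile = 99, seed = 3)
  expect_lte(jn95$threshold, jn99$threshold)
})

test_that("classification: silent cell is degenerate 'none'", {
  ts <- track_session()
  cls <- classify_cell(numeric(0), ts$series,
                       list(path_integrated = 0.2, travelled = 0.2,
                            time = 0.2))
  expect_equal(cls$label, "none")
  expect_true(cls$degenerate)
})

test_that("classification flags match the generative model", {
  ts <- track_session()
  thr <- list(path_integrated = 0.4, travelled = 0.4, time = 0.4)
  sp_pi <- generate_track_spikes(ts$traj,
                                 ground_truth("path_integrated", spacing = 150),
                                 seed = 56)
  cls <- classify_cell(sp_pi, ts$series, thr, n_alloc_perm = 200, seed = 1)
  expect_true(cls$flag_path_integrated)
  expect_equal(cls$label, "path_integrated")
  sp_tm <- generate_track_spikes(ts$traj,
                                 ground_truth("time", spacing = 15,
                                              field_width = 1.5), seed = 57)
  cls2 <- classify_cell(sp_tm, ts$series, thr, n_alloc_perm = 200, seed = 1)
  expect_true(cls2$flag_time)
  expect_false(cls2$flag_path_integrated)
})

test_that("toeplitz rendering repeats the autocorrelation on diagonals", {
  x <- (seq_len(120) - 0.5) * 10
  prof <- make_profile(5 * exp(-((x %% 100) - 50)^2 / 200))
  ac <- autocorrelation_1d(prof)
  tp <- toeplitz_rendering(ac, extent = 500)
  expect_equal(dim(tp), c(51, 51))
  expect_equal(tp[1, ], tp[, 1])
  expect_true(all(diag(tp) == 1))
})
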