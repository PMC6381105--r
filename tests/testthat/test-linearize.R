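C75 <- track_circumference(75)

test_that("one clockwise lap on the reference circle accumulates 471.24 cm", {
  tr <- circle_trajectory(radius = 75, speed = 471.2389 / 60, duration = 60)
  ser <- unwrap_cumulative_angle(tr)
  expect_equal(max(ser$signed), C75, tolerance = 0.5)
  expect_equal(C75, 471.2389, tolerance = 1e-4)
  # counter-clockwise lap accumulates -C
  tr2 <- circle_trajectory(radius = 75, speed = 471.2389 / 60, duration = 60,
                           clockwise = FALSE)
  ser2 <- unwrap_cumulative_angle(tr2)
  expect_equal(min(ser2$signed), -C75, tolerance = 0.5)
})

test_that("stationary trajectory gives all-zero distance series", {
  tr <- simulate_trajectory(duration = 20, mean_speed = 0, pause_rate = 0,
                            seed = 1)
  ser <- unwrap_cumulative_angle(tr)
  expect_true(all(abs(ser$signed) < 1e-9))
  expect_true(all(abs(ser$absolute) < 1e-9))
})

test_that("cumulative series equals the brute-force angle-difference sum", {
  ts <- track_session(seed = 7, duration = 60)
  tr <- ts$traj
  th <- atan2(tr$y1, tr$x1)
  sig <- 0; abs_d <- 0
  for (i in 2:nrow(tr)) {
    d <- th[i] - th[i - 1]
    d <- ((d + pi) %% (2 * pi)) - pi
    sig <- sig - 75 * d
    abs_d <- abs_d + abs(75 * d)
  }
  ser <- unwrap_cumulative_angle(tr)
  expect_equal(ser$signed[nrow(tr)], sig, tolerance = 1e-6)
  expect_equal(ser$absolute[nrow(tr)], abs_d, tolerance = 1e-6)
  # invariants
  expect_true(all(diff(ser$absolute) >= -1e-12))
  expect_true(all(abs(diff(ser$signed)) <= diff(ser$absolute) + 1e-12))
})

test_that("sample at the centre raises an angle error", {
  tr <- circle_trajectory(duration = 2)
  tr$x1[5] <- 0; tr$y1[5] <- 0
  expect_error(unwrap_cumulative_angle(tr), "centre")
})

test_that("lap segmentation follows floor(signed / C)", {
  # synthetic monotone series reaching 950 cm: laps 0,1,2 -> 3 segments
  ser <- tibble::tibble(t = seq(0, 99.9, by = 0.1),
                        signed = seq(0, 950, length.out = 1000))
  segs <- segment_laps(ser, C75)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$lap, c(0, 1, 2))
  # series never reaching C -> single lap
  ser2 <- tibble::tibble(t = 1:100, signed = seq(0, 300, length.out = 100))
  expect_equal(nrow(segment_laps(ser2, C75)), 1)
  # dipping below zero -> lap index -1
  ser3 <- tibble::tibble(t = 1:100, signed = seq(5, -10, length.out = 100))
  segs3 <- segment_laps(ser3, C75)
  expect_true(-1 %in% segs3$lap)
})

test_that("linearized activity conserves spikes and occupancy", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj, ground_truth("path_integrated"),
                              seed = 31)
  for (fr in c("path_integrated", "travelled", "time")) {
    prof <- linearize_activity(sp, ts$series, fr)
    expect_equal(sum(prof$count), length(sp))
    expect_equal(sum(prof$occupancy), traj_duration(ts$traj),
                 tolerance = 0.05)
    occ <- prof$occupancy > 0
    expect_equal(prof$rate[occ], prof$count[occ] / prof$occupancy[occ])
  }
})

test_that("default bins are 10 cm for distance frames and 1 s for time", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj, ground_truth("path_integrated"),
                              seed = 31)
  expect_equal(attr(linearize_activity(sp, ts$series, "travelled"), "bin"), 10)
  expect_equal(attr(linearize_activity(sp, ts$series, "time"), "bin"), 1)
})

test_that("empty spike train linearizes to all-zero counts", {
  ts <- track_session()
  prof <- linearize_activity(numeric(0), ts$series, "path_integrated")
  expect_true(all(prof$count == 0))
})

test_that("path-integrated profile of a generated cell recovers its spacing", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 33)
  ac <- autocorrelation_1d(linearize_activity(sp, ts$series, "path_integrated"))
  expect_equal(attr(ac, "first_peak_lag"), 150, tolerance = 10.1)
})

test_that("lap matrix: duplicated laps correlate exactly 1", {
  m <- matrix(rep(sin(seq(0, 2 * pi, length.out = 47)), 3), nrow = 3,
              byrow = TRUE)
  m <- structure(m, class = c("gt_lap_matrix", class(m)),
                 occupancy = matrix(1, 3, 47), lap_ids = 0:2, C = C75,
                 bin = C75 / 47, lap_direction = rep(1, 3))
  al <- allocentric_correlation(m)
  expect_equal(as.numeric(al$mean_r), 0.999999, tolerance = 1e-5)
  expect_true(all(al$pairs$r > 0.999999))
})

test_that("lap matrix has 47 bins tiling the circumference", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj, ground_truth("path_integrated"),
                              seed = 34)
  lm1 <- lap_position_matrix(sp, ts$series)
  expect_equal(ncol(lm1), 47)
  expect_equal(attr(lm1, "bin") * 47, C75, tolerance = 1e-9)
  expect_error(lap_position_matrix(sp, ts$series[1:100, ]), "lap")
})

test_that("directional split: direction-blind cells correlate, gated cells do not", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 35)
  ds <- directional_split(sp, ts$series)
  expect_gt(ds$r, 0.5)
  # fire only on clockwise runs
  cw_t <- ts$series$t[ts$series$direction == "CW"]
  sp_cw <- sp[vapply(sp, function(s) {
    any(abs(cw_t - s) < 0.02)
  }, logical(1))]
  ds2 <- tryCatch(directional_split(sp_cw, ts$series),
                  error = function(e) list(r = NA_real_))
  expect_true(is.na(ds2$r) || ds2$r <= 0.2)
})
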