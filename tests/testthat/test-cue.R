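test_that("visible arc: no inner wall means full visibility", {
  g <- track_geometry(radius_outer = 75, track_width = 74.999)
  va <- visible_arc(g)
  expect_equal(va$extent, 360, tolerance = 1)
})

test_that("analytic visible arc matches ray casting within 2 degrees", {
  for (geom in list(track_geometry(75, 15), track_geometry(50, 15))) {
    a <- visible_arc(geom, method = "analytic")$extent
    r <- visible_arc(geom, method = "raycast")$extent
    expect_lt(abs(a - r), 2)
  }
})

test_that("visible arc grows with card width and with inner-wall reduction", {
  e1 <- visible_arc(track_geometry(75, 15, card_width = 30))$extent
  e2 <- visible_arc(track_geometry(75, 15, card_width = 60))$extent
  expect_gte(e2, e1)
  e3 <- visible_arc(track_geometry(75, 30, card_width = 30))$extent
  expect_gte(e3, e1)  # lower inner wall radius -> more visibility
  expect_error(track_geometry(75, 15, card_width = 500), "wider")
})

test_that("region partition: equal extents, disjoint regions, buffer arithmetic", {
  g <- track_geometry(75, 15)
  p <- region_partition(g)
  expect_equal(p$visible$extent, p$non_visible$extent)
  expect_equal(p$buffer_extent, 360 - 2 * p$visible$extent)
  # regions never overlap: their centres are 180 deg apart, extents < 180
  expect_lt(p$visible$extent, 180)
  ang <- 0:359
  vis <- gridtrack:::in_region(ang, p$visible)
  non <- gridtrack:::in_region(ang, p$non_visible)
  expect_equal(sum(vis & non), 0)
  # a hypothetical 180-degree visible arc leaves no buffer
  p2 <- list(visible = list(center = 0, extent = 180),
             non_visible = list(center = 180, extent = 180))
  expect_equal(360 - 2 * p2$visible$extent, 0)
})

test_that("chi-square against 50:50: extremes and even split", {
  expect_equal(gridtrack:::chisq_5050(10, 0)$statistic, 10)
  expect_equal(gridtrack:::chisq_5050(7, 7)$statistic, 0)
  # all N fields in one region -> chi square = N
  for (n in c(4, 9, 16)) {
    expect_equal(gridtrack:::chisq_5050(n, 0)$statistic, n)
  }
})

test_that("field density by region counts field centroids and tests 50:50", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 95)
  g <- track_geometry(75, 15)
  p <- region_partition(g)
  fd <- field_density_by_region(sp, ts$series, p)
  expect_true(fd$n_visible + fd$n_non_visible + fd$n_buffer >= 1)
  expect_true(is.finite(fd$chi_square) || fd$n_visible + fd$n_non_visible == 0)
  expect_error(field_density_by_region(numeric(0), ts$series, p), "field")
})

test_that("region stability distinguishes noisy from stable regions", {
  # constructed: stable periodic firing in the visible region, jittered
  # field positions in the non-visible region
  traj <- simulate_trajectory(duration = 900, turn_rate = 2, seed = 96)
  ser <- unwrap_cumulative_angle(traj)
  g <- track_geometry(75, 15, card_angle = gridtrack:::wrap_deg(
    atan2(traj$y1[1], traj$x1[1]) * 180 / pi))
  p <- region_partition(g)
  ang <- gridtrack:::sample_track_angle(traj)
  vis <- gridtrack:::in_region(ang, p$visible)
  base <- gridtrack:::comb_rate(ser$signed, 50, 150, 15, 8, 0.05)
  noisy <- gridtrack:::comb_rate(ser$signed + 40 * sin(ser$t / 40), 50, 150,
                                 15, 8, 0.05)
  rate <- ifelse(vis, base, noisy)
  sp <- sample_inhomogeneous_spikes(traj$t, rate, seed = 97)
  rs <- region_stability(sp, ser, traj, p)
  rv <- rs$first_peak_r[rs$region == "visible"]
  rn <- rs$first_peak_r[rs$region == "non_visible"]
  expect_true(is.finite(rv))
  expect_true(!is.finite(rn) || rv > rn)
})

test_that("light-dark comparison: identical sessions correlate 1, noise drops it", {
  traj <- simulate_trajectory(duration = 600, seed = 98)
  ser <- unwrap_cumulative_angle(traj)
  gt <- ground_truth("allocentric", field_positions = c(30, 160, 330))
  sp <- generate_track_spikes(traj, gt, seed = 99)
  prof <- linearize_activity(sp, ser, "path_integrated")
  same <- light_dark_comparison(prof, prof, prof)
  expect_equal(same$r_light_light, 1, tolerance = 1e-9)
  expect_equal(same$r_light_dark, 1, tolerance = 1e-9)
  # a decoupled "dark" session drops the light-dark correlation
  traj2 <- simulate_trajectory(duration = 600, seed = 198)
  ser2 <- unwrap_cumulative_angle(traj2)
  gt_dark <- ground_truth("allocentric", field_positions = c(95, 250, 420))
  sp_dark <- generate_track_spikes(traj2, gt_dark, seed = 199)
  prof_dark <- linearize_activity(sp_dark, ser2, "path_integrated")
  traj3 <- simulate_trajectory(duration = 600, seed = 298)
  ser3 <- unwrap_cumulative_angle(traj3)
  sp3 <- generate_track_spikes(traj3, gt, seed = 299)
  prof3 <- linearize_activity(sp3, ser3, "path_integrated")
  cmp <- light_dark_comparison(prof, prof_dark, prof3)
  expect_gt(cmp$r_light_light, cmp$r_light_dark)
})
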