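# Ideal hexagonal-lattice rate map on a square grid, built without a
# trajectory: the noise-free substrate for gridness and spacing checks.
ideal_lattice_map <- function(spacing = 50, orientation = 15, extent = 75,
                              bin = 2.5) {
  ctr <- seq(-extent + bin / 2, extent - bin / 2, by = bin)
  g <- expand.grid(x = ctr, y = ctr)
  rate <- lattice_rate(g$x, g$y, spacing, orientation, peak_rate = 10)
  m <- matrix(rate, length(ctr), length(ctr))
  inside <- outer(ctr, ctr, function(x, y) sqrt(x^2 + y^2) <= extent)
  m[!inside] <- NA
  structure(list(rate = m, occupancy = ifelse(inside, 1, 0), mask = inside,
                 x = ctr, y = ctr, bin = bin, h = 5,
                 peak_rate = max(m, na.rm = TRUE), duration = sum(inside)),
            class = "gt_ratemap")
}

radial_map <- function(extent = 75, bin = 2.5) {
  ctr <- seq(-extent + bin / 2, extent - bin / 2, by = bin)
  g <- expand.grid(x = ctr, y = ctr)
  r <- sqrt(g$x^2 + g$y^2)
  m <- matrix(10 * exp(-r / 30) * (1 + cos(2 * pi * r / 40)) / 2,
              length(ctr), length(ctr))
  structure(list(rate = m, occupancy = matrix(1, length(ctr), length(ctr)),
                 mask = matrix(TRUE, length(ctr), length(ctr)),
                 x = ctr, y = ctr, bin = bin, h = 5,
                 peak_rate = max(m), duration = length(m)),
            class = "gt_ratemap")
}

test_that("rate map: conservation, zero-spike and Poisson-rate oracles", {
  tr <- arena_session()
  m0 <- compute_rate_map(tr, numeric(0))
  expect_true(all(m0$rate[m0$mask] == 0))
  expect_equal(sum(m0$occupancy), traj_duration(tr), tolerance = 0.05)
  # homogeneous 5 Hz cell: spatial mean rate ~5 Hz
  sp <- sample_inhomogeneous_spikes(tr$t, rep(5, nrow(tr)), seed = 2)
  m5 <- compute_rate_map(tr, sp)
  expect_equal(mean(m5$rate[m5$mask], na.rm = TRUE), 5, tolerance = 0.5)
  expect_error(compute_rate_map(tr[0, ], numeric(0)), "trajectory")
  expect_error(compute_rate_map(tr, traj_duration(tr) + 5), "outside")
})

test_that("autocorrelogram: normalisation, symmetry and brute-force oracle", {
  m <- ideal_lattice_map()
  a <- spatial_autocorrelogram(m)
  nc <- (length(a$lag_x) + 1) / 2
  expect_equal(a$r[nc, nc], 1, tolerance = 1e-6)
  # symmetry under lag negation
  expect_equal(a$r, a$r[rev(seq_len(nrow(a$r))), rev(seq_len(ncol(a$r)))],
               tolerance = 1e-6)
  expect_true(all(a$r >= -1 - 1e-12 & a$r <= 1 + 1e-12, na.rm = TRUE))
  # literal Pearson oracle at a handful of lags
  brute <- function(R, dx, dy) {
    n <- nrow(R)
    x <- c(); y <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      i2 <- i - dx; j2 <- j - dy
      if (i2 >= 1 && i2 <= n && j2 >= 1 && j2 <= n &&
          is.finite(R[i, j]) && is.finite(R[i2, j2])) {
        x <- c(x, R[i, j]); y <- c(y, R[i2, j2])
      }
    }
    cor(x, y)
  }
  for (lag in list(c(3, 0), c(0, 7), c(5, -4))) {
    idx_r <- nc + lag[1]; idx_c <- nc + lag[2]
    expect_equal(a$r[idx_r, idx_c],
                 brute(m$rate, lag[1], lag[2]), tolerance = 1e-6)
  }
})

test_that("constant map has undefined autocorrelation", {
  m <- ideal_lattice_map()
  m$rate[] <- ifelse(is.finite(m$rate), 3, NA)
  expect_error(spatial_autocorrelogram(m), "constant")
})

test_that("gridness: ideal lattice scores >= 1, radial map scores ~0", {
  a <- spatial_autocorrelogram(ideal_lattice_map())
  g <- gridness(a)
  expect_true(g$valid)
  expect_gte(g$score, 1.0)
  a2 <- spatial_autocorrelogram(radial_map())
  g2 <- gridness(a2)
  expect_lt(abs(g2$score), 0.2)
})

test_that("gridness and field detection invariant under rate rescaling", {
  m <- ideal_lattice_map()
  m2 <- m
  m2$rate <- m2$rate * 3.7
  m2$peak_rate <- m2$peak_rate * 3.7
  g1 <- gridness(spatial_autocorrelogram(m))
  g2 <- gridness(spatial_autocorrelogram(m2))
  expect_equal(g1$score, g2$score, tolerance = 1e-9)
  f1 <- detect_fields(m); f2 <- detect_fields(m2)
  expect_equal(f1$n_pixels, f2$n_pixels)
  expect_equal(f1$x, f2$x, tolerance = 1e-9)
})

test_that("field spacing: ideal lattice recovered, scaling similarity", {
  a50 <- spatial_autocorrelogram(ideal_lattice_map(spacing = 50))
  expect_equal(field_spacing_2d(a50), 50, tolerance = 2.5)
  a65 <- spatial_autocorrelogram(ideal_lattice_map(spacing = 65))
  expect_equal(field_spacing_2d(a65), 65, tolerance = 2.5)
  # six inner peaks sit at the lattice distance
  pk <- gridness(a50)$peaks
  expect_equal(nrow(pk), 6)
  expect_true(all(abs(pk$dist - 50) < 5))
})

test_that("simulated 2D grid cells pass the grid classification", {
  tr <- arena_session()
  ok <- 0
  for (s in 1:5) {
    sp <- generate_grid_spikes_2d(tr, ground_truth("slice2d",
                                                   lattice_spacing = 50),
                                  seed = 40 + s)
    g <- gridness(spatial_autocorrelogram(compute_rate_map(tr, sp)))
    if (isTRUE(g$valid) && g$score > 0.32) ok <- ok + 1
  }
  expect_gte(ok, 4)  # >= 95% of seeds in the acceptance-scale batch
})

test_that("lattice spacing of simulated maps is recovered within one bin", {
  tr <- arena_session()
  sp <- generate_grid_spikes_2d(tr, ground_truth("slice2d",
                                                 lattice_spacing = 50),
                                seed = 46)
  a <- spatial_autocorrelogram(compute_rate_map(tr, sp))
  expect_equal(field_spacing_2d(a), 50, tolerance = 2.6)
})

test_that("detect_fields: bumps, minimum size and empty maps", {
  # 1D: two separated bumps at 2.5 cm pixels
  x <- seq(0, 200, by = 2.5)
  prof <- 10 * exp(-(x - 50)^2 / 50) + 8 * exp(-(x - 150)^2 / 50)
  f <- detect_fields(prof)
  expect_equal(nrow(f), 2)
  expect_equal(sort(x[round(f$coord)]), c(50, 150), tolerance = 3)
  # single bump -> one field
  f1 <- detect_fields(10 * exp(-(x - 100)^2 / 50))
  expect_equal(nrow(f1), 1)
  # supra-threshold blob of 3 pixels < 5 -> no field
  v <- rep(0, 40); v[10:12] <- 10
  expect_equal(nrow(detect_fields(v)), 0)
  # zero peak -> empty
  expect_equal(nrow(detect_fields(rep(0, 40))), 0)
})

test_that("detect_fields centroids use the stated coordinates", {
  x <- seq(0, 200, by = 2.5)
  prof <- structure(tibble::tibble(bin_mid = x, count = 0, occupancy = 1,
                                   rate = 10 * exp(-(x - 120)^2 / 60)),
                    class = c("gt_linear_profile", "tbl_df", "tbl", "data.frame"),
                    frame = "path_integrated", bin = 2.5)
  f <- detect_fields(prof)
  expect_equal(f$coord, 120, tolerance = 1)
})

test_that("spike-time rotation preserves count and wraps", {
  sp <- sort(runif(50, 0, 600))
  rot <- rotate_spike_times(sp, 100, 600)
  expect_length(rot, 50)
  expect_true(all(rot >= 0 & rot <= 600))
  expect_false(is.unsorted(rot))
})

test_that("phase offset: self gives 0, shifted profile gives the shift", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 47)
  p1 <- linearize_activity(sp, ts$series, "path_integrated")
  off0 <- pair_phase_offset(p1, p1)
  expect_equal(off0$offset, 0)
  p2 <- p1
  p2$bin_mid <- p2$bin_mid + 30   # same profile displaced by 30 cm
  off30 <- pair_phase_offset(p1, p2)
  expect_equal(abs(off30$offset), 30, tolerance = 10.1)
  # arena: a map against itself peaks at the origin
  m <- ideal_lattice_map()
  self2d <- pair_phase_offset(m, m)
  expect_equal(self2d$offset, 0, tolerance = 1e-9)
})
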