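test_that("predicted profile integrates to the spike count and translates exactly", {
  axis <- seq(5, 1500, by = 10)
  p <- train_model_params(20, 50, 150)
  dens <- predict_profile(p, axis, 500)
  expect_equal(sum(dens) * 10, 500, tolerance = 0.001 * 500)
  # translation of the offset translates the profile
  p2 <- train_model_params(20, 80, 150)
  dens2 <- predict_profile(p2, axis, 500)
  expect_equal(dens2[(3 + 1):length(axis)], dens[1:(length(axis) - 3)],
               tolerance = 1e-3)  # edge mass renormalisation only
  # spacing beyond the extent leaves a single Gaussian
  p3 <- train_model_params(20, 700, 5000)
  dens3 <- predict_profile(p3, axis, 100)
  expect_equal(sum(dens3 > 1e-6 * max(dens3)), sum(abs(axis - 700) < 150),
               tolerance = 5)
  expect_error(train_model_params(20, 0, -5), "spacing")
  expect_error(train_model_params(-1, 0, 100), "width")
})

test_that("SSD is non-negative, zero at truth and locally optimal", {
  axis <- seq(5, 1500, by = 10)
  p <- train_model_params(20, 50, 150)
  dens <- predict_profile(p, axis, 500, bin = 10)
  obs <- structure(tibble::tibble(axis = axis, density = dens,
                                  occupied = TRUE),
                   frame = "path_integrated", bin = 10, n_spikes = 500)
  expect_equal(fit_score(obs, p), 0, tolerance = 1e-10)
  for (fac in c(0.8, 1.2)) {
    pp <- train_model_params(20, 50, 150 * fac)
    expect_gt(fit_score(obs, pp), 0)
  }
})

test_that("differential evolution solves standard benchmarks deterministically", {
  de <- differential_evolution(function(p) sum(p^2), rep(-5, 3), rep(5, 3),
                               seed = 2)
  expect_lt(sqrt(sum(de$par^2)), 1e-3)
  de2 <- differential_evolution(function(p) sum(p^2), rep(-5, 3), rep(5, 3),
                                seed = 2)
  expect_identical(de$par, de2$par)
  expect_error(differential_evolution(function(p) 0, numeric(0), numeric(0)),
               "bounds")
  # Rastrigin: reach the global basin in most seeds
  rast <- function(p) sum(p^2 - 10 * cos(2 * pi * p) + 10)
  hits <- sum(vapply(1:10, function(s) {
    differential_evolution(rast, rep(-5.12, 3), rep(5.12, 3), seed = s,
                           generations = 150)$value < 1
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("noise-free parameter recovery across a spacing grid", {
  axis <- seq(5, 2000, by = 10)
  for (spc in c(80, 150, 250)) {
    p_true <- train_model_params(20, 50, spc)
    dens <- predict_profile(p_true, axis, 600, bin = 10)
    obs <- structure(tibble::tibble(axis = axis, density = dens,
                                    occupied = TRUE),
                     frame = "path_integrated", bin = 10, n_spikes = 600)
    f <- fit_cell(NULL, NULL, "path_integrated", seed = 4, obs = obs,
                  generations = 150)
    expect_equal(f$params$spacing, spc, tolerance = 0.05 * spc)
    doff <- (f$params$first_offset - 50) %% f$params$spacing
    doff <- min(doff, f$params$spacing - doff)
    expect_lt(doff, 15)
  }
})

test_that("fit on spikes recovers spacing and prefers the true frame", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150,
                                           field_width = 20,
                                           first_offset = 50), seed = 21)
  f_pi <- fit_cell(sp, ts$series, "path_integrated", seed = 7)
  f_tm <- fit_cell(sp, ts$series, "time", seed = 7)
  expect_equal(f_pi$params$spacing, 150, tolerance = 15)
  expect_lt(f_pi$ssd, f_tm$ssd)
})

test_that("fitting score depends only on the linearized profile", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150),
                              seed = 22)
  obs <- observed_profile(sp, ts$series, "path_integrated")
  p <- train_model_params(20, 50, 150)
  s1 <- fit_score(obs, p)
  s2 <- fit_score(obs, p)
  expect_identical(s1, s2)
  expect_gte(s1, 0)
})

test_that("reconstructed map correlates with the observed map", {
  ts <- track_session()
  sp <- generate_track_spikes(ts$traj,
                              ground_truth("path_integrated", spacing = 150,
                                           field_width = 20), seed = 23)
  f <- fit_cell(sp, ts$series, "path_integrated", seed = 8,
                generations = 120)
  rec <- reconstruct_map(f, ts$traj, ts$series, sp)
  expect_gt(rec$r, 0.5)
  # zero-rate model flagged
  f0 <- f
  f0$params$first_offset <- 5e5
  f0$params$spacing <- 1e6   # no field anywhere near the session extent
  expect_error(reconstruct_map(f0, ts$traj, ts$series, sp), "zero-rate")
})

test_that("distance estimates from the two methods agree on synthetic cells", {
  d <- tibble::tibble(acorr = c(80, 120, 150, 200, 250),
                      fit = c(82, 118, 149, 207, 246))
  cmp <- compare_distance_methods(d)
  expect_gt(cmp$r, 0.9)
  ident <- compare_distance_methods(tibble::tibble(acorr = c(1, 2, 3),
                                                   fit = c(1, 2, 3)))
  expect_equal(ident$r, 1)
  expect_error(compare_distance_methods(tibble::tibble(acorr = 1, fit = 1)),
               "3 cells")
})
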