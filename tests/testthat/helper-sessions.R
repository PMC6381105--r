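# Shared synthetic fixtures, built once per test run and memoised so that
# several test files can reuse the same sessions.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

track_session <- function(seed = 3, duration = 600) {
  fixture(sprintf("track_%d_%d", seed, duration), function() {
    traj <- simulate_trajectory(duration = duration, seed = seed)
    list(traj = traj, series = unwrap_cumulative_angle(traj))
  })
}

arena_session <- function(seed = 5, duration = 300) {
  fixture(sprintf("arena_%d_%d", seed, duration), function() {
    simulate_trajectory("arena", duration = duration, seed = seed)
  })
}

# A trajectory moving on a perfect circle at constant speed (no noise);
# useful for exact-arithmetic checks. Positive direction = clockwise.
circle_trajectory <- function(radius = 75, speed = 10, duration = 60,
                              sample_rate = 50, clockwise = TRUE,
                              radius_outer = 75, track_width = 15) {
  tt <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  sgn <- if (clockwise) -1 else 1
  theta <- sgn * speed * tt / radius
  phi <- theta + sgn * pi / 2
  traj <- tibble::tibble(t = tt,
                         x1 = radius * cos(theta), y1 = radius * sin(theta),
                         x2 = radius * cos(theta) - 5 * cos(phi),
                         y2 = radius * sin(theta) - 5 * sin(phi))
  structure(traj, class = c("gt_trajectory", class(traj)),
            enclosure = "track", radius_outer = radius_outer,
            track_width = track_width, sample_rate = sample_rate)
}
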