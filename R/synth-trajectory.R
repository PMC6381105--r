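#' Simulate foraging behaviour in the circular arena or track
#'
#' Generates a two-marker head-tracking series emulating a rat foraging either
#' in a circular arena or on the 15 cm peripheral rim (the "track") of the
#' same enclosure. On the track the animal performs a 1D stochastic walk in
#' angle: running speed follows an Ornstein-Uhlenbeck process around
#' `mean_speed`, direction reversals arrive as a Poisson process at
#' `turn_rate` per minute, and a Poisson pause process (rate `pause_rate` Hz,
#' mean duration `pause_mean` s) reproduces the intermittent foraging that
#' makes the total distance covered in 10 min (~42 m, ~3 laps, ~98 turns)
#' smaller than `mean_speed * duration`. In the arena the heading diffuses
#' continuously and the walk reflects off the wall.
#'
#' The front marker `(x1, y1)` is the tracked head position; the second
#' marker sits 5 cm behind along the heading so that heading is defined as
#' `atan2(y1 - y2, x1 - x2)`.
#'
#' @param enclosure `"track"` or `"arena"`.
#' @param radius_outer Outer wall radius in cm (75 for the large apparatus,
#'   50 for the small).
#' @param track_width Track width in cm (track only).
#' @param duration Session duration in s.
#' @param sample_rate Tracking rate, samples/s.
#' @param mean_speed Mean running speed while moving, cm/s.
#' @param turn_rate Track: expected direction reversals per minute.
#'   Arena: heading diffusion coefficient (rad^2/s).
#' @param pause_rate Rate of pause onsets, Hz.
#' @param pause_mean Mean pause duration, s.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return A `gt_trajectory`: a tibble with columns `t, x1, y1, x2, y2` (cm)
#'   and attributes `enclosure`, `radius_outer`, `track_width`, `sample_rate`,
#'   `seed`, and (track) `n_reversals`.
#' @export
#' @examples
#' traj <- simulate_trajectory(duration = 60, seed = 1)
#' traj_travelled_distance(traj)
simulate_trajectory <- function(enclosure = c("track", "arena"),
                                radius_outer = 75,
                                track_width = 15,
                                duration = 600,
                                sample_rate = 50,
                                mean_speed = if (match.arg(enclosure) == "track") 9.7 else 14,
                                turn_rate = if (match.arg(enclosure) == "track") 9.8 else 1,
                                pause_rate = 0.13,
                                pause_mean = 3,
                                seed = 1L) {
  enclosure <- match.arg(enclosure)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  if (mean_speed < 0) stop("mean_speed must be >= 0")
  if (enclosure == "track" && track_width >= radius_outer) {
    stop("track_width must be smaller than radius_outer")
  }

  dt <- 1 / sample_rate
  n <- floor(duration * sample_rate)
  tt <- (seq_len(n) - 1L) * dt

  out <- with_seed(seed, {
    if (enclosure == "track") {
      simulate_track_walk(n, dt, radius_outer, track_width, mean_speed,
                          turn_rate, pause_rate, pause_mean)
    } else {
      simulate_arena_walk(n, dt, radius_outer, mean_speed, turn_rate,
                          pause_rate, pause_mean)
    }
  })

  traj <- tibble::tibble(
    t = tt,
    x1 = out$x, y1 = out$y,
    x2 = out$x - 5 * cos(out$phi),
    y2 = out$y - 5 * sin(out$phi)
  )
  structure(traj,
            class = c("gt_trajectory", class(traj)),
            enclosure = enclosure,
            radius_outer = radius_outer,
            track_width = if (enclosure == "track") track_width else NA_real_,
            sample_rate = sample_rate,
            seed = as.integer(seed),
            n_reversals = out$n_reversals)
}

## OU-speed 1D angular walk on the track annulus.
simulate_track_walk <- function(n, dt, r_out, width, mu_s, turn_per_min,
                                pause_rate, pause_mean) {
  r_in <- r_out - width
  r_mid <- r_out - width / 2
  tau_s <- 2            # OU time constant (s) of running speed
  sd_s <- 3             # stationary sd of running speed (cm/s)
  tau_w <- 2            # OU time constant of radial drift velocity
  sd_w <- 1             # sd of radial drift velocity (cm/s)

  theta <- numeric(n); rr <- numeric(n); phi <- numeric(n)
  theta[1] <- runif(1, 0, 2 * pi)
  rr[1] <- r_mid
  s <- mu_s
  d <- sample(c(-1, 1), 1)          # +1 = clockwise (theta decreasing)
  pause_left <- 0
  n_rev <- 0L
  p_turn <- (turn_per_min / 60) * dt
  p_pause <- pause_rate * dt
  a_s <- exp(-dt / tau_s); b_s <- sd_s * sqrt(1 - a_s^2)
  a_w <- exp(-dt / tau_w); b_w <- sd_w * sqrt(1 - a_w^2)

  eps_s <- rnorm(n); eps_w <- rnorm(n)
  u_turn <- runif(n); u_pause <- runif(n)
  pause_dur <- -pause_mean * log(runif(n))   # exponential draws, used lazily

  w <- 0                # radial drift velocity (cm/s)
  phi[1] <- theta[1] - d * pi / 2
  for (i in 2:n) {
    if (pause_left > 0) {
      pause_left <- pause_left - dt
      v <- 0
    } else {
      if (u_pause[i] < p_pause) pause_left <- pause_dur[i]
      s <- mu_s + a_s * (s - mu_s) + b_s * eps_s[i]
      v <- if (mu_s > 0) max(s, 0) else 0
    }
    if (u_turn[i] < p_turn) {
      d <- -d
      n_rev <- n_rev + 1L
    }
    if (v > 0) {
      w <- a_w * w - (rr[i - 1] - r_mid) * dt / tau_w + b_w * eps_w[i]
    } else {
      w <- 0
    }
    rr[i] <- min(max(rr[i - 1] + w * dt, r_in + 1.5), r_out - 1.5)
    theta[i] <- theta[i - 1] - d * v * dt / rr[i]
    phi[i] <- theta[i] - d * pi / 2
  }
  list(x = rr * cos(theta), y = rr * sin(theta), phi = phi,
       n_reversals = n_rev)
}

## Heading-diffusion walk in the open arena with wall reflection.
simulate_arena_walk <- function(n, dt, r_out, mu_s, diff_coef,
                                pause_rate, pause_mean) {
  r_max <- r_out - 2
  tau_s <- 2; sd_s <- 4
  a_s <- exp(-dt / tau_s); b_s <- sd_s * sqrt(1 - a_s^2)
  sd_phi <- sqrt(2 * diff_coef * dt)

  x <- numeric(n); y <- numeric(n); phi <- numeric(n)
  rstart <- r_max * sqrt(runif(1)); astart <- runif(1, 0, 2 * pi)
  x[1] <- rstart * cos(astart); y[1] <- rstart * sin(astart)
  phi[1] <- runif(1, 0, 2 * pi)
  s <- mu_s
  pause_left <- 0
  p_pause <- pause_rate * dt
  eps_s <- rnorm(n); eps_p <- rnorm(n); u_pause <- runif(n)
  pause_dur <- -pause_mean * log(runif(n))

  for (i in 2:n) {
    if (pause_left > 0) {
      pause_left <- pause_left - dt
      v <- 0
    } else {
      if (u_pause[i] < p_pause) pause_left <- pause_dur[i]
      s <- mu_s + a_s * (s - mu_s) + b_s * eps_s[i]
      v <- if (mu_s > 0) max(s, 0) else 0
    }
    phi[i] <- phi[i - 1] + sd_phi * eps_p[i]
    xn <- x[i - 1] + v * dt * cos(phi[i])
    yn <- y[i - 1] + v * dt * sin(phi[i])
    if (xn^2 + yn^2 > r_max^2) {
      # turn toward the centre instead of crossing the wall
      phi[i] <- atan2(-y[i - 1], -x[i - 1]) + rnorm(1, 0, 0.3)
      xn <- x[i - 1] + v * dt * cos(phi[i])
      yn <- y[i - 1] + v * dt * sin(phi[i])
    }
    x[i] <- xn; y[i] <- yn
  }
  list(x = x, y = y, phi = phi, n_reversals = NA_integer_)
}

#' @export
print.gt_trajectory <- function(x, ...) {
  cat(sprintf("<gt_trajectory> %s, %.0f s at %g Hz, outer radius %g cm\n",
              attr(x, "enclosure"), traj_duration(x), attr(x, "sample_rate"),
              attr(x, "radius_outer")))
  NextMethod()
}

#' Trajectory accessors
#'
#' Convenience extractors for `gt_trajectory` objects: session duration (s),
#' sampling rate (Hz), instantaneous running speed (cm/s, from position
#' differences, optionally smoothed), heading (radians, from the two
#' markers), and total travelled path length (cm, sum of per-sample Euclidean
#' displacements of the tracked marker).
#'
#' @param traj A `gt_trajectory` (or any tibble with `t, x1, y1, x2, y2`).
#' @param smooth_s Smoothing window for the speed series, s (0 = none).
#' @return Scalar or per-sample numeric vector.
#' @export
traj_duration <- function(traj) {
  dt <- traj$t[2] - traj$t[1]
  nrow(traj) * dt
}

#' @rdname traj_duration
#' @export
traj_sample_rate <- function(traj) {
  sr <- attr(traj, "sample_rate")
  if (is.null(sr)) sr <- 1 / (traj$t[2] - traj$t[1])
  sr
}

#' @rdname traj_duration
#' @export
traj_speed <- function(traj, smooth_s = 0.5) {
  dt <- traj$t[2] - traj$t[1]
  d <- sqrt(diff(traj$x1)^2 + diff(traj$y1)^2)
  v <- c(d[1], d) / dt
  if (smooth_s > 0) v <- roll_mean(v, max(1L, round(smooth_s / dt)))
  v
}

#' @rdname traj_duration
#' @export
traj_heading <- function(traj) {
  if (!all(c("x2", "y2") %in% names(traj))) {
    stop("trajectory has no second marker; heading undefined")
  }
  atan2(traj$y1 - traj$y2, traj$x1 - traj$x2)
}

#' @rdname traj_duration
#' @export
traj_travelled_distance <- function(traj) {
  sum(sqrt(diff(traj$x1)^2 + diff(traj$y1)^2))
}
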