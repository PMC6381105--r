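#' Ground-truth description of a synthetic cell
#'
#' Collects the generative parameters of a synthetic unit so that downstream
#' classification and parameter-recovery tests can be scored against the
#' truth. `field_width` is the Gaussian standard deviation of a firing field
#' (cm, or s for the time model).
#'
#' @param coding_model One of `"allocentric"`, `"path_integrated"`,
#'   `"travelled"`, `"time"`, `"slice2d"`, `"none"`.
#' @param field_width Gaussian field sd (cm or s).
#' @param first_offset Coordinate of the first field (cm or s).
#' @param spacing Distance (or time) between fields; must be positive.
#' @param peak_rate Peak firing rate, Hz.
#' @param baseline_rate Out-of-field rate, Hz.
#' @param lattice_spacing,orientation,phase 2D lattice parameters (cm, deg,
#'   cm 2-vector) used by `"slice2d"` and by [generate_grid_spikes_2d()].
#' @param field_positions Optional explicit field centres for the
#'   allocentric model (cm along the track circle); allocentric grid
#'   fields on the track typically have irregular spacing, which this
#'   represents. `NULL` places fields regularly at
#'   `first_offset + k * spacing`.
#' @return A `gt_ground_truth` list.
#' @export
ground_truth <- function(coding_model = c("path_integrated", "allocentric",
                                          "travelled", "time", "slice2d", "none"),
                         field_width = 15,
                         first_offset = 50,
                         spacing = 150,
                         peak_rate = 8,
                         baseline_rate = 0.05,
                         lattice_spacing = 50,
                         orientation = 15,
                         phase = c(0, 0),
                         field_positions = NULL) {
  coding_model <- match.arg(coding_model)
  if (spacing <= 0) stop("spacing must be > 0")
  if (peak_rate < 0) stop("peak_rate must be >= 0")
  if (field_width <= 0) stop("field_width must be > 0")
  structure(list(coding_model = coding_model, field_width = field_width,
                 first_offset = first_offset, spacing = spacing,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 lattice_spacing = lattice_spacing, orientation = orientation,
                 phase = phase, field_positions = field_positions),
            class = "gt_ground_truth")
}

#' Directional or speed tuning of a synthetic cell
#'
#' @param kind `"head_direction"` or `"speed"`.
#' @param pfd Preferred firing direction, deg (head-direction cells).
#' @param concentration von Mises concentration `kappa >= 0`.
#' @param baseline_rate Additive baseline rate, Hz.
#' @param peak_rate Rate at the preferred direction, Hz.
#' @param slope,intercept Linear speed tuning, Hz per cm/s and Hz.
#' @return A `gt_tuning_spec` list.
#' @export
tuning_spec <- function(kind = c("head_direction", "speed"),
                        pfd = 90, concentration = 4,
                        baseline_rate = 0, peak_rate = 15,
                        slope = 0.5, intercept = 1) {
  kind <- match.arg(kind)
  if (concentration < 0) stop("concentration must be >= 0")
  structure(list(kind = kind, pfd = pfd, concentration = concentration,
                 baseline_rate = baseline_rate, peak_rate = peak_rate,
                 slope = slope, intercept = intercept),
            class = "gt_tuning_spec")
}

#' Firing rate of an ideal hexagonal lattice at arbitrary positions
#'
#' Sum of circular Gaussian bumps centred on the nodes of a triangular
#' lattice with the given spacing, orientation and spatial phase. Used both
#' to generate 2D grid-cell spikes and to build the "fake track" surrogate of
#' the spectral slice test.
#'
#' @param x,y Positions, cm.
#' @param spacing Lattice constant, cm.
#' @param orientation Lattice orientation, deg.
#' @param phase Spatial phase offset, cm 2-vector.
#' @param field_sd Field Gaussian sd, cm (default `0.16 * spacing`).
#' @param peak_rate Rate at a node, Hz.
#' @return Numeric vector of rates, Hz.
#' @export
lattice_rate <- function(x, y, spacing, orientation = 15, phase = c(0, 0),
                         field_sd = 0.16 * spacing, peak_rate = 8) {
  o <- orientation * pi / 180
  b1 <- spacing * c(cos(o), sin(o))
  b2 <- spacing * c(cos(o + pi / 3), sin(o + pi / 3))
  B <- cbind(b1, b2)
  Binv <- solve(B)
  qx <- x - phase[1]; qy <- y - phase[2]
  nc <- Binv %*% rbind(qx, qy)      # lattice coordinates
  n1 <- round(nc[1, ]); n2 <- round(nc[2, ])
  d2min <- rep(Inf, length(x))
  for (i in -1:1) for (j in -1:1) {
    cxy <- B %*% rbind(n1 + i, n2 + j)
    d2 <- (qx - cxy[1, ])^2 + (qy - cxy[2, ])^2
    d2min <- pmin(d2min, d2)
  }
  peak_rate * exp(-d2min / (2 * field_sd^2))
}

#' Inhomogeneous-Poisson spike sampling by thinning
#'
#' Draws spike times from a piecewise-constant rate sampled at the
#' tracking rate: homogeneous-Poisson candidates at the maximal rate are
#' accepted with probability `rate/rate_max`. Exact for bounded rates and
#' deterministic per seed; `rate[i]` applies on `[t[i], t[i] + dt)`.
#'
#' @param t Regular time grid, s.
#' @param rate Rate per sample, Hz.
#' @param seed Integer seed.
#' @return Sorted spike times, s.
#' @export
sample_inhomogeneous_spikes <- function(t, rate, seed) {
  stopifnot(length(t) == length(rate))
  dt <- t[2] - t[1]
  dur <- length(t) * dt
  rmax <- max(rate, 0)
  if (!is.finite(rmax) || rmax <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1, rmax * dur)
    if (n_cand == 0) return(numeric(0))
    cand <- sort(runif(n_cand, 0, dur))
    idx <- pmin(floor(cand / dt) + 1L, length(t))
    keep <- runif(n_cand) < rate[idx] / rmax
    cand[keep]
  })
}

## Periodic-comb Gaussian rate along a 1D coordinate: fields at
## first_offset + k * spacing for all integers k.
comb_rate <- function(u, offset, spacing, sd, peak, baseline) {
  d <- (u - offset) %% spacing
  dmin <- pmin(d, spacing - d)
  baseline + peak * exp(-dmin^2 / (2 * sd^2))
}

#' Generate spikes of a synthetic unit on the circular track
#'
#' Inhomogeneous-Poisson spikes whose rate follows a periodic Gaussian-bump
#' profile in one of five coordinates: track angle (`allocentric`; fields
#' anchored at fixed positions on the circle), signed cumulative angular
#' distance (`path_integrated`), absolute cumulative angular distance
#' (`travelled`), elapsed time (`time`), or the 2D lattice rate sampled along
#' the actual path (`slice2d`).
#'
#' @param traj A track `gt_trajectory`.
#' @param gt A [ground_truth()] object.
#' @param seed Integer seed.
#' @param r_ref Reference radius for the distance coordinate (defaults to the
#'   trajectory's outer radius).
#' @return A numeric vector of spike times (s), with the ground truth stored
#'   in the `"ground_truth"` attribute.
#' @export
generate_track_spikes <- function(traj, gt, seed = 1L,
                                  r_ref = attr(traj, "radius_outer")) {
  stopifnot(inherits(gt, "gt_ground_truth"))
  model <- gt$coding_model
  if (model == "none") {
    rate <- rep(gt$baseline_rate + gt$peak_rate * 0.2, nrow(traj))
  } else if (model == "slice2d") {
    rate <- gt$baseline_rate +
      lattice_rate(traj$x1, traj$y1, gt$lattice_spacing, gt$orientation,
                   gt$phase, field_sd = 0.16 * gt$lattice_spacing,
                   peak_rate = gt$peak_rate)
  } else {
    series <- unwrap_cumulative_angle(traj, r_ref = r_ref)
    u <- switch(model,
      allocentric = series$signed %% track_circumference(r_ref),
      path_integrated = series$signed,
      travelled = series$absolute,
      time = traj$t,
      stop("unknown coding model: ", model)
    )
    if (model == "allocentric") {
      C <- track_circumference(r_ref)
      centers <- if (!is.null(gt$field_positions)) gt$field_positions
                 else seq(gt$first_offset, C - 1e-9, by = gt$spacing)
      rate <- rep(gt$baseline_rate, length(u))
      for (ci in centers) {
        d <- abs(u - ci); d <- pmin(d, C - d)
        rate <- rate + gt$peak_rate * exp(-d^2 / (2 * gt$field_width^2))
      }
    } else {
      rate <- comb_rate(u, gt$first_offset, gt$spacing, gt$field_width,
                        gt$peak_rate, gt$baseline_rate)
    }
  }
  spikes <- sample_inhomogeneous_spikes(traj$t, rate, seed)
  attr(spikes, "ground_truth") <- gt
  spikes
}

#' Generate spikes of a synthetic 2D grid cell in the arena
#'
#' @inheritParams generate_track_spikes
#' @return Spike times (s) with the ground truth attached.
#' @export
generate_grid_spikes_2d <- function(traj, gt, seed = 1L) {
  stopifnot(inherits(gt, "gt_ground_truth"))
  if (identical(attr(traj, "enclosure"), "track")) {
    warning("2D lattice generator applied to a track trajectory; ",
            "rate is sampled only on the annulus")
  }
  rate <- gt$baseline_rate +
    lattice_rate(traj$x1, traj$y1, gt$lattice_spacing, gt$orientation,
                 gt$phase, field_sd = 0.16 * gt$lattice_spacing,
                 peak_rate = gt$peak_rate)
  if (gt$peak_rate == 0 && gt$baseline_rate == 0) rate <- rate * 0
  spikes <- sample_inhomogeneous_spikes(traj$t, rate, seed)
  attr(spikes, "ground_truth") <- gt
  spikes
}

#' Generate spikes of a head-direction- or speed-tuned synthetic cell
#'
#' Head-direction cells fire with a von Mises tuning
#' `rate = baseline + peak * exp(kappa * (cos(theta - pfd) - 1))`; speed
#' cells fire at `intercept + slope * speed`, clipped at zero.
#'
#' @param traj A `gt_trajectory`; head-direction tuning requires the second
#'   marker.
#' @param spec A [tuning_spec()].
#' @param seed Integer seed.
#' @return Spike times (s).
#' @export
generate_tuned_spikes <- function(traj, spec, seed = 1L) {
  stopifnot(inherits(spec, "gt_tuning_spec"))
  if (spec$kind == "head_direction") {
    if (!all(c("x2", "y2") %in% names(traj))) {
      stop("head-direction tuning requires a two-marker trajectory")
    }
    theta <- traj_heading(traj)
    rate <- spec$baseline_rate +
      spec$peak_rate * exp(spec$concentration *
                             (cos(theta - spec$pfd * pi / 180) - 1))
  } else {
    v <- traj_speed(traj)
    rate <- pmax(spec$intercept + spec$slope * v, 0)
  }
  spikes <- sample_inhomogeneous_spikes(traj$t, rate, seed)
  attr(spikes, "tuning_spec") <- spec
  spikes
}
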