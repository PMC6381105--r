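## Speed tuning, head-direction tuning, LFP theta and intrinsic spike-train
## theta rhythmicity.

#' Speed tuning of a cell
#'
#' Instantaneous firing rate (spike counts per tracking sample, smoothed
#' over `smooth_s`) is related to running speed: rates are averaged in
#' 2 cm/s speed bins (bins with under 1 s of occupancy excluded) and the
#' Pearson correlation, regression slope and intercept across bins are
#' returned.
#'
#' @param spikes Spike times, s.
#' @param traj A `gt_trajectory` (session of at least 60 s).
#' @param bin_speed Speed bin width, cm/s.
#' @param smooth_s Smoothing window for rate and speed series, s.
#' @param min_occupancy_s Minimum occupancy per speed bin, s.
#' @return A `gt_speed_tuning` list: `curve` (tibble `speed`, `rate`,
#'   `occupancy`), `r`, `z`, `slope`, `intercept`, `n_bins`.
#' @export
speed_tuning <- function(spikes, traj, bin_speed = 2, smooth_s = 0.5,
                         min_occupancy_s = 1) {
  if (traj_duration(traj) < 60) stop("session shorter than 60 s")
  dt <- traj$t[2] - traj$t[1]
  v <- traj_speed(traj, smooth_s = smooth_s)
  cnt <- as.numeric(tabulate(pmin(floor(spikes / dt) + 1L, nrow(traj)),
                             nbins = nrow(traj)))
  rate <- roll_mean(cnt / dt, max(1L, round(smooth_s / dt)))
  edges <- seq(0, max(v) + bin_speed, by = bin_speed)
  idx <- findInterval(v, edges)
  occ <- tapply(rep(dt, length(v)), idx, sum)
  mean_rate <- tapply(rate, idx, mean)
  keep <- occ >= min_occupancy_s
  curve <- tibble::tibble(
    speed = edges[as.integer(names(occ))[keep]] + bin_speed / 2,
    rate = as.numeric(mean_rate[keep]),
    occupancy = as.numeric(occ[keep]))
  if (nrow(curve) < 3 || stats::sd(curve$speed) < 1e-12) {
    stop("speed range too narrow: correlation undefined")
  }
  r <- cor(curve$speed, curve$rate)
  fitl <- lm(rate ~ speed, data = curve)
  structure(list(curve = curve, r = r, z = fisher_z(r),
                 slope = unname(coef(fitl)[2]),
                 intercept = unname(coef(fitl)[1]),
                 n_bins = nrow(curve)),
            class = "gt_speed_tuning")
}

#' Head-direction tuning of a cell
#'
#' Directional tuning curve in 6 degree bins: spikes fired while the head
#' faced each direction divided by the time spent facing it. Returns the
#' Rayleigh mean vector length of the tuning curve (0 untuned, 1 perfectly
#' tuned) and the preferred firing direction (angle of the bin with the
#' highest rate).
#'
#' @param spikes Spike times, s.
#' @param traj A two-marker `gt_trajectory`.
#' @param bin_deg Direction bin width, deg.
#' @return A `gt_hd_tuning` list: `curve` (tibble `direction`, `rate`,
#'   `occupancy`), `vector_length`, `pfd`, `peak_rate`, `mean_rate`.
#' @export
hd_tuning <- function(spikes, traj, bin_deg = 6) {
  theta <- wrap_deg(traj_heading(traj) * 180 / pi)
  dt <- traj$t[2] - traj$t[1]
  nb <- round(360 / bin_deg)
  idx <- pmin(floor(theta / bin_deg) + 1L, nb)
  occ <- as.numeric(tabulate(idx, nbins = nb)) * dt
  if (all(occ == 0)) stop("no directional occupancy")
  sp_th <- approx(traj$t, theta, xout = spikes, rule = 2)$y
  ## headings wrap; interpolate on unwrapped angle to avoid 0/360 artefacts
  unw <- (cumsum(c(theta[1] * pi / 180, wrap_pi(diff(theta * pi / 180))))) * 180 / pi
  sp_th <- wrap_deg(approx(traj$t, unw, xout = spikes, rule = 2)$y)
  cnt <- as.numeric(tabulate(pmin(floor(sp_th / bin_deg) + 1L, nb), nbins = nb))
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  ctr <- (seq_len(nb) - 0.5) * bin_deg
  rv <- rayleigh_vector(ctr[occ > 0] * pi / 180, w = rate[occ > 0])
  pk <- which.max(rate)
  structure(list(curve = tibble::tibble(direction = ctr, rate = rate,
                                        occupancy = occ),
                 vector_length = rv$length,
                 pfd = ctr[pk],
                 peak_rate = rate[pk],
                 mean_rate = length(spikes) / traj_duration(traj)),
            class = "gt_hd_tuning")
}

#' Rotation-shuffle threshold for head-direction selectivity
#'
#' As [grid_shuffle_threshold()], with the Rayleigh vector length of the
#' directional tuning curve as the statistic and a 99th-percentile pooled
#' threshold.
#'
#' @param cells List of `list(traj = , spikes = )`.
#' @param n_per_cell Rotations per cell (400).
#' @param percentile Pooled percentile (99).
#' @param seed Integer seed.
#' @return A `gt_shuffle` list (see [grid_shuffle_threshold()]).
#' @export
hd_shuffle_threshold <- function(cells, n_per_cell = 400, percentile = 99,
                                 seed = 1L) {
  scores <- numeric(0)
  for (ci in seq_along(cells)) {
    traj <- cells[[ci]]$traj
    spikes <- cells[[ci]]$spikes
    dur <- traj_duration(traj)
    if (dur < 40) {
      warning("session shorter than 40 s; cell ", ci, " skipped")
      next
    }
    shifts <- with_seed(derive_seed(seed, ci),
                        runif(n_per_cell, 20, dur - 20))
    sc <- vapply(shifts, function(sh) {
      sp <- rotate_spike_times(spikes, sh, dur)
      tryCatch(hd_tuning(sp, traj)$vector_length, error = function(e) NA_real_)
    }, numeric(1))
    scores <- c(scores, sc)
  }
  structure(list(threshold = unname(quantile(scores, percentile / 100,
                                             na.rm = TRUE)),
                 scores = scores, percentile = percentile,
                 n_per_cell = n_per_cell, seed = as.integer(seed)),
            class = "gt_shuffle")
}

#' Stability of preferred firing directions across environments
#'
#' Per-cell circular difference of the PFD between two conditions and the
#' population-level V-test with hypothesised mean direction 0 (stable
#' cells).
#'
#' @param pfd_a,pfd_b Preferred directions, deg, paired across cells.
#' @return A list: `differences` (deg, in (-180, 180]), `v_test` (tibble
#'   from [v_test()]), `mean_difference`.
#' @export
pfd_stability <- function(pfd_a, pfd_b) {
  ok <- is.finite(pfd_a) & is.finite(pfd_b)
  if (sum(ok) < 3) stop("need at least 3 paired cells")
  d <- circ_diff_deg(pfd_a[ok], pfd_b[ok])
  list(differences = d, v_test = v_test(d, 0),
       mean_difference = rayleigh_vector(d * pi / 180)$mean_angle * 180 / pi)
}

## Zero-phase Butterworth band-pass.
bandpass <- function(x, fs, f_lo = 4, f_hi = 12, order = 4) {
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' LFP theta-band analysis
#'
#' Band-passes the LFP between 4 and 12 Hz, takes the analytic-signal
#' instantaneous frequency, downsamples it to the position sampling rate,
#' and reports the theta peak frequency (the occupancy-weighted mode of the
#' instantaneous-frequency histogram in 0.05 Hz bins) and the regression
#' slope of frequency on running speed.
#'
#' @param lfp A `gt_lfp` (tibble `t`, `v` with `sample_rate` attribute).
#' @param traj The matching trajectory (for speed); optional.
#' @param f_lo,f_hi Band edges, Hz.
#' @param down_rate Downsampling target, Hz; defaults to the position rate.
#' @return A `gt_theta` list: `peak_frequency`, `freq` (tibble `t`,
#'   `frequency`, `speed`), `speed_slope`, `speed_r`.
#' @export
lfp_theta <- function(lfp, traj = NULL, f_lo = 4, f_hi = 12,
                      down_rate = NULL) {
  fs <- attr(lfp, "sample_rate")
  if (is.null(fs)) fs <- 1 / (lfp$t[2] - lfp$t[1])
  if (nrow(lfp) < 10 * fs) stop("LFP shorter than 10 s")
  if (stats::sd(lfp$v) < 1e-12) stop("flat LFP signal")
  xf <- bandpass(lfp$v, fs, f_lo, f_hi)
  z <- analytic_signal(xf)
  fi <- instantaneous_frequency(z, fs)
  if (is.null(down_rate)) {
    down_rate <- if (!is.null(traj)) traj_sample_rate(traj) else 25
  }
  step <- max(1L, round(fs / down_rate))
  sel <- seq(1L, length(fi), by = step)
  tt <- lfp$t[sel]; fd <- fi[sel]
  ## trim filter edges
  edge <- tt > 1 & tt < max(lfp$t) - 1
  tt <- tt[edge]; fd <- fd[edge]
  sp <- if (!is.null(traj)) approx(traj$t, traj_speed(traj), xout = tt,
                                   rule = 2)$y else rep(NA_real_, length(tt))
  inband <- fd >= f_lo & fd <= f_hi
  ## bin centres on multiples of 0.05 Hz so integer frequencies sit
  ## mid-bin, not on an edge
  h <- graphics::hist(fd[inband],
                      breaks = seq(f_lo - 0.025, f_hi + 0.025, by = 0.05),
                      plot = FALSE)
  pkf <- h$mids[which.max(h$counts)]
  slope <- NA_real_; rr <- NA_real_
  if (!is.null(traj)) {
    ok <- inband & is.finite(sp)
    if (sum(ok) > 10 && stats::sd(sp[ok]) > 1e-9) {
      fitl <- lm(fd[ok] ~ sp[ok])
      slope <- unname(coef(fitl)[2])
      rr <- cor(sp[ok], fd[ok])
    }
  }
  structure(list(peak_frequency = pkf,
                 freq = tibble::tibble(t = tt, frequency = fd, speed = sp),
                 speed_slope = slope, speed_r = rr),
            class = "gt_theta")
}

#' Spike-time autocorrelogram
#'
#' Counts of spike pairs per lag bin over a symmetric window (1 ms bins,
#' +/-500 ms by default); the zero-lag (self-pair) count is removed.
#'
#' @param spikes Spike times, s.
#' @param bin_s Lag bin, s.
#' @param window_s Half window, s.
#' @return A tibble `lag` (s), `count`.
#' @export
spike_autocorrelogram <- function(spikes, bin_s = 0.001, window_s = 0.5) {
  sp <- sort(spikes)
  n <- length(sp)
  edges <- seq(-window_s, window_s, by = bin_s)
  counts <- numeric(length(edges) - 1L)
  j0 <- 1L
  for (i in seq_len(n)) {
    while (j0 <= n && sp[j0] < sp[i] - window_s) j0 <- j0 + 1L
    j <- j0
    while (j <= n && sp[j] <= sp[i] + window_s) {
      if (j != i) {
        d <- sp[j] - sp[i]
        k <- floor((d + window_s) / bin_s) + 1L
        if (k >= 1 && k <= length(counts)) counts[k] <- counts[k] + 1
      }
      j <- j + 1L
    }
  }
  tibble::tibble(lag = (edges[-1] + edges[-length(edges)]) / 2,
                 count = counts)
}

#' Intrinsic theta frequency of a spike train
#'
#' The spike-time autocorrelogram (1 ms bins, +/-500 ms) is band-passed in
#' the theta band and the theta frequency is the amplitude-weighted mean
#' of the analytic-signal instantaneous frequency (filter edges trimmed).
#' Significance of the rhythm is assessed with a theta index, the ratio of
#' band-passed oscillation power to the broadband power of the
#' autocorrelogram around it; trains with `theta_index` below
#' `min_theta_index` are flagged as not theta-modulated (frequency `NA`).
#'
#' @param spikes Spike times, s (at least 100).
#' @param f_lo,f_hi Theta band, Hz.
#' @param bin_s,window_s Autocorrelogram resolution (see
#'   [spike_autocorrelogram()]).
#' @param min_theta_index Detection threshold on the theta index.
#' @return A `gt_theta_intrinsic` list: `frequency` (Hz or `NA`),
#'   `theta_index`, `modulated`, `acorr` (the autocorrelogram tibble).
#' @export
intrinsic_theta <- function(spikes, f_lo = 4, f_hi = 12,
                            bin_s = 0.001, window_s = 0.5,
                            min_theta_index = 0.05) {
  if (length(spikes) < 100) stop("intrinsic theta requires >= 100 spikes")
  ac <- spike_autocorrelogram(spikes, bin_s, window_s)
  fs <- 1 / bin_s
  v <- ac$count
  ## remove the slow envelope: subtract a heavily smoothed version
  env <- gauss_smooth(v, round(0.25 / bin_s))
  x <- v - env
  xf <- bandpass(x, fs, f_lo, f_hi)
  z <- analytic_signal(xf)
  amp <- Mod(z)
  fi <- instantaneous_frequency(z, fs)
  trim_n <- round(0.1 / bin_s)   # drop filter edge transients
  trim <- seq_along(fi) > trim_n & seq_along(fi) < length(fi) - trim_n
  inband <- fi >= f_lo & fi <= f_hi & trim
  theta_index <- stats::var(xf) / max(stats::var(x), 1e-12)
  modulated <- is.finite(theta_index) && theta_index >= min_theta_index &&
    any(inband)
  freqv <- NA_real_
  if (modulated) {
    freqv <- sum(fi[inband] * amp[inband]) / sum(amp[inband])
  }
  structure(list(frequency = freqv, theta_index = theta_index,
                 modulated = modulated, acorr = ac),
            class = "gt_theta_intrinsic")
}
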