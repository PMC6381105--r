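#' Generate a synthetic theta-band LFP trace
#'
#' A frequency-modulated sinusoid whose instantaneous frequency is
#' `f0 + speed_slope * speed(t)` (speed taken from the trajectory and
#' interpolated to the LFP rate), plus white Gaussian noise. Sampled at
#' 1024 Hz as in the recording setup.
#'
#' @param traj A `gt_trajectory` supplying the speed series.
#' @param f0 Carrier frequency, Hz; a warning is raised outside the theta
#'   band (4-12 Hz).
#' @param speed_slope Frequency modulation, Hz per cm/s.
#' @param amplitude Oscillation amplitude (arbitrary units).
#' @param noise_sd White-noise sd (same units).
#' @param seed Integer seed.
#' @param sample_rate LFP sampling rate, Hz.
#' @return A `gt_lfp` tibble with columns `t`, `v` and attribute
#'   `sample_rate`; length is `duration * sample_rate` samples.
#' @export
generate_lfp <- function(traj, f0 = 8, speed_slope = 0, amplitude = 1,
                         noise_sd = 0.1, seed = 1L, sample_rate = 1024) {
  if (f0 < 4 || f0 > 12) {
    warning("f0 = ", f0, " Hz is outside the theta band (4-12 Hz)")
  }
  dur <- traj_duration(traj)
  n <- floor(dur * sample_rate)
  tl <- (seq_len(n) - 1L) / sample_rate
  v_traj <- traj_speed(traj, smooth_s = 0.5)
  sp <- approx(traj$t, v_traj, xout = tl, rule = 2)$y
  finst <- f0 + speed_slope * sp
  phase <- 2 * pi * cumsum(finst) / sample_rate
  v <- with_seed(seed, amplitude * sin(phase) + rnorm(n, sd = noise_sd))
  lfp <- tibble::tibble(t = tl, v = v)
  structure(lfp, class = c("gt_lfp", class(lfp)), sample_rate = sample_rate)
}
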