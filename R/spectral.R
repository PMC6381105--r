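## Is the 1D track pattern a genuine periodic pattern (one dominant
## spectral peak) or a slice through the 2D hexagonal lattice (up to three
## peaks)?

#' Spatial power spectral density of a linearized profile
#'
#' Mean-subtracted periodogram of the path-integrated firing profile,
#' computed on a fine grid (2.5 cm bins by default, finer than the 10 cm
#' analysis bins, to resolve multi-peak slice spectra). Unoccupied interior
#' bins are linearly interpolated before the transform. Normalised so that
#' the sum of the spectrum equals the profile variance (Parseval).
#'
#' @param profile A `gt_linear_profile` (use `bin = 2.5` for spectra), or
#'   a plain numeric vector sampled at `bin` spacing.
#' @param bin Bin width, cm (taken from the profile when available).
#' @param min_bins Minimum profile length.
#' @return A `gt_spectrum` tibble: `frequency` (cycles/cm), `power`; with
#'   attributes `bin`, `n`, `total_power`.
#' @export
psd <- function(profile, bin = NULL, min_bins = 64) {
  if (inherits(profile, "gt_linear_profile")) {
    v <- profile$rate
    if (is.null(bin)) bin <- attr(profile, "bin")
  } else {
    v <- as.numeric(profile)
    if (is.null(bin)) stop("bin width required for a plain vector")
  }
  ok <- is.finite(v)
  if (sum(ok) < min_bins) stop("profile shorter than ", min_bins, " occupied bins")
  idx <- which(ok)
  v2 <- approx(idx, v[idx], xout = seq(min(idx), max(idx)), rule = 2)$y
  n <- length(v2)
  x <- v2 - mean(v2)
  if (stats::sd(x) < 1e-14) {
    sp <- tibble::tibble(frequency = numeric(0), power = numeric(0))
    return(structure(sp, class = c("gt_spectrum", class(sp)),
                     bin = bin, n = n, total_power = 0, flagged = "zero-power"))
  }
  X <- stats::fft(x)
  nf <- floor(n / 2)
  power <- (Mod(X[2:(nf + 1)])^2) / n^2 * 2   # one-sided
  if (n %% 2 == 0) power[nf] <- power[nf] / 2
  freq <- (1:nf) / (n * bin)
  out <- tibble::tibble(frequency = freq, power = power)
  structure(out, class = c("gt_spectrum", class(out)),
            bin = bin, n = n, total_power = sum(power), flagged = NULL)
}

#' One-peakness score of a power spectrum
#'
#' The peak interval is the contiguous band of frequencies between the two
#' local minima flanking the global maximum of the PSD; the score is the
#' area under the spectrum in that interval divided by the total area.
#' Close to 1 for a single-period (1D regular) pattern; low for slice-like
#' three-peak spectra and for broadband profiles.
#'
#' @param spectrum A `gt_spectrum`.
#' @return Score in (0, 1].
#' @export
one_peakness <- function(spectrum) {
  p <- spectrum$power
  if (length(p) < 3 || sum(p) <= 0) stop("zero-power spectrum")
  imax <- which.max(p)
  ## flanking local minima
  lo <- imax
  while (lo > 1 && p[lo - 1] < p[lo]) lo <- lo - 1
  hi <- imax
  while (hi < length(p) && p[hi + 1] < p[hi]) hi <- hi + 1
  sum(p[lo:hi]) / sum(p)
}

#' Fake-track null for the slice hypothesis
#'
#' Builds the null distribution of the one-peakness score expected if the
#' track firing were a slice through the 2D lattice observed in the arena:
#' the lattice rate is sampled along the real track path for a grid of
#' spatial phase shifts covering one lattice unit cell; from each shifted
#' rate a Poisson surrogate train with the cell's own spike count is drawn
#' (so surrogates carry the same sampling noise as the observed profile),
#' linearized on the path-integrated axis and scored; the 95th percentile
#' of the scores is the threshold.
#'
#' @param series A `gt_distance_series` of the track session.
#' @param traj The track trajectory (supplies the x,y path).
#' @param lattice A list with `spacing`, `orientation`, `phase` (as
#'   [ground_truth()]), e.g. fitted from the arena session or idealized.
#' @param n_spikes Spike count of the cell under test (surrogates are
#'   rate-matched to it). `NULL` scores the noise-free rate profile
#'   instead.
#' @param seed Integer seed for the surrogate spikes.
#' @param n_shift Shifts per unit-cell axis (default 10, so 100 phases).
#' @param bin Spectral bin, cm.
#' @param percentile Threshold percentile (95).
#' @return A `gt_slicenull` list: `threshold`, `scores`, `shifts` (tibble),
#'   `lattice`, `percentile`.
#' @export
fake_track_null <- function(series, traj, lattice, n_spikes = NULL,
                            seed = 1L, n_shift = 10,
                            bin = 2.5, percentile = 95) {
  if (is.null(lattice$spacing) || !is.finite(lattice$spacing)) {
    stop("missing lattice parameters")
  }
  o <- (lattice$orientation %||% 0) * pi / 180
  s <- lattice$spacing
  b1 <- s * c(cos(o), sin(o))
  b2 <- s * c(cos(o + pi / 3), sin(o + pi / 3))
  fr <- (seq_len(n_shift) - 1) / n_shift
  grid <- expand.grid(a = fr, b = fr)
  dt <- traj$t[2] - traj$t[1]
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sh <- grid$a[i] * b1 + grid$b[i] * b2
    rate <- lattice_rate(traj$x1 + sh[1], traj$y1 + sh[2], s,
                         lattice$orientation %||% 0,
                         lattice$phase %||% c(0, 0), peak_rate = 1)
    if (is.null(n_spikes)) {
      prof <- rate_weighted_profile(series, rate, bin)
    } else {
      rate <- rate * n_spikes / max(sum(rate) * dt, 1e-12)
      sp_t <- sample_inhomogeneous_spikes(traj$t, rate, derive_seed(seed, i))
      prof <- linearize_activity(sp_t, series, "path_integrated", bin = bin)
    }
    sp <- tryCatch(psd(prof, bin = bin), error = function(e) NULL)
    if (is.null(sp) || nrow(sp) < 3) return(NA_real_)
    one_peakness(sp)
  }, numeric(1))
  structure(list(threshold = unname(quantile(scores, percentile / 100,
                                             na.rm = TRUE)),
                 scores = scores,
                 shifts = tibble::as_tibble(grid),
                 lattice = lattice, percentile = percentile),
            class = "gt_slicenull")
}

## Occupancy-weighted mean of a per-sample rate on the path-integrated axis.
rate_weighted_profile <- function(series, rate, bin = 2.5) {
  coord <- series$signed
  edges <- seq(floor(min(coord) / bin) * bin,
               ceiling((max(coord) + 1e-9) / bin) * bin, by = bin)
  nb <- length(edges) - 1L
  idx <- pmin(pmax(findInterval(coord, edges), 1L), nb)
  num <- as.numeric(tapply(rate, factor(idx, levels = seq_len(nb)), sum))
  den <- as.numeric(tabulate(idx, nbins = nb))
  v <- ifelse(den > 0, num / den, NA_real_)
  out <- tibble::tibble(bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                        count = num, occupancy = den, rate = v)
  structure(out, class = c("gt_linear_profile", class(out)),
            frame = "path_integrated", bin = bin)
}

#' Slice test of one track cell
#'
#' `TRUE` when the observed one-peakness exceeds the fake-track threshold,
#' i.e. the cell's 1D pattern is too single-peaked to be a slice through
#' its 2D lattice.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param traj The track trajectory.
#' @param lattice Lattice parameters (see [fake_track_null()]).
#' @param bin Spectral bin, cm.
#' @param null Optional precomputed `gt_slicenull`.
#' @param ... Passed to [fake_track_null()].
#' @return A tibble: `score`, `threshold`, `rejects_slice`.
#' @export
slice_test <- function(spikes, series, traj, lattice, bin = 2.5,
                       null = NULL, ...) {
  prof <- linearize_activity(spikes, series, "path_integrated", bin = bin)
  score <- one_peakness(psd(prof, bin = bin))
  if (is.null(null)) {
    null <- fake_track_null(series, traj, lattice, n_spikes = length(spikes),
                            bin = bin, ...)
  }
  tibble::tibble(score = score, threshold = null$threshold,
                 rejects_slice = score > null$threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
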