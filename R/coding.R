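## The core inference: is track firing anchored to the track (allocentric),
## to the signed cumulative distance (path integration), to absolute
## travelled distance, or to elapsed time?

## Pearson autocorrelation of a rate vector (NA = unoccupied) over positive
## lags; returns r per lag (NA where < min_pairs overlapping bins).
rate_autocorr_lags <- function(v, max_lag, min_pairs = 10) {
  n <- length(v)
  fin <- is.finite(v)
  v0 <- ifelse(fin, v, 0)
  out <- rep(NA_real_, max_lag)
  for (l in seq_len(max_lag)) {
    if (l >= n - 2) break
    i1 <- 1:(n - l); i2 <- (1 + l):n
    ok <- fin[i1] & fin[i2]
    m <- sum(ok)
    if (m < min_pairs) next
    x <- v0[i1] * ok; y <- v0[i2] * ok
    sx <- sum(x); sy <- sum(y)
    vx <- m * sum(x * x) - sx * sx
    vy <- m * sum(y * y) - sy * sy
    if (vx < 1e-12 || vy < 1e-12) next
    out[l] <- (m * sum(x * y) - sx * sy) / sqrt(vx * vy)
  }
  pmin(pmax(out, -1), 1)
}

## Local maxima of an autocorrelation sequence: above `min_value`, separated
## by at least `min_sep` bins (greedy, in lag order). Returns indices.
acorr_peak_lags <- function(r, min_value = 0, min_sep = 2) {
  idx <- local_maxima(r)  # interior maxima only: the lag-1 shoulder of the
                          # central peak is not a field-distance peak
  idx <- idx[idx >= 1 & is.finite(r[idx]) & r[idx] > min_value]
  keep <- integer(0)
  for (i in idx) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_sep) {
      keep <- c(keep, i)
    }
  }
  keep
}

#' 1D autocorrelation of a linearized firing profile
#'
#' Pearson autocorrelation of the binned rate over overlapping occupied
#' bins at each positive lag. Peaks are local maxima above zero separated
#' by at least two bins; the lag of the first peak measures the distance
#' between firing fields, and the mean of the first two peak values is the
#' regularity statistic tested against the jitter null.
#'
#' @param profile A `gt_linear_profile` from [linearize_activity()].
#' @param max_lag Maximum lag in frame units (default 500 cm or, for the
#'   time frame, 60 s).
#' @param min_pairs Minimum overlapping occupied bins per lag.
#' @return A `gt_acorr1d` tibble (`lag`, `r`, lag 0 included with r = 1)
#'   with attributes `peak_lags`, `peak_values`, `first_peak_lag`,
#'   `mean_first_two`, `frame`, `bin`.
#' @export
autocorrelation_1d <- function(profile, max_lag = NULL, min_pairs = 10) {
  binw <- attr(profile, "bin")
  frame <- attr(profile, "frame")
  if (is.null(max_lag)) max_lag <- if (identical(frame, "time")) 60 else 500
  v <- profile$rate
  vv <- v[is.finite(v)]
  if (length(vv) < 3 || stats::sd(vv) < 1e-12) {
    stop("profile constant or empty: autocorrelation undefined")
  }
  L <- max(2L, min(floor(max_lag / binw), nrow(profile) - 3L))
  r <- rate_autocorr_lags(v, L, min_pairs)
  pk <- acorr_peak_lags(r)
  peak_vals <- r[pk]
  out <- tibble::tibble(lag = c(0, seq_len(L) * binw), r = c(1, r))
  structure(out, class = c("gt_acorr1d", class(out)),
            peak_lags = pk * binw, peak_values = peak_vals,
            first_peak_lag = if (length(pk) >= 1) pk[1] * binw else NA_real_,
            mean_first_two = if (length(pk) >= 2) mean(peak_vals[1:2]) else NA_real_,
            frame = frame, bin = binw)
}

#' Toeplitz rendering of a 1D autocorrelation
#'
#' The matrix whose entry (i, j) is the autocorrelation at lag |i - j|,
#' rendered over the first `extent` frame units (500 cm, about one lap, by
#' default); periodic firing shows as regular diagonal banding.
#'
#' @param acorr A `gt_acorr1d`.
#' @param extent Rendering extent in frame units.
#' @return A numeric matrix.
#' @export
toeplitz_rendering <- function(acorr, extent = 500) {
  binw <- attr(acorr, "bin")
  n <- min(floor(extent / binw) + 1L, nrow(acorr))
  r <- acorr$r[seq_len(n)]
  stats::toeplitz(r)
}

## All lap-pair correlations of a lap matrix: one pairwise-complete cor()
## call over rows, then pairs with fewer than min_bins mutually occupied
## bins are dropped.
lap_pair_correlations <- function(m, min_bins = 5) {
  cm <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  fin <- matrix(as.numeric(is.finite(m)), nrow(m), ncol(m))
  cnt <- tcrossprod(fin)
  cm[cnt < min_bins] <- NA_real_
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(lap_a = iu[, 1], lap_b = iu[, 2], r = cm[iu])
}

#' Allocentric lap correlation
#'
#' Average Pearson correlation of cell activity between each pair of laps
#' of the lap-position matrix, averaged through the Fisher Z scale.
#' High values mean the firing fields keep the same track position across
#' laps (allocentric coding).
#'
#' @param lapmat A `gt_lap_matrix`.
#' @param min_bins Minimum mutually occupied bins per lap pair.
#' @return A list: `mean_r`, `pairs` (tibble of all pair correlations),
#'   `n_laps`.
#' @export
allocentric_correlation <- function(lapmat, min_bins = 5) {
  pairs <- lap_pair_correlations(lapmat, min_bins)
  list(mean_r = fisher_mean_r(pairs$r), pairs = pairs, n_laps = nrow(lapmat))
}

## Circular shift of a vector by s bins to the right (NA-preserving).
circ_shift <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(v)
  c(v[(n - s + 1):n], v[1:(n - s)])
}

#' Path-integration-corrected lap correlation
#'
#' If firing follows path-integrated distance with field distance `delta`,
#' the pattern precesses by `C mod delta` per lap. Each lap row is
#' circularly shifted by `lap_index * (C mod delta)` so that a
#' delta-periodic pattern re-aligns across laps; the mean Fisher-averaged
#' lap-pair correlation of the shifted matrix is returned. A corrected
#' correlation exceeding the uncorrected (allocentric) one indicates
#' path-integrated coding. When `delta` divides the circumference the shift
#' is zero and the corrected value equals the allocentric one; when `delta`
#' is not larger than one position bin the correction cannot be resolved
#' and the allocentric value is returned with `corrected = FALSE`.
#'
#' @param lapmat A `gt_lap_matrix`.
#' @param field_distance Field distance `delta` in cm (usually the first
#'   peak of [autocorrelation_1d()] of the path-integrated profile).
#' @param min_bins Minimum mutually occupied bins per lap pair.
#' @return A list: `mean_r`, `pairs`, `shift_cm` per lap, `residual`
#'   (`C mod delta`), `corrected` (logical).
#' @export
path_integrated_correlation <- function(lapmat, field_distance,
                                        min_bins = 5) {
  C <- attr(lapmat, "C"); binw <- attr(lapmat, "bin")
  lap_ids <- attr(lapmat, "lap_ids")
  if (!is.finite(field_distance) || field_distance <= binw) {
    al <- allocentric_correlation(lapmat, min_bins)
    return(list(mean_r = al$mean_r, pairs = al$pairs,
                shift_cm = rep(0, nrow(lapmat)), residual = NA_real_,
                corrected = FALSE))
  }
  rho <- C %% field_distance
  if (min(rho, field_distance - rho) < 1e-9) rho <- 0
  shifts_cm <- lap_ids * rho
  shifted <- lapmat
  for (k in seq_len(nrow(lapmat))) {
    shifted[k, ] <- circ_shift(lapmat[k, ], round(shifts_cm[k] / binw))
  }
  pairs <- lap_pair_correlations(shifted, min_bins)
  list(mean_r = fisher_mean_r(pairs$r), pairs = pairs,
       shift_cm = shifts_cm, residual = rho, corrected = TRUE)
}

#' Split-half control of the path-integration correction
#'
#' Guards against circularity: the path-integrated firing map is split in
#' two equal (temporal) halves; the field distance is estimated from the
#' first half only and the correction is then applied to the laps of the
#' second half. Requires at least 4 laps.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param C Circumference, cm.
#' @param nbins Lap-matrix position bins.
#' @return A list: `field_distance` (from the first half),
#'   `allocentric_r` and `corrected_r` on the second half, `n_laps`.
#' @export
split_half_control <- function(spikes, series,
                               C = attr(series, "circumference"), nbins = 47) {
  lapmat <- lap_position_matrix(spikes, series, C, nbins)
  L <- nrow(lapmat)
  if (L < 4) stop("split-half control requires at least 4 laps")
  t_cut <- max(series$t) / 2
  in_first <- series$t <= t_cut
  prof1 <- linearize_activity(spikes[spikes <= t_cut], series,
                              "path_integrated", restrict = in_first)
  fd <- attr(autocorrelation_1d(prof1), "first_peak_lag")

  win <- attr(lapmat, "lap_windows")
  second_rows <- which((win[, "start_t"] + win[, "end_t"]) / 2 > t_cut)
  sub <- function(m, rows) {
    out <- m[rows, , drop = FALSE]
    attr(out, "occupancy") <- attr(m, "occupancy")[rows, , drop = FALSE]
    attr(out, "lap_ids") <- attr(m, "lap_ids")[rows]
    attr(out, "lap_direction") <- attr(m, "lap_direction")[rows]
    attr(out, "C") <- attr(m, "C"); attr(out, "bin") <- attr(m, "bin")
    class(out) <- class(m)
    out
  }
  second <- sub(lapmat, second_rows)
  if (nrow(second) < 2) stop("not enough laps in the second half")
  list(field_distance = fd,
       allocentric_r = allocentric_correlation(second)$mean_r,
       corrected_r = path_integrated_correlation(second, fd)$mean_r,
       n_laps = L)
}

## Internal fast context for jitter surrogates: fixed occupancy/binning per
## frame, only spike coordinates change.
make_jitter_context <- function(series, frame, bin = NULL) {
  if (is.null(bin)) bin <- if (frame == "time") 1 else 10
  coord <- switch(frame,
                  path_integrated = series$signed,
                  travelled = series$absolute,
                  time = series$t)
  dt <- series$t[2] - series$t[1]
  edges <- seq(floor(min(coord) / bin) * bin,
               ceiling((max(coord) + 1e-9) / bin) * bin, by = bin)
  nb <- length(edges) - 1L
  occ <- as.numeric(tabulate(pmin(pmax(findInterval(coord, edges), 1L), nb),
                             nbins = nb)) * dt
  cf <- approxfun(series$t, coord, rule = 2)
  max_lag <- if (frame == "time") 60 else 500
  list(edges = edges, nb = nb, occ = occ, coordfun = cf, bin = bin,
       max_lag_bins = max(2L, min(floor(max_lag / bin), nb - 3L)))
}

## Mean of the first two autocorrelation peak values of a jittered train.
jitter_statistic <- function(spike_times, ctx) {
  sc <- ctx$coordfun(spike_times)
  cnt <- as.numeric(tabulate(pmin(pmax(findInterval(sc, ctx$edges), 1L),
                                  ctx$nb), nbins = ctx$nb))
  v <- ifelse(ctx$occ > 0, cnt / ctx$occ, NA_real_)
  vv <- v[is.finite(v)]
  if (length(vv) < 3 || stats::sd(vv) < 1e-12) return(NA_real_)
  r <- rate_autocorr_lags(v, ctx$max_lag_bins)
  pk <- acorr_peak_lags(r)
  if (length(pk) < 2) return(NA_real_)
  mean(r[pk[1:2]])
}

## One jittered surrogate train. Noise magnitudes are drawn per spike
## uniformly within [min_scale, max_scale] with random sign. mode
## "interval": the noise perturbs interspike intervals and spike times are
## re-accumulated, so displacement diffuses along the train and long-range
## regularity is destroyed while the local rate is kept. mode
## "independent": each spike is displaced independently (displacement is
## bounded by max_scale, so slow periodicity survives; kept for
## comparison).
jitter_train <- function(spikes, dur, mode, min_scale, max_scale) {
  sp <- sort(spikes)
  m <- length(sp)
  if (mode == "independent") {
    noise <- runif(m, min_scale, max_scale) * sample(c(-1, 1), m, replace = TRUE)
    return(pmin(pmax(sp + noise, 0), dur))
  }
  isi <- diff(sp)
  noise <- runif(m - 1, min_scale, max_scale) *
    sample(c(-1, 1), m - 1, replace = TRUE)
  isi2 <- pmax(isi + noise, 0)
  out <- sp[1] + c(0, cumsum(isi2))
  ## keep the surrogate inside the session by wrapping
  out %% dur
}

#' Jitter surrogate null for 1D firing regularity
#'
#' Builds the null distribution of the regularity statistic (mean of the
#' first two autocorrelation peak values) under spike-time jitter: for each
#' permutation, noise whose magnitude is drawn uniformly between one fifth
#' of the smallest interspike interval and 500 ms (random sign, independent
#' per spike) is added to the spike-time series; the linearized
#' autocorrelation is then recomputed. The threshold is the stated
#' percentile of the null distribution.
#'
#' In the default `"interval"` mode the noise perturbs each interspike
#' interval and spike times are re-accumulated, so the displacement
#' diffuses along the train: firing-rate structure is preserved locally
#' while periodic alignment at field-distance scales is destroyed, which is
#' the property a regularity null requires (independent per-spike offsets
#' bounded by 500 ms displace spikes by a few cm at track running speeds
#' and leave the statistic essentially unchanged; that mode is available as
#' `"independent"`).
#'
#' @param spikes Spike times, s (at least 2).
#' @param series A `gt_distance_series`.
#' @param frame `"path_integrated"`, `"travelled"` or `"time"`.
#' @param n Number of permutations (default 400).
#' @param percentile Threshold percentile (default 99).
#' @param seed Integer seed.
#' @param max_jitter Upper end of the jitter-scale range, s.
#' @param mode `"interval"` (cumulative) or `"independent"` per-spike
#'   jitter.
#' @return A `gt_jitter` list: `threshold`, `null` (the n statistics),
#'   `observed`, `frame`, `percentile`, `seed`.
#' @export
jitter_null <- function(spikes, series,
                        frame = c("path_integrated", "travelled", "time"),
                        n = 400, percentile = 99, seed = 1L,
                        max_jitter = 0.5, mode = c("interval", "independent")) {
  frame <- match.arg(frame)
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (length(spikes) < 2) stop("jitter null requires at least 2 spikes")
  ctx <- make_jitter_context(series, frame)
  dur <- max(series$t)
  min_scale <- max(min(diff(sort(spikes))) / 5, 1e-4)
  stats_null <- with_seed(seed, {
    vapply(seq_len(n), function(j) {
      jitter_statistic(jitter_train(spikes, dur, mode, min_scale, max_jitter),
                       ctx)
    }, numeric(1))
  })
  structure(list(threshold = unname(quantile(stats_null, percentile / 100,
                                             na.rm = TRUE, names = FALSE)),
                 null = stats_null,
                 observed = jitter_statistic(spikes, ctx),
                 frame = frame, percentile = percentile,
                 seed = as.integer(seed)),
            class = "gt_jitter")
}

## Permutation test for per-cell allocentric significance: random circular
## rotations of each lap row; p = fraction of permuted mean r >= observed.
allocentric_permutation_test <- function(lapmat, n = 1000, seed = 1L) {
  obs <- allocentric_correlation(lapmat)$mean_r
  nb <- ncol(lapmat)
  L <- nrow(lapmat)
  m0 <- unclass(lapmat)[seq_len(L), , drop = FALSE]
  cols <- matrix(rep(seq_len(nb), each = L), L, nb)
  rows <- matrix(rep(seq_len(L), nb), L, nb)
  null <- with_seed(seed, {
    vapply(seq_len(n), function(j) {
      sh <- sample.int(nb, L, replace = TRUE)
      jdx <- ((cols - sh - 1L) %% nb) + 1L
      m <- matrix(m0[cbind(as.vector(rows), as.vector(jdx))], L, nb)
      fast_mean_pair_r(m)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + sum(is.finite(null)))
  list(observed = obs, p_value = p, null = null)
}

## Fisher-averaged mean of all lap-pair correlations, lean inner loop of
## the permutation test (same quantity as allocentric_correlation()).
fast_mean_pair_r <- function(m, min_bins = 5) {
  cm <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  fin <- matrix(as.numeric(is.finite(m)), nrow(m), ncol(m))
  cnt <- tcrossprod(fin)
  ut <- upper.tri(cm)
  r <- cm[ut]
  r[cnt[ut] < min_bins] <- NA_real_
  fisher_mean_r(r)
}

#' Classify the coding scheme of one track cell
#'
#' Computes the three linearizations, their autocorrelation regularity
#' statistics and the lap-correlation analysis, and flags each coding
#' scheme: a distance/time frame is flagged when the mean of the first two
#' autocorrelation peaks reaches that frame's jitter threshold; allocentric
#' coding is flagged by a per-cell permutation test of the lap correlation
#' (alpha = 0.05). The primary label is the flagged distance frame with the
#' largest margin over its threshold, else `"allocentric"` if only the lap
#' test is significant, else `"none"`.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param thresholds Named list/vector with elements `path_integrated`,
#'   `travelled`, `time`: the jitter thresholds (from [jitter_null()] or a
#'   pooled study threshold).
#' @param alpha Allocentric permutation-test level.
#' @param n_alloc_perm Permutations for the allocentric test.
#' @param seed Integer seed.
#' @param nbins Lap-matrix bins.
#' @return A one-row tibble: spike count, per-frame statistics and flags,
#'   field distance, allocentric and corrected lap correlations, p value,
#'   and `label`.
#' @export
classify_cell <- function(spikes, series, thresholds,
                          alpha = 0.05, n_alloc_perm = 1000, seed = 1L,
                          nbins = 47) {
  thr <- unlist(thresholds)[c("path_integrated", "travelled", "time")]
  frames <- c("path_integrated", "travelled", "time")
  if (length(spikes) < 5) {
    return(tibble::tibble(
      n_spikes = length(spikes), stat_path_integrated = NA_real_,
      stat_travelled = NA_real_, stat_time = NA_real_,
      flag_path_integrated = FALSE, flag_travelled = FALSE,
      flag_time = FALSE, flag_allocentric = FALSE,
      field_distance = NA_real_, allocentric_r = NA_real_,
      corrected_r = NA_real_, allocentric_p = NA_real_,
      label = "none", degenerate = TRUE))
  }
  stats_frame <- purrr::map_dbl(frames, function(fr) {
    ctx <- make_jitter_context(series, fr)
    jitter_statistic(spikes, ctx)
  })
  names(stats_frame) <- frames
  flags <- is.finite(stats_frame) & is.finite(thr) & stats_frame >= thr

  prof_pi <- linearize_activity(spikes, series, "path_integrated")
  fd <- tryCatch(attr(autocorrelation_1d(prof_pi), "first_peak_lag"),
                 error = function(e) NA_real_)

  al_r <- NA_real_; corr_r <- NA_real_; al_p <- NA_real_; al_flag <- FALSE
  lm_try <- tryCatch(lap_position_matrix(spikes, series, nbins = nbins),
                     error = function(e) NULL)
  if (!is.null(lm_try)) {
    perm <- allocentric_permutation_test(lm_try, n_alloc_perm, seed)
    al_r <- perm$observed; al_p <- perm$p_value
    al_flag <- is.finite(al_p) && al_p < alpha
    corr_r <- path_integrated_correlation(lm_try, fd)$mean_r
  }

  label <- "none"
  if (any(flags)) {
    margin <- stats_frame - thr
    label <- frames[which.max(ifelse(flags, margin, -Inf))]
  } else if (al_flag) {
    label <- "allocentric"
  }
  tibble::tibble(
    n_spikes = length(spikes),
    stat_path_integrated = stats_frame[["path_integrated"]],
    stat_travelled = stats_frame[["travelled"]],
    stat_time = stats_frame[["time"]],
    flag_path_integrated = unname(flags[["path_integrated"]]),
    flag_travelled = unname(flags[["travelled"]]),
    flag_time = unname(flags[["time"]]),
    flag_allocentric = al_flag,
    field_distance = fd, allocentric_r = al_r, corrected_r = corr_r,
    allocentric_p = al_p, label = label, degenerate = FALSE)
}
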