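## Small numeric helpers shared by several modules. These are deliberately
## plain: each is either a textbook formula (analytic signal, Rayleigh vector)
## or a convention the whole package must share (angle wrapping, smoothing).

#' Fisher Z-transformation of correlation coefficients
#'
#' `fisher_z()` maps Pearson correlations to the Z scale (`atanh`), on which
#' correlation values are averaged and tested throughout the package;
#' `fisher_z_inv()` maps back (`tanh`). Values with `|r| = 1` are clipped to
#' 0.999999 (keeping their sign) so that averages stay finite; the clip is
#' reported via the `"clipped"` attribute.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param z Numeric vector of Z values.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' fisher_z(0.6) # 0.6931
#' fisher_z_inv(fisher_z(0.25))
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("fisher_z(): correlation outside [-1, 1]")
  }
  r <- pmin(pmax(r, -1), 1)
  clip <- abs(r) >= 1
  r[clip] <- sign(r[clip]) * 0.999999
  z <- atanh(r)
  attr(z, "clipped") <- any(clip, na.rm = TRUE)
  z
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

## Mean correlation through the Z scale; NAs dropped.
fisher_mean_r <- function(r) {
  r <- r[is.finite(r)]
  if (length(r) == 0L) return(NA_real_)
  fisher_z_inv(mean(fisher_z(r)))
}

## Wrap angles (radians) to (-pi, pi].
wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

## Wrap degrees to [0, 360).
wrap_deg <- function(a) ((a %% 360) + 360) %% 360

## Signed circular difference in degrees, result in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- wrap_pi((a - b) * pi / 180) * 180 / pi
  d
}

## Rayleigh mean resultant vector of angles (radians) with optional weights.
## Returns list(length, mean_angle).
rayleigh_vector <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  keep <- is.finite(theta) & is.finite(w)
  theta <- theta[keep]; w <- w[keep]
  if (length(theta) == 0L || sum(w) <= 0) {
    return(list(length = NA_real_, mean_angle = NA_real_))
  }
  C <- sum(w * cos(theta)) / sum(w)
  S <- sum(w * sin(theta)) / sum(w)
  list(length = sqrt(C^2 + S^2), mean_angle = atan2(S, C))
}

#' Circular V-test for a specified mean direction
#'
#' Tests non-uniformity of a sample of angles with the alternative
#' concentrated at a known direction `mu`. The statistic is
#' `V = n * Rbar * cos(theta_bar - mu)` with `u = V * sqrt(2 / n)` referred to
#' the standard normal (large-sample approximation).
#'
#' @param theta_deg Angles in degrees.
#' @param mu_deg Hypothesised mean direction in degrees (default 0).
#' @return A tibble with `n`, `v` (the V statistic), `u` and `p_value`.
#' @export
v_test <- function(theta_deg, mu_deg = 0) {
  theta <- theta_deg[is.finite(theta_deg)] * pi / 180
  n <- length(theta)
  if (n < 1) stop("v_test(): no finite angles")
  rv <- rayleigh_vector(theta)
  v <- n * rv$length * cos(rv$mean_angle - mu_deg * pi / 180)
  u <- v * sqrt(2 / n)
  tibble::tibble(n = n, v = v, u = u, p_value = stats::pnorm(u, lower.tail = FALSE))
}

## Analytic signal of a real series via the frequency-domain construction
## (positive frequencies doubled, negative zeroed). Used for instantaneous
## frequency of band-passed LFP and of spike-train autocorrelograms.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Instantaneous frequency (Hz) from an analytic signal sampled at fs.
## Length matches the input (first difference padded at the front).
instantaneous_frequency <- function(z, fs) {
  ph <- Arg(z)
  dph <- wrap_pi(diff(ph))
  f <- dph * fs / (2 * pi)
  c(f[1], f)
}

## Gaussian-kernel smoothing of a regularly sampled series, NA-aware
## (normalised by the smoothed mask so edges and gaps are unbiased).
## sd_bins is the kernel standard deviation in samples.
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  num <- stats::filter(c(rep(0, half), x0, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), as.numeric(ok), rep(0, half)), k, sides = 2)
  out <- as.numeric(num / den)[(half + 1):(half + length(x))]
  out[!ok & !(as.numeric(den)[(half + 1):(half + length(x))] > 0)] <- NA_real_
  out
}

## Centered rolling mean with window w samples (odd), edges shrunk.
roll_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, ifelse(is.finite(x), x, 0)))
  cn <- cumsum(c(0, as.numeric(is.finite(x))))
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / pmax(cn[hi + 1] - cn[lo], 1)
}

## Local maxima of a series: strictly greater than both neighbours; plateaus
## take their first index. Returns integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  x[!is.finite(x)] <- -Inf
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

## Deterministic child seeds derived from a user seed; keeps values < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
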