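## 2D rate maps and autocorrelogram-based grid metrics.

## Separable Gaussian smoothing of a matrix (zero padding outside).
smooth2d_gauss <- function(m, sd_bins) {
  if (sd_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  sm_rows <- t(apply(m, 1, function(v) {
    stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)[(half + 1):(half + length(v))]
  }))
  apply(sm_rows, 2, function(v) {
    stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)[(half + 1):(half + length(v))]
  })
}

#' Occupancy-normalised 2D firing-rate map
#'
#' Implements the quotient kernel estimator: the rate at a location is the
#' Gaussian-smoothed spike count divided by the Gaussian-smoothed occupancy
#' time, on a grid of `bin` x `bin` cm bins (2.5 cm default) with smoothing
#' factor `h` (5 cm = 2 bins default). Bins never visited are invalid
#' (`NA`).
#'
#' @param traj A `gt_trajectory`.
#' @param spikes Spike times, s; must lie within the session.
#' @param bin Bin side, cm.
#' @param h Gaussian smoothing factor (kernel sd), cm.
#' @param extent Half-extent of the grid, cm; defaults to the enclosure
#'   radius.
#' @return A `gt_ratemap` list: `rate` (Hz matrix, x by y), `occupancy`
#'   (s), `mask` (visited), `x`, `y` (bin centres), `bin`, `h`,
#'   `peak_rate`, `duration`.
#' @export
compute_rate_map <- function(traj, spikes, bin = 2.5, h = 2 * 2.5,
                             extent = NULL) {
  if (nrow(traj) < 2) stop("empty trajectory")
  if (length(spikes) > 0 &&
      (min(spikes) < 0 || max(spikes) > traj_duration(traj) + 1e-9)) {
    stop("spike times outside the session")
  }
  if (is.null(extent)) {
    extent <- attr(traj, "radius_outer")
    if (is.null(extent) || !is.finite(extent)) {
      extent <- max(abs(c(traj$x1, traj$y1))) + bin
    }
  }
  edges <- seq(-extent, extent + bin - 1e-9, by = bin)
  nb <- length(edges) - 1L
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  dt <- traj$t[2] - traj$t[1]

  ix <- pmin(pmax(findInterval(traj$x1, edges), 1L), nb)
  iy <- pmin(pmax(findInterval(traj$y1, edges), 1L), nb)
  occ <- matrix(0, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)), factor(iy, levels = seq_len(nb)))
  occ[] <- as.numeric(tab) * dt

  sx <- approx(traj$t, traj$x1, xout = spikes, rule = 2)$y
  sy <- approx(traj$t, traj$y1, xout = spikes, rule = 2)$y
  cnt <- matrix(0, nb, nb)
  if (length(spikes) > 0) {
    jx <- pmin(pmax(findInterval(sx, edges), 1L), nb)
    jy <- pmin(pmax(findInterval(sy, edges), 1L), nb)
    tj <- table(factor(jx, levels = seq_len(nb)), factor(jy, levels = seq_len(nb)))
    cnt[] <- as.numeric(tj)
  }

  sdb <- h / bin
  occ_s <- smooth2d_gauss(occ, sdb)
  cnt_s <- smooth2d_gauss(cnt, sdb)
  mask <- occ > 0
  rate <- matrix(NA_real_, nb, nb)
  ok <- mask & occ_s > 1e-9
  rate[ok] <- cnt_s[ok] / occ_s[ok]
  structure(list(rate = rate, occupancy = occ, mask = mask,
                 x = ctr, y = ctr, bin = bin, h = h,
                 peak_rate = suppressWarnings(max(rate, na.rm = TRUE)),
                 duration = traj_duration(traj)),
            class = "gt_ratemap")
}

#' @export
print.gt_ratemap <- function(x, ...) {
  cat(sprintf("<gt_ratemap> %d x %d bins of %g cm, peak %.2f Hz\n",
              length(x$x), length(x$y), x$bin, x$peak_rate))
  invisible(x)
}

## Full 2D cross-correlation sum_s A(s) B(s + tau) over all lags, via FFT.
## Returns a (2m-1) x (2n-1) matrix with lag 0 at the centre.
xcorr2_fft <- function(A, B) {
  m <- nrow(A); n <- ncol(A)
  M <- stats::nextn(2 * m - 1, 2); N <- stats::nextn(2 * n - 1, 2)
  Ap <- matrix(0, M, N); Bp <- matrix(0, M, N)
  Ap[1:m, 1:n] <- A; Bp[1:m, 1:n] <- B
  FA <- stats::fft(Ap); FB <- stats::fft(Bp)
  CC <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (M * N)
  ## lag tau in [-(m-1), m-1]: entry at index (tau mod M) + 1
  idx_r <- c((M - m + 2):M, 1:m)
  idx_c <- c((N - n + 2):N, 1:n)
  CC[idx_r, idx_c]
}

## Masked-Pearson cross-correlogram of two equally shaped maps (NA = invalid).
masked_pearson_xcorr <- function(A, B, min_overlap = 20) {
  wa <- ifelse(is.finite(A), 1, 0); wb <- ifelse(is.finite(B), 1, 0)
  a <- ifelse(is.finite(A), A, 0); b <- ifelse(is.finite(B), B, 0)
  n   <- round(xcorr2_fft(wa, wb))
  Sx  <- xcorr2_fft(a, wb)
  Sy  <- xcorr2_fft(wa, b)
  Sxy <- xcorr2_fft(a, b)
  Sxx <- xcorr2_fft(a^2, wb)
  Syy <- xcorr2_fft(wa, b^2)
  num <- n * Sxy - Sx * Sy
  den <- sqrt(pmax(n * Sxx - Sx^2, 0) * pmax(n * Syy - Sy^2, 0))
  r <- ifelse(n >= min_overlap & den > 1e-9, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  list(r = r, n = n)
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson product-moment correlation of the map with itself at every 2D
#' spatial lag, computed only over bins valid in both copies (correction for
#' edge effects and unvisited locations). Lags with fewer than `min_overlap`
#' mutually valid bins are invalid.
#'
#' @param map A `gt_ratemap`.
#' @param min_overlap Minimum number of overlapping valid bins per lag.
#' @return A `gt_acorr2d` list: `r` (correlations in `[-1, 1]`), `n`
#'   (overlap counts), `lag_x`, `lag_y` (cm), `bin`.
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20) {
  v <- map$rate
  vv <- v[is.finite(v)]
  if (length(vv) < min_overlap || stats::sd(vv) < 1e-12) {
    stop("map constant or too small: autocorrelation undefined")
  }
  mx <- masked_pearson_xcorr(v, v, min_overlap)
  nl <- nrow(mx$r)
  lag <- (seq_len(nl) - (nrow(v))) * map$bin
  structure(list(r = mx$r, n = mx$n, lag_x = lag, lag_y = lag, bin = map$bin),
            class = "gt_acorr2d")
}

## Contiguous region around the centre of an autocorrelogram with r >= thr
## (8-connected). Returns logical matrix.
central_region <- function(R, thr = 0.2) {
  nr <- nrow(R); nc <- ncol(R)
  c0 <- c((nr + 1) %/% 2, (nc + 1) %/% 2)
  above <- is.finite(R) & R >= thr
  visited <- matrix(FALSE, nr, nc)
  if (!above[c0[1], c0[2]]) return(visited)
  queue <- matrix(c0, ncol = 2)
  visited[c0[1], c0[2]] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    nb <- sweep(offs, 2, as.numeric(p), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
    nb <- nb[ok, , drop = FALSE]
    for (k in seq_len(nrow(nb))) {
      i <- nb[k, 1]; j <- nb[k, 2]
      if (!visited[i, j] && above[i, j]) {
        visited[i, j] <- TRUE
        queue <- rbind(queue, c(i, j))
      }
    }
  }
  visited
}

## Local maxima of an autocorrelogram outside the central region, within
## the reliable lag range (overlap shrinks with lag; peaks beyond
## max_dist_frac of the maximum lag are ignored).
## Returns tibble x, y (cm), r, dist.
acorr_peaks <- function(acorr, min_r = 0.1, central_thr = 0.2,
                        max_dist_frac = 0.67) {
  R <- acorr$r
  nr <- nrow(R)
  cen <- central_region(R, central_thr)
  loc <- matrix(FALSE, nr, nr)
  Rz <- ifelse(is.finite(R), R, -Inf)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, nr, nr)
    src_r <- seq_len(nr) + di; src_c <- seq_len(nr) + dj
    okr <- src_r >= 1 & src_r <= nr; okc <- src_c >= 1 & src_c <= nr
    sh[okr, okc] <- Rz[src_r[okr], src_c[okc]]
    if (di == -1 || (di == 0 && dj == -1)) {
      loc0 <- Rz > sh      # strict on "earlier" neighbours
    } else {
      loc0 <- Rz >= sh
    }
    loc <- if (di == -1 && dj == -1) loc0 else loc & loc0
  }
  cand <- which(loc & is.finite(R) & R > min_r & !cen, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          r = numeric(0), dist = numeric(0)))
  }
  x <- acorr$lag_x[cand[, 1]]
  y <- acorr$lag_y[cand[, 2]]
  out <- tibble::tibble(x = x, y = y, r = R[cand],
                        dist = sqrt(x^2 + y^2)) |>
    dplyr::arrange(.data$dist)
  dplyr::filter(out, .data$dist <= max_dist_frac * max(abs(acorr$lag_x)))
}

## Bilinear interpolation of matrix Z over grids xg (rows), yg (cols).
interp2_bilinear <- function(xg, yg, Z, xq, yq) {
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  fi <- (xq - xg[1]) / dx; fj <- (yq - yg[1]) / dy
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  out <- rep(NA_real_, length(xq))
  ok <- i0 >= 1 & i0 + 1 <= length(xg) & j0 >= 1 & j0 + 1 <= length(yg)
  gi <- i0[ok]; gj <- j0[ok]; a <- wi[ok]; b <- wj[ok]
  n <- nrow(Z)
  v00 <- Z[cbind(gi, gj)];     v10 <- Z[cbind(gi + 1, gj)]
  v01 <- Z[cbind(gi, gj + 1)]; v11 <- Z[cbind(gi + 1, gj + 1)]
  out[ok] <- (1 - a) * (1 - b) * v00 + a * (1 - b) * v10 +
    (1 - a) * b * v01 + a * b * v11
  out
}

#' Gridness score of a spatial autocorrelogram
#'
#' Selects the six fields closest to the centre of the autocorrelogram,
#' takes the annular region enclosing them (central peak excluded, outer
#' radius just beyond the six peaks), correlates it with itself rotated by
#' 60 and 120 degrees (group 1) and by 30, 90 and 150 degrees (group 2),
#' and returns the difference between the minimum of group 1 and the
#' maximum of group 2. Rotational symmetry of a hexagonal lattice makes the
#' score large; a radially symmetric map scores near 0.
#'
#' @param acorr A `gt_acorr2d`.
#' @param min_peak_r Peak-detection threshold on the correlation value.
#' @param central_thr Threshold defining the central-peak extent.
#' @param outer_factor Outer annulus radius as a multiple of the median
#'   distance of the six peaks.
#' @param min_peaks Minimum inner peaks required for a defined score.
#'   Six peaks surround the centre for a hexagonal pattern; a perfectly
#'   circular ridge discretises to as few as four local maxima, so the
#'   default accepts four and reports `n_peaks`.
#' @return A `gt_gridness` list: `score`, `rotations` (named correlations),
#'   `peaks` (tibble), `n_peaks`, `r_inner`, `r_outer`, `valid`.
#' @export
gridness <- function(acorr, min_peak_r = 0.1, central_thr = 0.2,
                     outer_factor = 1.3, min_peaks = 4) {
  pk <- acorr_peaks(acorr, min_peak_r, central_thr)
  if (nrow(pk) < min_peaks) {
    return(structure(list(score = NA_real_, rotations = NULL,
                          peaks = pk, n_peaks = nrow(pk),
                          r_inner = NA, r_outer = NA, valid = FALSE),
                     class = "gt_gridness"))
  }
  six <- pk[seq_len(min(6, nrow(pk))), ]
  cen <- central_region(acorr$r, central_thr)
  cen_idx <- which(cen, arr.ind = TRUE)
  r_inner <- if (nrow(cen_idx) == 0) acorr$bin else {
    max(sqrt((acorr$lag_x[cen_idx[, 1]])^2 +
               (acorr$lag_y[cen_idx[, 2]])^2)) + acorr$bin / 2
  }
  r_outer <- outer_factor * stats::median(six$dist)

  gx <- acorr$lag_x; gy <- acorr$lag_y
  coords <- expand.grid(ix = seq_along(gx), iy = seq_along(gy))
  cx <- gx[coords$ix]; cy <- gy[coords$iy]
  d <- sqrt(cx^2 + cy^2)
  in_ann <- d > r_inner & d <= r_outer
  vals <- acorr$r[cbind(coords$ix, coords$iy)]
  sel <- in_ann & is.finite(vals)
  cxs <- cx[sel]; cys <- cy[sel]; v0 <- vals[sel]

  rots <- c(30, 60, 90, 120, 150)
  rc <- vapply(rots, function(a) {
    ar <- a * pi / 180
    xr <- cxs * cos(ar) - cys * sin(ar)
    yr <- cxs * sin(ar) + cys * cos(ar)
    vr <- interp2_bilinear(gx, gy, ifelse(is.finite(acorr$r), acorr$r, NA), xr, yr)
    ok <- is.finite(vr)
    if (sum(ok) < 20) return(NA_real_)
    suppressWarnings(cor(v0[ok], vr[ok]))
  }, numeric(1))
  names(rc) <- paste0("rot", rots)
  score <- min(rc[c("rot60", "rot120")]) - max(rc[c("rot30", "rot90", "rot150")])
  structure(list(score = unname(score), rotations = rc, peaks = six,
                 n_peaks = nrow(pk), r_inner = r_inner, r_outer = r_outer,
                 valid = TRUE),
            class = "gt_gridness")
}

#' @export
print.gt_gridness <- function(x, ...) {
  cat(sprintf("<gt_gridness> score = %.3f (valid = %s)\n",
              x$score, x$valid))
  invisible(x)
}

#' Field spacing from the 2D autocorrelogram
#'
#' Mean of the six distances from the central peak to the vertices of the
#' inner hexagon.
#'
#' @inheritParams gridness
#' @return Spacing in cm (`NA` if fewer than six peaks).
#' @export
field_spacing_2d <- function(acorr, min_peak_r = 0.1, central_thr = 0.2) {
  pk <- acorr_peaks(acorr, min_peak_r, central_thr)
  if (nrow(pk) < 6) return(NA_real_)
  mean(pk$dist[1:6])
}

#' Circular rotation of spike times
#'
#' Shifts all spike times by `shift` seconds modulo the session duration,
#' preserving spike count and interspike structure modulo the wrap. The
#' building block of the rotation shuffles.
#'
#' @param spikes Spike times, s.
#' @param shift Shift, s.
#' @param duration Session duration, s.
#' @return Rotated, sorted spike times.
#' @export
rotate_spike_times <- function(spikes, shift, duration) {
  sort((spikes + shift) %% duration)
}

#' Rotation-shuffle threshold for the gridness score
#'
#' For every cell, spike times are circularly rotated relative to the
#' position series by a random time drawn uniformly between 20 s and the
#' session duration minus 20 s; rate map, autocorrelogram and gridness are
#' recomputed per rotation. The stated percentile of the distribution pooled
#' across all rotations of all cells is the classification threshold.
#'
#' @param cells A list of `list(traj = , spikes = )` pairs.
#' @param n_per_cell Rotations per cell (default 400).
#' @param percentile Pooled percentile (default 95).
#' @param seed Integer seed.
#' @param ... Passed on to [compute_rate_map()].
#' @return A `gt_shuffle` list: `threshold`, `scores` (pooled null
#'   distribution), `percentile`, `n_per_cell`, `seed`.
#' @export
grid_shuffle_threshold <- function(cells, n_per_cell = 400, percentile = 95,
                                   seed = 1L, ...) {
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
      g <- tryCatch({
        m <- compute_rate_map(traj, sp, ...)
        a <- spatial_autocorrelogram(m)
        gridness(a)$score
      }, error = function(e) NA_real_)
      if (is.null(g)) NA_real_ else g
    }, numeric(1))
    scores <- c(scores, sc)
  }
  structure(list(threshold = unname(quantile(scores, percentile / 100,
                                             na.rm = TRUE)),
                 scores = scores, percentile = percentile,
                 n_per_cell = n_per_cell, seed = as.integer(seed)),
            class = "gt_shuffle")
}

#' Detect firing fields in a rate map or linear profile
#'
#' Connected regions (8-connectivity in 2D, adjacency in 1D) of bins whose
#' rate exceeds `threshold_frac` of the cell's peak rate, with at least
#' `min_pixels` bins. Defaults follow the arena (nine 2.5 cm pixels) and
#' track (five 2.5 cm pixels) conventions.
#'
#' @param x A `gt_ratemap`, a `gt_linear_profile`, or a numeric vector.
#' @param min_pixels Minimum region size in bins (default 9 for 2D, 5 for
#'   1D).
#' @param threshold_frac Fraction of the peak rate (0.30).
#' @return A tibble, one row per field: `field`, `n_pixels`, `peak_rate`,
#'   and centroid columns (`x`, `y` for maps; `coord` for profiles), with a
#'   `"peak_rate_sd"` attribute (the firing-field variability statistic).
#' @export
detect_fields <- function(x, min_pixels = NULL, threshold_frac = 0.30) {
  UseMethod("detect_fields")
}

#' @export
detect_fields.gt_ratemap <- function(x, min_pixels = 9, threshold_frac = 0.30) {
  R <- x$rate
  pk <- suppressWarnings(max(R, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0) {
    return(empty_fields(c("x", "y")))
  }
  above <- is.finite(R) & R > threshold_frac * pk
  lab <- label_components_2d(above)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    if (nrow(w) < min_pixels) return(NULL)
    vals <- R[w]
    cx <- sum(x$x[w[, 1]] * vals) / sum(vals)
    cy <- sum(x$y[w[, 2]] * vals) / sum(vals)
    tibble::tibble(n_pixels = nrow(w), peak_rate = max(vals),
                   x = cx, y = cy)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_fields(c("x", "y")))
  out <- dplyr::mutate(out, field = dplyr::row_number(), .before = 1)
  attr(out, "peak_rate_sd") <- if (nrow(out) > 1) stats::sd(out$peak_rate) else 0
  out
}

#' @export
detect_fields.gt_linear_profile <- function(x, min_pixels = 5,
                                            threshold_frac = 0.30) {
  detect_fields_1d(x$rate, x$bin_mid, min_pixels, threshold_frac)
}

#' @export
detect_fields.numeric <- function(x, min_pixels = 5, threshold_frac = 0.30) {
  detect_fields_1d(x, seq_along(x), min_pixels, threshold_frac)
}

empty_fields <- function(coord_cols) {
  out <- tibble::tibble(field = integer(0), n_pixels = integer(0),
                        peak_rate = numeric(0))
  for (cc in coord_cols) out[[cc]] <- numeric(0)
  attr(out, "peak_rate_sd") <- NA_real_
  out
}

detect_fields_1d <- function(rate, coord, min_pixels, threshold_frac) {
  pk <- suppressWarnings(max(rate, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0) return(empty_fields("coord"))
  above <- is.finite(rate) & rate > threshold_frac * pk
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  rows <- list()
  for (k in which(r$values)) {
    sel <- starts[k]:ends[k]
    if (length(sel) < min_pixels) next
    vals <- rate[sel]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      n_pixels = length(sel), peak_rate = max(vals),
      coord = sum(coord[sel] * vals) / sum(vals))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_fields("coord"))
  out <- dplyr::mutate(out, field = dplyr::row_number(), .before = 1)
  attr(out, "peak_rate_sd") <- if (nrow(out) > 1) stats::sd(out$peak_rate) else 0
  out
}

## 8-connected component labelling via igraph.
label_components_2d <- function(above) {
  lab <- matrix(0L, nrow(above), ncol(above))
  px <- which(above)
  if (length(px) == 0) return(lab)
  nr <- nrow(above)
  id_of <- integer(length(above)); id_of[px] <- seq_along(px)
  edges <- integer(0)
  w <- which(above, arr.ind = TRUE)
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    ni <- w[, 1] + off[1]; nj <- w[, 2] + off[2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= ncol(above)
    lin_a <- (w[ok, 2] - 1L) * nr + w[ok, 1]
    lin_b <- (nj[ok] - 1L) * nr + ni[ok]
    okb <- above[lin_b]
    edges <- c(edges, rbind(id_of[lin_a[okb]], id_of[lin_b[okb]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(px), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[px] <- as.integer(comp)
  lab
}

#' Spatial phase offset between two simultaneously recorded cells
#'
#' Arena: the 2D spatial cross-correlogram of the two rate maps is computed
#' and the offset of the cross-correlogram peak nearest the origin is
#' returned. Track: the cross-correlation of the two path-integrated
#' profiles is computed over lags and the lag of the first peak is the
#' phase offset.
#'
#' @param a,b Two `gt_ratemap`s (arena) or two `gt_linear_profile`s
#'   (track).
#' @param max_lag Maximum lag searched (cm).
#' @return Arena: tibble `dx`, `dy`, `offset`, `r`. Track: tibble
#'   `offset`, `r`.
#' @export
pair_phase_offset <- function(a, b, max_lag = NULL) {
  if (inherits(a, "gt_ratemap") && inherits(b, "gt_ratemap")) {
    mx <- masked_pearson_xcorr(a$rate, b$rate)
    nl <- nrow(mx$r)
    lag <- (seq_len(nl) - length(a$x)) * a$bin
    ## local maxima of the cross-correlogram; nearest the origin wins
    pk <- acorr_peaks(structure(list(r = mx$r, lag_x = lag, lag_y = lag,
                                     bin = a$bin), class = "gt_acorr2d"),
                      min_r = -1, central_thr = Inf)
    if (nrow(pk) == 0) stop("no cross-correlogram peak found")
    best <- pk[which.min(pk$dist), ]
    return(tibble::tibble(dx = best$x, dy = best$y,
                          offset = best$dist, r = best$r))
  }
  ## 1D: cross-correlation of the two profiles on a common grid
  ta <- tibble::as_tibble(a); tb <- tibble::as_tibble(b)
  both <- dplyr::inner_join(ta, tb, by = "bin_mid", suffix = c("_a", "_b"))
  both <- dplyr::filter(both, .data$occupancy_a > 0, .data$occupancy_b > 0)
  if (nrow(both) < 10) stop("empty overlap between the two profiles")
  binw <- attr(a, "bin")
  if (is.null(max_lag)) max_lag <- (nrow(both) - 5) * binw / 2
  L <- floor(max_lag / binw)
  va <- both$rate_a; vb <- both$rate_b
  lags <- -L:L
  rr <- vapply(lags, function(l) {
    if (l >= 0) {
      xx <- va[1:(length(va) - l)]; yy <- vb[(1 + l):length(vb)]
    } else {
      xx <- va[(1 - l):length(va)]; yy <- vb[1:(length(vb) + l)]
    }
    if (length(xx) < 5 || stats::sd(xx) < 1e-12 || stats::sd(yy) < 1e-12) {
      return(NA_real_)
    }
    cor(xx, yy)
  }, numeric(1))
  pk_idx <- local_maxima(rr)
  if (length(pk_idx) == 0) pk_idx <- which.max(rr)
  best_val <- max(rr[pk_idx], na.rm = TRUE)
  cand <- pk_idx[rr[pk_idx] >= best_val - 1e-9]
  best <- cand[which.min(abs(lags[cand]))]
  tibble::tibble(offset = lags[best] * binw, r = rr[best])
}
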