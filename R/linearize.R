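#' Unwrap the track trajectory into cumulative angular distance
#'
#' Converts a track trajectory into per-sample signed and absolute cumulative
#' distances. The angular position of each sample is unwrapped and converted
#' to distance with a fixed reference radius `r_ref` (the outer wall radius,
#' 75 cm for the large track, so one full lap is `2*pi*75 = 471.24` cm).
#' Clockwise motion (decreasing counter-clockwise angle) counts positive:
#' the per-sample signed increment is `-r_ref * dtheta`. The absolute series
#' accumulates `|increments|` (the travelled-distance coordinate).
#'
#' Each sample also receives a lap index (`floor(signed / C)`, see
#' [segment_laps()]) and a direction label `"CW"`, `"CCW"` or `"still"`:
#' the signed increment rate smoothed over `still_window` s is compared with
#' `still_speed` cm/s.
#'
#' @param traj A track `gt_trajectory` (any tibble with `t, x1, y1`).
#' @param center Enclosure centre, cm 2-vector.
#' @param r_ref Reference radius in cm; defaults to the trajectory's outer
#'   radius, else 75.
#' @param still_window Smoothing window for the direction label, s.
#' @param still_speed Speed below which a sample is labelled `"still"`, cm/s.
#' @return A `gt_distance_series` tibble: `t`, `theta` (unwrapped angle,
#'   rad), `signed`, `absolute` (cm), `lap`, `direction`; attributes
#'   `r_ref` and `circumference`.
#' @export
unwrap_cumulative_angle <- function(traj, center = c(0, 0),
                                    r_ref = NULL,
                                    still_window = 0.5, still_speed = 0.5) {
  if (is.null(r_ref)) {
    r_ref <- attr(traj, "radius_outer")
    if (is.null(r_ref) || !is.finite(r_ref)) r_ref <- 75
  }
  x <- traj$x1 - center[1]; y <- traj$y1 - center[2]
  rr <- sqrt(x^2 + y^2)
  if (any(rr < 1e-9)) stop("sample at the enclosure centre: angle undefined")
  th_raw <- atan2(y, x)
  dth <- wrap_pi(diff(th_raw))
  theta <- th_raw[1] + c(0, cumsum(dth))
  inc <- -r_ref * c(0, dth)                 # clockwise positive
  signed <- cumsum(inc)
  absolute <- cumsum(abs(inc))
  C <- track_circumference(r_ref)
  lap <- floor(signed / C)

  dt <- traj$t[2] - traj$t[1]
  w <- max(1L, round(still_window / dt))
  sm_rate <- roll_mean(inc / dt, w)
  direction <- ifelse(abs(sm_rate) < still_speed, "still",
                      ifelse(sm_rate > 0, "CW", "CCW"))

  out <- tibble::tibble(t = traj$t, theta = theta, signed = signed,
                        absolute = absolute, lap = lap,
                        direction = direction)
  structure(out, class = c("gt_distance_series", class(out)),
            r_ref = r_ref, circumference = C)
}

#' Lap segmentation of a cumulative-distance series
#'
#' Laps are dissociated where the signed cumulative distance crosses a
#' multiple of the circumference `C`: the lap index of a sample is
#' `floor(signed / C)` (negative for net counter-clockwise travel).
#'
#' @param series A `gt_distance_series` (or any tibble with a `signed`
#'   column).
#' @param C Circumference, cm; defaults to the series' own.
#' @return A tibble with one row per lap segment: `lap`, `start_index`,
#'   `end_index`, `start_t`, `end_t`, `n_samples`.
#' @export
segment_laps <- function(series, C = attr(series, "circumference")) {
  if (is.null(C)) C <- track_circumference(75)
  if (C <= 0) stop("C must be > 0")
  lap <- floor(series$signed / C)
  r <- rle(lap)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tibble::tibble(lap = r$values,
                 start_index = starts, end_index = ends,
                 start_t = series$t[starts], end_t = series$t[ends],
                 n_samples = r$lengths)
}

## Coordinate of each spike in a given frame by linear interpolation of the
## per-sample frame coordinate at the spike time.
spike_coordinate <- function(spikes, t, coord) {
  if (length(spikes) == 0L) return(numeric(0))
  approx(t, coord, xout = spikes, rule = 2)$y
}

#' Linearize spiking activity into one of the three 1D reference frames
#'
#' Bins firing along the path-integrated distance (signed cumulative cm),
#' travelled distance (absolute cumulative cm) or elapsed time (s). Each
#' spike is assigned the frame coordinate at its time by linear
#' interpolation; occupancy is the tracking time spent per bin; rate is
#' count/occupancy on occupied bins. Default bin widths are 10 cm for the
#' distance frames and 1 s for time.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series` from [unwrap_cumulative_angle()].
#' @param frame `"path_integrated"`, `"travelled"` or `"time"`.
#' @param bin Bin width (cm or s); default 10 cm / 1 s.
#' @param restrict Optional logical vector (one per tracking sample)
#'   restricting both occupancy and spikes to a subset of the session.
#' @return A `gt_linear_profile` tibble: `bin_mid`, `count`, `occupancy`
#'   (s), `rate` (Hz; `NA` on unoccupied bins); attributes `frame`, `bin`.
#' @export
linearize_activity <- function(spikes, series,
                               frame = c("path_integrated", "travelled", "time"),
                               bin = NULL, restrict = NULL) {
  frame <- match.arg(frame)
  if (is.null(bin)) bin <- if (frame == "time") 1 else 10
  coord <- switch(frame,
                  path_integrated = series$signed,
                  travelled = series$absolute,
                  time = series$t)
  dt <- series$t[2] - series$t[1]
  keep <- if (is.null(restrict)) rep(TRUE, length(coord)) else restrict
  csub <- coord[keep]
  if (length(csub) == 0L) stop("restriction leaves no tracking samples")
  edges <- seq(floor(min(coord) / bin) * bin,
               ceiling((max(coord) + 1e-9) / bin) * bin, by = bin)
  if (length(edges) < 2) edges <- c(edges, edges + bin)
  nb <- length(edges) - 1L
  occ_idx <- pmin(pmax(findInterval(csub, edges), 1L), nb)
  occupancy <- as.numeric(tabulate(occ_idx, nbins = nb)) * dt

  sc <- spike_coordinate(spikes, series$t, coord)
  if (!is.null(restrict) && length(spikes) > 0L) {
    ok <- approx(series$t, as.numeric(keep), xout = spikes, rule = 2)$y > 0.5
    sc <- sc[ok]
  }
  cnt_idx <- pmin(pmax(findInterval(sc, edges), 1L), nb)
  count <- as.numeric(tabulate(cnt_idx, nbins = nb))

  rate <- ifelse(occupancy > 0, count / occupancy, NA_real_)
  out <- tibble::tibble(bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                        count = count, occupancy = occupancy, rate = rate)
  structure(out, class = c("gt_linear_profile", class(out)),
            frame = frame, bin = bin)
}

#' Lap-by-position firing-rate matrix
#'
#' Builds the laps x track-position rate matrix underlying the allocentric
#' versus path-integrated comparison. Position within a lap is the signed
#' cumulative distance modulo `C`; the circle is tiled by `nbins` equal bins
#' (47 bins of `C/47 ~ 10.03` cm by default so the bins tile exactly). A
#' lap is the region of the cumulative-distance axis between consecutive
#' multiples of `C` (lap index `floor(signed / C)`): every sample with the
#' same lap index contributes to that lap's row, however many times the
#' animal re-enters it. Rows are ordered by first visit; bins never visited
#' in a lap are `NA`.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param C Circumference, cm.
#' @param nbins Number of position bins.
#' @param min_occupancy_s Minimum total occupancy (s) for a lap row to be
#'   retained.
#' @param min_coverage_bins Minimum number of occupied position bins for a
#'   lap row to be retained (brief dips across a lap boundary are not
#'   usable laps).
#' @return A `gt_lap_matrix`: numeric matrix laps x bins with attributes
#'   `occupancy` (same shape), `lap_ids`, `C`, `bin` and `lap_direction`
#'   (+1 net clockwise, -1 net counter-clockwise per lap row).
#' @export
lap_position_matrix <- function(spikes, series, C = attr(series, "circumference"),
                                nbins = 47, min_occupancy_s = 2,
                                min_coverage_bins = 10) {
  if (is.null(C)) C <- track_circumference(75)
  dt <- series$t[2] - series$t[1]
  binw <- C / nbins
  pos <- ((series$signed %% C) + C) %% C
  pos_bin <- pmin(floor(pos / binw) + 1L, nbins)
  spike_pos <- spike_coordinate(spikes, series$t, series$signed)
  sp_posbin <- pmin(floor((((spike_pos %% C) + C) %% C) / binw) + 1L, nbins)

  sample_lap <- floor(series$signed / C)
  lap_vals <- unique(sample_lap[order(series$t)])
  spike_t_lap <- floor(spike_pos / C)
  rows <- list(); occs <- list(); ids <- integer(0); dirs <- numeric(0)
  t0 <- numeric(0); t1 <- numeric(0)
  for (lv in lap_vals) {
    sel <- which(sample_lap == lv)
    occ <- as.numeric(tabulate(pos_bin[sel], nbins = nbins)) * dt
    if (sum(occ) < min_occupancy_s || sum(occ > 0) < min_coverage_bins) next
    in_lap <- length(spikes) > 0 & spike_t_lap == lv
    cnt <- as.numeric(tabulate(sp_posbin[in_lap], nbins = nbins))
    rows[[length(rows) + 1L]] <- ifelse(occ > 0, cnt / occ, NA_real_)
    occs[[length(occs) + 1L]] <- occ
    ids <- c(ids, lv)
    t0 <- c(t0, series$t[sel[1]]); t1 <- c(t1, series$t[sel[length(sel)]])
    net <- series$signed[sel[length(sel)]] - series$signed[sel[1]]
    dirs <- c(dirs, ifelse(net >= 0, 1, -1))
  }
  if (length(rows) < 2) {
    stop("fewer than 2 laps with sufficient occupancy")
  }
  m <- do.call(rbind, rows)
  structure(m, class = c("gt_lap_matrix", class(m)),
            occupancy = do.call(rbind, occs),
            lap_ids = ids, C = C, bin = binw, lap_direction = dirs,
            lap_windows = cbind(start_t = t0, end_t = t1))
}

#' Clockwise/counter-clockwise split of the path-integrated profile
#'
#' Restricts the path-integrated linearization to samples labelled CW or CCW
#' and correlates the two rate profiles over mutually occupied bins.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param bin Bin width, cm.
#' @param min_bins Minimum mutually occupied bins required.
#' @return A list with `cw`, `ccw` (two `gt_linear_profile`s) and `r`
#'   (Pearson correlation over mutually occupied bins).
#' @export
directional_split <- function(spikes, series, bin = 10, min_bins = 10) {
  cw_keep <- series$direction == "CW"
  ccw_keep <- series$direction == "CCW"
  if (!any(cw_keep) || !any(ccw_keep)) {
    stop("one running direction has no samples")
  }
  ## shared bin grid: linearize on the full series, then restrict
  cw <- linearize_activity(spikes, series, "path_integrated", bin,
                           restrict = cw_keep)
  ccw <- linearize_activity(spikes, series, "path_integrated", bin,
                            restrict = ccw_keep)
  both <- dplyr::inner_join(
    dplyr::filter(tibble::as_tibble(cw), .data$occupancy > 0),
    dplyr::filter(tibble::as_tibble(ccw), .data$occupancy > 0),
    by = "bin_mid", suffix = c("_cw", "_ccw")
  )
  if (nrow(both) < min_bins) {
    stop("fewer than ", min_bins, " mutually occupied bins")
  }
  r <- suppressWarnings(cor(both$rate_cw, both$rate_ccw))
  list(cw = cw, ccw = ccw, r = r, n_bins = nrow(both))
}
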