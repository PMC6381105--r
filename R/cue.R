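## Cue-card visibility geometry on the circular track and the analyses
## that depend on it: region-wise firing stability, field density and
## light/dark comparisons.

#' Track geometry for cue-visibility analysis
#'
#' @param radius_outer Outer wall radius, cm.
#' @param track_width Track width, cm.
#' @param card_angle Angular position of the cue-card centre, deg.
#' @param card_width Card width, cm (arc length on the outer wall).
#' @return A `gt_track_geometry` list with derived `radius_inner` and
#'   `radius_mid`.
#' @export
track_geometry <- function(radius_outer = 75, track_width = 15,
                           card_angle = 0, card_width = 30) {
  if (radius_outer <= 0 || track_width <= 0 || track_width >= radius_outer) {
    stop("invalid geometry: need 0 < track_width < radius_outer")
  }
  if (card_width >= 2 * pi * radius_outer) {
    stop("cue card wider than the outer circumference")
  }
  structure(list(radius_outer = radius_outer,
                 radius_inner = radius_outer - track_width,
                 radius_mid = radius_outer - track_width / 2,
                 card_angle = wrap_deg(card_angle),
                 card_width = card_width),
            class = "gt_track_geometry")
}

## Does the segment from P (on the mid circle) to Q (on the outer wall)
## avoid the inner disk of radius r_in?
segment_clears_inner <- function(px, py, qx, qy, r_in) {
  dx <- qx - px; dy <- qy - py
  tt <- -(px * dx + py * dy) / (dx^2 + dy^2)
  tt <- pmin(pmax(tt, 0), 1)
  cx <- px + tt * dx; cy <- py + tt * dy
  (cx^2 + cy^2) >= r_in^2 - 1e-9
}

#' Arc of the track from which the cue card is visible
#'
#' A mid-track position sees the card when a straight sight line to at
#' least one point of the card (on the outer wall) does not cross the
#' inner wall. Solved analytically by the tangent construction: the
#' tangent from a card border to the inner circle, intercepted with the
#' mid-track circle, bounds the visible region at
#' `acos(r_in / r_mid) + acos(r_in / r_out)` beyond the card border. A
#' ray-casting verification is available via `method = "raycast"`.
#'
#' @param geom A [track_geometry()].
#' @param method `"analytic"` (tangent construction) or `"raycast"`
#'   (numeric check on a 1 degree x 1 cm sampling).
#' @return A list: `arc` (c(start, end), deg, counter-clockwise interval
#'   containing the card), `extent` (deg), `center` (deg).
#' @export
visible_arc <- function(geom, method = c("analytic", "raycast")) {
  method <- match.arg(method)
  r_in <- geom$radius_inner; r_mid <- geom$radius_mid
  r_out <- geom$radius_outer
  half_card <- (geom$card_width / 2) / r_out * 180 / pi
  if (method == "analytic") {
    if (r_in <= 0) {
      ext <- 360
    } else {
      beyond <- (acos(pmin(r_in / r_mid, 1)) +
                   acos(pmin(r_in / r_out, 1))) * 180 / pi
      ext <- min(2 * (half_card + beyond), 360)
    }
  } else {
    ## sample mid-track angles at 1 deg, card points at ~1 cm
    ang <- seq(0, 359, by = 1)
    rel <- ang - geom$card_angle
    card_ang <- geom$card_angle +
      seq(-half_card, half_card, length.out = max(ceiling(geom$card_width), 2))
    qx <- r_out * cos(card_ang * pi / 180)
    qy <- r_out * sin(card_ang * pi / 180)
    vis <- vapply(ang, function(a) {
      px <- r_mid * cos(a * pi / 180); py <- r_mid * sin(a * pi / 180)
      any(segment_clears_inner(px, py, qx, qy, r_in))
    }, logical(1))
    ext <- sum(vis)
  }
  list(arc = c(wrap_deg(geom$card_angle - ext / 2),
               wrap_deg(geom$card_angle + ext / 2)),
       extent = ext, center = geom$card_angle)
}

#' Equal-area partition of the track into cue-visible and non-visible
#' regions
#'
#' The visible region is centred on the card with the visible-arc extent;
#' the non-visible region is diametrically opposite with the same extent;
#' both are trimmed to the smaller of the two so their areas match, and
#' the remaining ambiguous buffer is excluded.
#'
#' @param geom A [track_geometry()].
#' @param ... Passed to [visible_arc()].
#' @return A `gt_region_partition` list: `visible`, `non_visible`
#'   (centre/extent pairs, deg), `buffer_extent` (deg).
#' @export
region_partition <- function(geom, ...) {
  va <- visible_arc(geom, ...)
  ext <- min(va$extent, 360 - va$extent)
  structure(list(visible = list(center = va$center, extent = ext),
                 non_visible = list(center = wrap_deg(va$center + 180),
                                    extent = ext),
                 buffer_extent = 360 - 2 * ext),
            class = "gt_region_partition")
}

## Membership of track angles (deg) in a centre/extent region.
in_region <- function(angle_deg, region) {
  abs(circ_diff_deg(angle_deg, region$center)) <= region$extent / 2
}

## Track angle (deg, position convention: signed cumulative distance mod C
## mapped to 360 deg clockwise from the unwrap origin) of a series sample.
## For region analyses we use the geometric angle of the tracked position.
sample_track_angle <- function(traj) {
  wrap_deg(atan2(traj$y1, traj$x1) * 180 / pi)
}

#' Region-wise firing stability
#'
#' Autocorrelation of the path-integrated firing profile restricted to
#' each region of the partition; the correlation value at the first peak
#' measures firing stability in that region.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param traj The trajectory (for the geometric angle of each sample).
#' @param partition A [region_partition()].
#' @return A tibble: `region`, `first_peak_r`, `first_peak_lag`,
#'   `n_bins`.
#' @export
region_stability <- function(spikes, series, traj, partition) {
  ang <- sample_track_angle(traj)
  out <- purrr::map_dfr(c("visible", "non_visible"), function(rg) {
    keep <- in_region(ang, partition[[rg]])
    res <- tryCatch({
      prof <- linearize_activity(spikes, series, "path_integrated",
                                 restrict = keep)
      ac <- autocorrelation_1d(prof)
      pv <- attr(ac, "peak_values")
      tibble::tibble(region = rg,
                     first_peak_r = if (length(pv) >= 1) pv[1] else NA_real_,
                     first_peak_lag = attr(ac, "first_peak_lag"),
                     n_bins = sum(prof$occupancy > 0))
    }, error = function(e) {
      tibble::tibble(region = rg, first_peak_r = NA_real_,
                     first_peak_lag = NA_real_, n_bins = NA_integer_)
    })
    res
  })
  out
}

#' Field density by cue region
#'
#' Counts firing fields (from the path-integrated profile, 2.5 cm pixels,
#' at least five contiguous above 30 percent of peak) whose angular
#' centroid falls in the visible or non-visible region, and tests the
#' counts against a 50:50 split with a chi-square test (1 df).
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param partition A [region_partition()].
#' @param unwrap_origin_deg Track angle (deg) of the sample where the
#'   signed cumulative distance is zero; used to map profile coordinates
#'   back to track angles.
#' @param fields Optional precomputed field tibble with a `coord` column
#'   (cm, path-integrated axis).
#' @return A tibble: `n_visible`, `n_non_visible`, `n_buffer`,
#'   `chi_square`, `p_value`.
#' @export
field_density_by_region <- function(spikes, series, partition,
                                    unwrap_origin_deg = NULL,
                                    fields = NULL) {
  C <- attr(series, "circumference")
  if (is.null(C)) C <- track_circumference(75)
  if (is.null(fields)) {
    prof <- linearize_activity(spikes, series, "path_integrated", bin = 2.5)
    fields <- detect_fields(prof)
  }
  if (nrow(fields) == 0) stop("no firing fields detected")
  if (is.null(unwrap_origin_deg)) unwrap_origin_deg <- series$theta[1] * 180 / pi
  ## signed cumulative distance is clockwise-positive from the origin angle
  ang <- wrap_deg(unwrap_origin_deg - (fields$coord %% C) / C * 360)
  nv <- sum(in_region(ang, partition$visible))
  nn <- sum(in_region(ang, partition$non_visible))
  nb <- nrow(fields) - nv - nn
  chi <- chisq_5050(nv, nn)
  tibble::tibble(n_visible = nv, n_non_visible = nn, n_buffer = nb,
                 chi_square = chi$statistic, p_value = chi$p_value)
}

## Chi-square against a 50:50 split, 1 df, no continuity correction.
chisq_5050 <- function(a, b) {
  n <- a + b
  if (n == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  e <- n / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Light-dark-light stability comparison
#'
#' Correlates the path-integrated firing profiles of the same cell across
#' a light-dark-light session triplet: `r_light_light` between the two
#' light sessions and `r_light_dark` between the first light and the dark
#' session, over mutually occupied bins.
#'
#' @param prof_light1,prof_dark,prof_light2 `gt_linear_profile`s of the
#'   three sessions (path-integrated frame, same bin width).
#' @return A tibble: `r_light_light`, `r_light_dark`, `z_light_light`,
#'   `z_light_dark`.
#' @export
light_dark_comparison <- function(prof_light1, prof_dark, prof_light2) {
  r_ll <- profile_correlation(prof_light1, prof_light2)
  r_ld <- profile_correlation(prof_light1, prof_dark)
  tibble::tibble(r_light_light = r_ll, r_light_dark = r_ld,
                 z_light_light = fisher_z(r_ll), z_light_dark = fisher_z(r_ld))
}

## Pearson correlation of two linear profiles over mutually occupied bins,
## aligned on position within the lap (coordinate modulo C) so that
## sessions with different starting positions are comparable.
profile_correlation <- function(a, b, C = track_circumference(75)) {
  binw <- attr(a, "bin")
  fold <- function(p) {
    pos <- ((p$bin_mid %% C) + C) %% C
    idx <- floor(pos / binw) + 1L
    nb <- ceiling(C / binw)
    num <- tapply(p$count, factor(idx, levels = seq_len(nb)), sum)
    den <- tapply(p$occupancy, factor(idx, levels = seq_len(nb)), sum)
    num <- ifelse(is.na(num), 0, num); den <- ifelse(is.na(den), 0, den)
    ifelse(den > 0, num / den, NA_real_)
  }
  va <- fold(a); vb <- fold(b)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 5) stop("fewer than 5 mutually occupied bins")
  suppressWarnings(cor(va[ok], vb[ok]))
}
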