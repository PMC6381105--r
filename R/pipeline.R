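## Study-level orchestration: per-session analysis, the synthetic
## simulation study validating the classifier, scale comparison and
## within-session stability.

#' Analyse every unit of a session
#'
#' Runs the full per-cell pipeline appropriate to the enclosure. Track
#' sessions: linearization in the three frames, jitter nulls and coding
#' classification, field distance, optional model fits and slice test,
#' cue-region stability; arena sessions: rate map, autocorrelogram,
#' gridness, field spacing and fields. Intrinsic theta is computed for
#' every unit, LFP theta once per session when an LFP is present. Partial
#' failures are recorded per cell (`error_*` columns), never abort the
#' session.
#'
#' @param session A `gt_session`.
#' @param seed Integer seed for all stochastic steps.
#' @param n_jitter Jitter permutations per frame for the per-cell nulls.
#' @param include_fit Fit the Gaussian spike-train model in all three
#'   frames (slower).
#' @param include_slice Run the spectral slice test (track sessions with
#'   lattice ground truth or `lattice` supplied).
#' @param lattice Optional lattice parameters for the slice test.
#' @return A `gt_session_report` list: `cells` (one row per unit),
#'   `theta` (LFP theta or `NULL`), `seed`.
#' @export
run_session_analysis <- function(session, seed = 1L, n_jitter = 100,
                                 include_fit = FALSE, include_slice = FALSE,
                                 lattice = NULL) {
  stopifnot(inherits(session, "gt_session"))
  traj <- session$trajectory
  on_track <- identical(attr(traj, "enclosure"), "track")
  series <- if (on_track) unwrap_cumulative_angle(traj) else NULL
  theta <- NULL
  if (!is.null(session$lfp)) {
    theta <- tryCatch(lfp_theta(session$lfp, traj), error = function(e) NULL)
  }
  rows <- purrr::imap(session$spikes, function(sp, u) {
    base <- tibble::tibble(unit = u, n_spikes = length(sp),
                           mean_rate = length(sp) / traj_duration(traj))
    extra <- tryCatch({
      if (on_track) {
        analyse_track_unit(sp, series, traj, derive_seed(seed, u), n_jitter,
                           include_fit, include_slice, lattice)
      } else {
        analyse_arena_unit(sp, traj)
      }
    }, error = function(e) tibble::tibble(error = conditionMessage(e)))
    it <- tryCatch(intrinsic_theta(sp), error = function(e) NULL)
    extra$intrinsic_theta_hz <- if (is.null(it)) NA_real_ else it$frequency
    dplyr::bind_cols(base, extra)
  })
  structure(list(cells = dplyr::bind_rows(rows), theta = theta,
                 seed = as.integer(seed)),
            class = "gt_session_report")
}

analyse_track_unit <- function(sp, series, traj, seed, n_jitter,
                               include_fit, include_slice, lattice) {
  thr <- purrr::map(c(path_integrated = "path_integrated",
                      travelled = "travelled", time = "time"),
                    function(fr) {
                      tryCatch(jitter_null(sp, series, fr, n = n_jitter,
                                           seed = seed)$threshold,
                               error = function(e) NA_real_)
                    })
  cls <- classify_cell(sp, series, thr, seed = seed)
  out <- dplyr::select(cls, -"n_spikes")
  if (include_fit) {
    fits <- purrr::map(c("path_integrated", "travelled", "time"),
                       function(fr) {
                         tryCatch(fit_cell(sp, series, fr, seed = seed),
                                  error = function(e) NULL)
                       })
    out$fit_spacing <- if (!is.null(fits[[1]])) fits[[1]]$params$spacing else NA_real_
    out$ssd_path_integrated <- if (!is.null(fits[[1]])) fits[[1]]$ssd else NA_real_
    out$ssd_travelled <- if (!is.null(fits[[2]])) fits[[2]]$ssd else NA_real_
    out$ssd_time <- if (!is.null(fits[[3]])) fits[[3]]$ssd else NA_real_
  }
  if (include_slice && !is.null(lattice)) {
    st <- tryCatch(slice_test(sp, series, traj, lattice, seed = seed),
                   error = function(e) NULL)
    out$one_peakness <- if (!is.null(st)) st$score else NA_real_
    out$rejects_slice <- if (!is.null(st)) st$rejects_slice else NA
  }
  geom <- tryCatch(track_geometry(attr(traj, "radius_outer"),
                                  attr(traj, "track_width")),
                   error = function(e) NULL)
  if (!is.null(geom)) {
    part <- region_partition(geom)
    rs <- tryCatch(region_stability(sp, series, traj, part),
                   error = function(e) NULL)
    if (!is.null(rs)) {
      out$r_visible <- rs$first_peak_r[rs$region == "visible"]
      out$r_non_visible <- rs$first_peak_r[rs$region == "non_visible"]
    }
  }
  out
}

analyse_arena_unit <- function(sp, traj) {
  m <- compute_rate_map(traj, sp)
  a <- spatial_autocorrelogram(m)
  g <- gridness(a)
  flds <- detect_fields(m)
  tibble::tibble(gridness = g$score,
                 spacing_2d = field_spacing_2d(a),
                 n_fields = nrow(flds),
                 peak_rate = m$peak_rate,
                 field_peak_sd = attr(flds, "peak_rate_sd"))
}

## One synthetic study cell of a given generative class. Allocentric cells
## get an irregular anchored field layout (the track layouts of real
## allocentric grid cells are irregular; a regular allocentric layout is
## also periodic in signed distance and therefore genuinely ambiguous with
## path-integrated coding).
study_ground_truth <- function(class, spacing_cm = 150, time_spacing_s = 15,
                               peak_rate = 8, seed = 1L) {
  switch(class,
    allocentric = ground_truth(
      "allocentric", spacing = spacing_cm, peak_rate = peak_rate,
      field_positions = with_seed(seed, irregular_positions(3, 60))),
    path_integrated = ground_truth("path_integrated", spacing = spacing_cm,
                                   peak_rate = peak_rate),
    travelled = ground_truth("travelled", spacing = spacing_cm,
                             peak_rate = peak_rate),
    time = ground_truth("time", spacing = time_spacing_s, field_width = 1.5,
                        peak_rate = peak_rate),
    none = ground_truth("none", peak_rate = peak_rate),
    stop("unknown class: ", class))
}

## n field centres on the circle with minimum circular separation (cm).
irregular_positions <- function(n, min_sep, C = track_circumference(75)) {
  for (try in 1:100) {
    pos <- sort(runif(n, 0, C))
    gaps <- diff(c(pos, pos[1] + C))
    if (min(gaps) >= min_sep) return(pos)
  }
  pos
}

#' Simulation study of the coding-scheme classifier
#'
#' Generates `n_per_class` synthetic cells per generative class under
#' published-summary track behaviour (600 s sessions by default), pools
#' jitter-null statistics across all cells per frame to set the three
#' thresholds (99th percentile), classifies every cell, and tabulates the
#' confusion between generative class and assigned flags/labels.
#'
#' @param classes Generative classes to simulate.
#' @param n_per_class Cells per class.
#' @param duration Session duration, s.
#' @param spacing_cm Field distance of the distance-frame classes, cm.
#' @param time_spacing_s Field period of the time class, s.
#' @param n_jitter_per_cell Jitter permutations per cell per frame (pooled
#'   across the batch).
#' @param n_alloc_perm Permutations of the per-cell allocentric test.
#' @param seed Integer seed.
#' @return A `gt_study` list: `cells` (tibble with truth and
#'   classification), `thresholds`, `confusion` (truth x label table),
#'   `flag_rates` (per class fraction flagged per frame), `seed`.
#' @export
run_simulation_study <- function(classes = c("allocentric", "path_integrated",
                                             "travelled", "time"),
                                 n_per_class = 50, duration = 600,
                                 spacing_cm = 150, time_spacing_s = 15,
                                 n_jitter_per_cell = 50, n_alloc_perm = 1000,
                                 seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  grid <- expand.grid(class = classes, rep = seq_len(n_per_class),
                      stringsAsFactors = FALSE)
  n_cells <- nrow(grid)

  ## generate all cells
  cells <- purrr::map(seq_len(n_cells), function(i) {
    cl <- grid$class[i]
    s_traj <- derive_seed(seed, 2L * i)
    s_spk <- derive_seed(seed, 2L * i + 1L)
    traj <- simulate_trajectory(duration = duration, seed = s_traj)
    series <- unwrap_cumulative_angle(traj)
    gt <- study_ground_truth(cl, spacing_cm, time_spacing_s,
                             seed = derive_seed(seed, 5000L + i))
    sp <- generate_track_spikes(traj, gt, seed = s_spk)
    list(class = cl, traj = traj, series = series, spikes = sp,
         seed_traj = s_traj, seed_spikes = s_spk)
  })

  ## pooled jitter null per frame
  frames <- c("path_integrated", "travelled", "time")
  pooled <- purrr::map(frames, function(fr) {
    unlist(purrr::map(seq_along(cells), function(i) {
      ce <- cells[[i]]
      if (length(ce$spikes) < 2) return(numeric(0))
      jn <- tryCatch(jitter_null(ce$spikes, ce$series, fr,
                                 n = n_jitter_per_cell,
                                 seed = derive_seed(seed, 1000L + i)),
                     error = function(e) NULL)
      if (is.null(jn)) numeric(0) else jn$null
    }))
  })
  names(pooled) <- frames
  thresholds <- purrr::map_dbl(pooled, function(x) {
    unname(quantile(x, 0.99, na.rm = TRUE))
  })

  ## classify
  rows <- purrr::map(seq_along(cells), function(i) {
    ce <- cells[[i]]
    cls <- classify_cell(ce$spikes, ce$series, thresholds,
                         n_alloc_perm = n_alloc_perm,
                         seed = derive_seed(seed, 2000L + i))
    dplyr::bind_cols(tibble::tibble(cell = i, true_class = ce$class), cls)
  })
  cells_tb <- dplyr::bind_rows(rows)

  confusion <- table(truth = cells_tb$true_class, label = cells_tb$label)
  flag_rates <- cells_tb |>
    dplyr::group_by(.data$true_class) |>
    dplyr::summarise(
      flagged_path_integrated = mean(.data$flag_path_integrated),
      flagged_travelled = mean(.data$flag_travelled),
      flagged_time = mean(.data$flag_time),
      flagged_allocentric = mean(.data$flag_allocentric),
      mean_allocentric_r = mean(.data$allocentric_r, na.rm = TRUE),
      mean_corrected_r = mean(.data$corrected_r, na.rm = TRUE),
      .groups = "drop")
  structure(list(cells = cells_tb, thresholds = thresholds,
                 confusion = confusion, flag_rates = flag_rates,
                 seed = as.integer(seed)),
            class = "gt_study")
}

#' @export
print.gt_study <- function(x, ...) {
  cat("<gt_study> thresholds:",
      paste(sprintf("%s %.3f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Field-spacing comparison across environments
#'
#' Per-cell spacing ratios between pairs of environments (track spacing
#' from the path-integrated field distance, arena spacing from the 2D
#' autocorrelogram) and Pearson correlations of spacing across
#' environments.
#'
#' @param spacings A data frame with columns `cell`, `environment`,
#'   `spacing` (cm).
#' @param pairs A list of 2-vectors of environment names to compare.
#' @return A tibble, one row per pair: `env_a`, `env_b`, `n`,
#'   `mean_ratio` (a over b), `sd_ratio`, `r`, `p_value`.
#' @export
scale_comparison <- function(spacings,
                             pairs = list(c("large_track", "large_arena"),
                                          c("small_arena", "large_arena"),
                                          c("large_track", "small_track"))) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(spacings),
                             id_cols = "cell",
                             names_from = "environment",
                             values_from = "spacing")
  purrr::map_dfr(pairs, function(p) {
    if (!all(p %in% names(wide))) {
      return(tibble::tibble(env_a = p[1], env_b = p[2], n = 0L,
                            mean_ratio = NA_real_, sd_ratio = NA_real_,
                            r = NA_real_, p_value = NA_real_))
    }
    a <- wide[[p[1]]]; b <- wide[[p[2]]]
    ok <- is.finite(a) & is.finite(b) & b > 0
    n <- sum(ok)
    ratio <- a[ok] / b[ok]
    r <- if (n >= 3) cor(a[ok], b[ok]) else NA_real_
    pv <- if (n >= 3) {
      tval <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
      2 * stats::pt(-abs(tval), n - 2)
    } else NA_real_
    tibble::tibble(env_a = p[1], env_b = p[2], n = n,
                   mean_ratio = mean(ratio), sd_ratio = stats::sd(ratio),
                   r = r, p_value = pv)
  })
}

#' Within-session stability of the path-integrated pattern
#'
#' First autocorrelation peak value of the path-integrated profile
#' computed separately on the two temporal halves of the session.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param min_spikes Minimum spikes per half.
#' @return A tibble: `half`, `first_peak_r`, `first_peak_lag`,
#'   `n_spikes`.
#' @export
session_half_stability <- function(spikes, series, min_spikes = 50) {
  t_mid <- max(series$t) / 2
  purrr::map_dfr(1:2, function(hf) {
    keep <- if (hf == 1) series$t <= t_mid else series$t > t_mid
    sp <- if (hf == 1) spikes[spikes <= t_mid] else spikes[spikes > t_mid]
    if (length(sp) < min_spikes) {
      return(tibble::tibble(half = hf, first_peak_r = NA_real_,
                            first_peak_lag = NA_real_,
                            n_spikes = length(sp)))
    }
    res <- tryCatch({
      prof <- linearize_activity(sp, series, "path_integrated",
                                 restrict = keep)
      ac <- autocorrelation_1d(prof)
      pv <- attr(ac, "peak_values")
      tibble::tibble(half = hf,
                     first_peak_r = if (length(pv)) pv[1] else NA_real_,
                     first_peak_lag = attr(ac, "first_peak_lag"),
                     n_spikes = length(sp))
    }, error = function(e) {
      tibble::tibble(half = hf, first_peak_r = NA_real_,
                     first_peak_lag = NA_real_, n_spikes = length(sp))
    })
    res
  })
}
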