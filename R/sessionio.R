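## Session container and plain-text on-disk formats.
##
## A session directory holds: manifest.yaml (geometry, condition, rates,
## file names), tracking.csv (t,x1,y1,x2,y2; cm; origin at the enclosure
## centre, x rightward, y upward), one ascending-float file per unit
## (seconds, one per line), optionally lfp.csv (t,v) and a ground-truth
## JSON sidecar for synthetic sessions. Numeric precision: positions to
## 0.01 cm, times to 1e-4 s.

#' Assemble a session object
#'
#' @param trajectory A `gt_trajectory`.
#' @param spikes A list of numeric spike-time vectors (one per unit).
#' @param lfp Optional `gt_lfp`.
#' @param condition `"light"` or `"dark"`.
#' @param cue_card List with `angle_deg`, `width_cm`, `present`.
#' @param ground_truth Optional list of `gt_ground_truth` per unit.
#' @return A `gt_session` list.
#' @export
new_session <- function(trajectory, spikes, lfp = NULL,
                        condition = c("light", "dark"),
                        cue_card = list(angle_deg = 0, width_cm = 30,
                                        present = TRUE),
                        ground_truth = NULL) {
  condition <- match.arg(condition)
  if (!is.list(spikes)) spikes <- list(spikes)
  validate_session_parts(trajectory, spikes, lfp)
  structure(list(trajectory = trajectory, spikes = spikes, lfp = lfp,
                 condition = condition, cue_card = cue_card,
                 ground_truth = ground_truth),
            class = "gt_session")
}

validate_session_parts <- function(trajectory, spikes, lfp) {
  tt <- trajectory$t
  if (any(diff(tt) <= 0)) stop("trajectory timestamps not strictly increasing")
  steps <- diff(tt)
  if (max(steps) - min(steps) > 1e-6) {
    stop("trajectory timestamps not uniformly spaced")
  }
  dur <- traj_duration(trajectory)
  for (u in seq_along(spikes)) {
    sp <- spikes[[u]]
    if (length(sp) && (min(sp) < 0 || max(sp) > dur + 1e-9)) {
      bad <- sp[sp < 0 | sp > dur + 1e-9][1]
      stop(sprintf("unit %d: spike at t = %.4f s outside session [0, %.4f]",
                   u, bad, dur))
    }
    if (is.unsorted(sp)) stop(sprintf("unit %d: spike times not ascending", u))
  }
  invisible(TRUE)
}

#' @export
print.gt_session <- function(x, ...) {
  cat(sprintf("<gt_session> %s %s, %.0f s, %d unit(s)%s\n",
              attr(x$trajectory, "enclosure") %||% "?", x$condition,
              traj_duration(x$trajectory), length(x$spikes),
              if (!is.null(x$lfp)) ", LFP" else ""))
  invisible(x)
}

fmt <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

#' Write a session to a directory
#'
#' Writes the plain-text formats described in the package overview and
#' returns the manifest path.
#'
#' @param session A `gt_session`.
#' @param dir Target directory (created if needed).
#' @return Path to the written `manifest.yaml`, invisibly usable by
#'   [load_session()].
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- session$trajectory
  track_df <- data.frame(t = fmt(traj$t, 4),
                         x1 = fmt(traj$x1, 2), y1 = fmt(traj$y1, 2),
                         x2 = fmt(traj$x2, 2), y2 = fmt(traj$y2, 2))
  utils::write.csv(track_df, file.path(dir, "tracking.csv"),
                   row.names = FALSE, quote = FALSE)
  unit_files <- character(length(session$spikes))
  for (u in seq_along(session$spikes)) {
    unit_files[u] <- sprintf("unit_%02d.txt", u)
    writeLines(fmt(session$spikes[[u]], 4), file.path(dir, unit_files[u]))
  }
  lfp_file <- NULL
  if (!is.null(session$lfp)) {
    lfp_file <- "lfp.csv"
    lfp_df <- data.frame(t = fmt(session$lfp$t, 6), v = fmt(session$lfp$v, 5))
    utils::write.csv(lfp_df, file.path(dir, lfp_file),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    enclosure = attr(traj, "enclosure") %||% "track",
    radius_outer_cm = as.numeric(attr(traj, "radius_outer") %||% 75),
    track_width_cm = as.numeric(attr(traj, "track_width") %||% NA),
    condition = session$condition,
    cue_card = session$cue_card,
    sample_rate_hz = as.numeric(traj_sample_rate(traj)),
    lfp_rate_hz = if (!is.null(session$lfp))
      as.numeric(attr(session$lfp, "sample_rate")) else NULL,
    tracking_file = "tracking.csv",
    unit_files = as.list(unit_files),
    lfp_file = lfp_file)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(session$ground_truth)) {
    gt_plain <- lapply(session$ground_truth, function(g) unclass(g))
    jsonlite::write_json(gt_plain, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  file.path(dir, "manifest.yaml")
}

#' Load and validate a session from a manifest
#'
#' Reads the manifest and every referenced file, rebuilds the session
#' object and validates it (files exist, timestamps strictly increasing
#' and uniform, spikes inside the session); errors name the offending
#' record.
#'
#' @param manifest_path Path to `manifest.yaml`.
#' @return A `gt_session`.
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  m <- yaml::read_yaml(manifest_path)
  req <- c(m$tracking_file, unlist(m$unit_files), m$lfp_file)
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing)) stop("missing session file(s): ",
                            paste(missing, collapse = ", "))
  if (!is.numeric(m$radius_outer_cm) || m$radius_outer_cm <= 0) {
    stop("manifest: radius_outer_cm must be positive")
  }
  tr <- utils::read.csv(file.path(dir, m$tracking_file))
  traj <- tibble::as_tibble(tr)
  traj <- structure(traj, class = c("gt_trajectory", class(traj)),
                    enclosure = m$enclosure,
                    radius_outer = m$radius_outer_cm,
                    track_width = m$track_width_cm %||% NA_real_,
                    sample_rate = m$sample_rate_hz)
  spikes <- lapply(file.path(dir, unlist(m$unit_files)), function(f) {
    x <- scan(f, what = numeric(), quiet = TRUE)
    if (length(x) == 0) numeric(0) else x
  })
  lfp <- NULL
  if (!is.null(m$lfp_file)) {
    ld <- utils::read.csv(file.path(dir, m$lfp_file))
    lfp <- tibble::as_tibble(ld)
    lfp <- structure(lfp, class = c("gt_lfp", class(lfp)),
                     sample_rate = m$lfp_rate_hz)
  }
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    gt <- lapply(gt, function(g) {
      g <- lapply(g, function(x) if (is.list(x)) unlist(x) else x)
      g
    })
  }
  new_session(traj, spikes, lfp, condition = m$condition,
              cue_card = m$cue_card, ground_truth = gt)
}

#' Validate a session directory
#'
#' Loads the session, reporting success or the validation failure.
#'
#' @param manifest_path Path to `manifest.yaml`.
#' @return `TRUE` invisibly on success; errors otherwise.
#' @export
validate_session <- function(manifest_path) {
  s <- load_session(manifest_path)
  invisible(TRUE)
}
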