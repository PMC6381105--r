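## Generative model comparison: a three-parameter Gaussian spike-train
## model (field width, first-field offset, inter-field spacing) fitted per
## reference frame by differential evolution, scored by the sum of squared
## differences between Gaussian-smoothed observed and modelled profiles.

#' Parameters of the Gaussian spike-train model
#'
#' @param width Gaussian sd of a spike train (field), cm or s; > 0.
#' @param first_offset Coordinate of the first field, cm or s.
#' @param spacing Distance or time between fields; must exceed `width / 2`.
#' @param frame Reference frame label.
#' @return A `gt_train_params` list.
#' @export
train_model_params <- function(width, first_offset, spacing,
                               frame = "path_integrated") {
  if (width <= 0) stop("width must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  if (spacing <= width / 2) stop("spacing must exceed width / 2")
  structure(list(width = width, first_offset = first_offset,
                 spacing = spacing, frame = frame),
            class = "gt_train_params")
}

#' Predicted smoothed firing profile of the Gaussian spike-train model
#'
#' Spike density along the axis: a sum of Gaussians of sd `width` centred
#' at `first_offset + k * spacing` for every field index k whose field
#' overlaps the axis extent, scaled so the integral over the axis equals
#' the observed spike count (the model re-arranges the recorded spikes, it
#' does not add or remove any). On the signed path-integrated axis the
#' comb extends in both directions, so `first_offset` is identified
#' modulo `spacing`.
#'
#' @param params A `gt_train_params` (or list with `width`,
#'   `first_offset`, `spacing`).
#' @param axis Bin-centre grid covering the session extent (cm or s).
#' @param total_spikes Observed spike count.
#' @param bin Bin width for exact per-bin integration of the comb (pnorm
#'   differences); `NULL` evaluates the density pointwise at `axis`.
#'   Bin integration prevents combs finer than the grid from aliasing
#'   into spurious good fits.
#' @return Numeric density (spikes per axis unit) on `axis`.
#' @export
predict_profile <- function(params, axis, total_spikes, bin = NULL) {
  if (params$spacing <= 0) stop("spacing must be > 0")
  s <- params$spacing; w <- params$width
  d <- (axis - params$first_offset) %% s
  jr <- ceiling((3 * w + (if (is.null(bin)) 0 else bin)) / s) + 1L
  dens <- numeric(length(axis))
  if (is.null(bin)) {
    for (j in (-jr):jr) {
      dens <- dens + stats::dnorm(d - j * s, 0, w)
    }
    norm_bin <- axis[2] - axis[1]
  } else {
    for (j in (-jr):jr) {
      dens <- dens + (stats::pnorm((d + bin / 2 - j * s) / w) -
                        stats::pnorm((d - bin / 2 - j * s) / w)) / bin
    }
    norm_bin <- bin
  }
  tot <- sum(dens) * norm_bin
  if (tot <= 1e-12) return(dens * 0)
  dens * total_spikes / tot
}

#' Observed smoothed spike-density profile on a frame axis
#'
#' The observed counterpart of [predict_profile()]: spike counts binned on
#' the frame axis and smoothed with a fixed Gaussian of sd `smooth` (one
#' 10 cm / 1 s bin by default), expressed as density so that the integral
#' equals the spike count. Only occupied bins are retained for scoring.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param frame Reference frame.
#' @param bin Bin width.
#' @param smooth Gaussian sd of the fixed observation smoothing, axis units.
#' @return A tibble `axis`, `density`, `occupied`, with attributes `frame`,
#'   `bin`, `n_spikes`.
#' @export
observed_profile <- function(spikes, series,
                             frame = c("path_integrated", "travelled", "time"),
                             bin = NULL, smooth = NULL) {
  frame <- match.arg(frame)
  if (is.null(bin)) bin <- if (frame == "time") 1 else 10
  if (is.null(smooth)) smooth <- bin
  lp <- linearize_activity(spikes, series, frame, bin)
  dens <- gauss_smooth(lp$count, smooth / bin) / bin
  out <- tibble::tibble(axis = lp$bin_mid, density = dens,
                        occupied = lp$occupancy > 0)
  structure(out, frame = frame, bin = bin, n_spikes = length(spikes))
}

#' Model fitting score (sum of squared differences)
#'
#' `SSD = sum over occupied bins of (observed - predicted)^2`, where the
#' observed profile comes from [observed_profile()] and the prediction from
#' [predict_profile()] with the same axis and spike count.
#'
#' @param obs An [observed_profile()] tibble.
#' @param params Model parameters.
#' @return Non-negative SSD.
#' @export
fit_score <- function(obs, params) {
  pred <- predict_profile(params, obs$axis, attr(obs, "n_spikes"),
                          bin = attr(obs, "bin"))
  sum((obs$density[obs$occupied] - pred[obs$occupied])^2)
}

#' Differential evolution global optimiser (DE/rand/1/bin)
#'
#' Minimises `objective` over a box. Classic differential evolution:
#' each generation every member x_i is challenged by a trial vector built
#' from three distinct others (a + F (b - c)) with binomial crossover CR;
#' the better of member and trial survives. Deterministic given `seed`.
#'
#' @param objective Function of a numeric vector, returning a scalar.
#' @param lower,upper Bounds (equal length, finite).
#' @param n_pop Population size (default `15 * D`).
#' @param F Differential weight (0.8).
#' @param CR Crossover probability (0.9).
#' @param generations Number of generations (200).
#' @param seed Integer seed.
#' @param tol Early stop when the population objective spread falls below
#'   `tol` (0 disables).
#' @param init Optional matrix of candidate members (rows, clipped to the
#'   bounds) inserted into the initial population — informed
#'   initialization for multimodal objectives.
#' @return A list: `par`, `value`, `generations_run`, `trace` (best value
#'   per generation).
#' @export
differential_evolution <- function(objective, lower, upper,
                                   n_pop = NULL, F = 0.8, CR = 0.9,
                                   generations = 200, seed = 1L,
                                   tol = 1e-10, init = NULL) {
  D <- length(lower)
  if (D == 0 || length(upper) != D) stop("empty or mismatched bounds")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper < lower)) {
    stop("bounds must be finite with upper >= lower")
  }
  if (is.null(n_pop)) n_pop <- 15L * D
  with_seed(seed, {
    pop <- matrix(runif(n_pop * D, rep(lower, each = n_pop),
                        rep(upper, each = n_pop)), n_pop, D)
    if (!is.null(init) && nrow(init) > 0) {
      k <- min(nrow(init), n_pop)
      for (i in seq_len(k)) {
        pop[i, ] <- pmin(pmax(init[i, seq_len(D)], lower), upper)
      }
    }
    fit <- apply(pop, 1, objective)
    trace <- numeric(generations)
    gen_run <- 0L
    for (g in seq_len(generations)) {
      gen_run <- g
      for (i in seq_len(n_pop)) {
        idx <- sample.int(n_pop - 1L, 3L)
        idx <- ifelse(idx >= i, idx + 1L, idx)
        mutant <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- runif(D) < CR
        cross[sample.int(D, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        ft <- objective(trial)
        if (ft <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- ft
        }
      }
      trace[g] <- min(fit)
      if (tol > 0 && (max(fit) - min(fit)) < tol) break
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best],
         generations_run = gen_run, trace = trace[seq_len(gen_run)])
  })
}

#' Fit the Gaussian spike-train model to one cell in one frame
#'
#' Minimises the SSD over (width, first offset, spacing) with differential
#' evolution. Bounds: width in `[0.25, 3]` bins-equivalent scale of the
#' frame (2.5-30 cm or 0.25-3 s), offset within the axis extent, spacing
#' from one bin to half the extent.
#'
#' @param spikes Spike times, s.
#' @param series A `gt_distance_series`.
#' @param frame `"path_integrated"`, `"travelled"` or `"time"`.
#' @param seed Integer seed.
#' @param generations DE generations.
#' @param n_restarts Independent DE runs (seeds derived from `seed`); the
#'   best final SSD wins. The comb objective has subharmonic local optima
#'   (a comb at half the true spacing), so a single run occasionally
#'   stalls there.
#' @param obs Optional precomputed [observed_profile()] (overrides
#'   `spikes`/`series`).
#' @return A `gt_fit` list: `params` (`gt_train_params`), `ssd`, `frame`,
#'   `n_spikes`, `seed`, `trace`, `obs`.
#' @export
fit_cell <- function(spikes, series,
                     frame = c("path_integrated", "travelled", "time"),
                     seed = 1L, generations = 200, n_restarts = 2,
                     obs = NULL) {
  frame <- match.arg(frame)
  if (is.null(obs)) obs <- observed_profile(spikes, series, frame)
  if (sum(obs$occupied) < 10 ||
      stats::sd(obs$density[obs$occupied]) < 1e-12) {
    stop("degenerate profile: nothing to fit")
  }
  n_spk <- attr(obs, "n_spikes")
  binw <- attr(obs, "bin")
  ext <- range(obs$axis)
  span <- diff(ext)
  lower <- c(width = binw / 4, offset = ext[1], spacing = binw)
  upper <- c(width = 3 * binw, offset = ext[2], spacing = span / 2)
  objective <- function(p) {
    if (p[3] <= p[1] / 2) return(1e12)
    fit_score(obs, list(width = p[1], first_offset = p[2], spacing = p[3]))
  }
  ## informed candidates: the profile's autocorrelation peak lag (and its
  ## harmonics) as spacing guesses, the density argmax as a field centre
  init <- NULL
  d_occ <- obs$density
  d_occ[!obs$occupied] <- NA
  pk_lag <- tryCatch({
    r <- rate_autocorr_lags(d_occ, max(2L, min(floor(nrow(obs) / 2), 100L)))
    pk <- acorr_peak_lags(r)
    if (length(pk) >= 1) pk[1] * binw else NA_real_
  }, error = function(e) NA_real_)
  if (is.finite(pk_lag)) {
    off0 <- obs$axis[which.max(obs$density)]
    cand_s <- unique(pmin(pmax(c(pk_lag, pk_lag / 2, 2 * pk_lag),
                               lower[3]), upper[3]))
    init <- cbind(width = rep(c(binw, 2 * binw), each = length(cand_s)),
                  offset = off0, spacing = rep(cand_s, 2))
  }
  de <- NULL
  for (rs in seq_len(max(1L, n_restarts))) {
    cand <- differential_evolution(objective, lower, upper,
                                   seed = derive_seed(seed, rs - 1L),
                                   generations = generations, init = init)
    if (is.null(de) || cand$value < de$value) de <- cand
  }
  params <- train_model_params(de$par[1], de$par[2], de$par[3], frame)
  structure(list(params = params, ssd = de$value, frame = frame,
                 n_spikes = n_spk, seed = as.integer(seed),
                 trace = de$trace, obs = obs),
            class = "gt_fit")
}

#' @export
print.gt_fit <- function(x, ...) {
  cat(sprintf(
    "<gt_fit> frame %s: width %.1f, offset %.1f, spacing %.1f (SSD %.4g)\n",
    x$frame, x$params$width, x$params$first_offset, x$params$spacing, x$ssd))
  invisible(x)
}

#' Reconstruct a track rate map from fitted model parameters
#'
#' Evaluates the fitted spike-density model along the real animal path in
#' the fitted frame, maps the model rate back to x,y, bins and smooths it
#' exactly as the observed map, and correlates model and observed maps
#' over mutually valid bins.
#'
#' @param fit A `gt_fit`.
#' @param traj The session trajectory.
#' @param series The matching `gt_distance_series`.
#' @param spikes Observed spikes (for the observed map).
#' @param bin,h Map binning/smoothing (cm), as [compute_rate_map()].
#' @return A list: `model_map` (`gt_ratemap`-like), `observed_map`,
#'   `r` (Pearson over valid bins), `z` (Fisher Z).
#' @export
reconstruct_map <- function(fit, traj, series, spikes, bin = 2.5, h = 5) {
  coord <- switch(fit$frame,
                  path_integrated = series$signed,
                  travelled = series$absolute,
                  time = series$t)
  dens <- predict_profile(fit$params, coord, fit$n_spikes)
  if (all(dens <= 1e-12)) stop("zero-rate model: correlation undefined")
  ## expected spikes per tracking sample: density d(coord) * |dcoord|
  dcoord <- c(abs(diff(coord)), 0)
  if (fit$frame == "time") dcoord <- rep(series$t[2] - series$t[1], length(coord))
  wexp <- dens * dcoord

  obs_map <- compute_rate_map(traj, spikes, bin = bin, h = h)
  mod_map <- weighted_rate_map(traj, wexp, bin = bin, h = h)
  ok <- is.finite(obs_map$rate) & is.finite(mod_map$rate)
  if (sum(ok) < 20) stop("insufficient map overlap")
  r <- suppressWarnings(cor(obs_map$rate[ok], mod_map$rate[ok]))
  list(model_map = mod_map, observed_map = obs_map, r = r, z = fisher_z(r))
}

## Rate map from per-sample expected spike weights instead of spike events.
weighted_rate_map <- function(traj, w, bin = 2.5, h = 5, extent = NULL) {
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
  lin <- (iy - 1L) * nb + ix
  occ <- matrix(0, nb, nb); cnt <- matrix(0, nb, nb)
  occ_t <- tapply(rep(dt, length(lin)), lin, sum)
  cnt_t <- tapply(w, lin, sum)
  occ[as.integer(names(occ_t))] <- occ_t
  cnt[as.integer(names(cnt_t))] <- cnt_t
  sdb <- h / bin
  occ_s <- smooth2d_gauss(occ, sdb); cnt_s <- smooth2d_gauss(cnt, sdb)
  mask <- occ > 0
  rate <- matrix(NA_real_, nb, nb)
  ok <- mask & occ_s > 1e-9
  rate[ok] <- cnt_s[ok] / occ_s[ok]
  structure(list(rate = rate, occupancy = occ, mask = mask, x = ctr, y = ctr,
                 bin = bin, h = h,
                 peak_rate = suppressWarnings(max(rate, na.rm = TRUE)),
                 duration = traj_duration(traj)),
            class = "gt_ratemap")
}

#' Agreement between autocorrelation- and fit-derived field distances
#'
#' Pearson correlation (with Fisher-Z one-sample significance) between the
#' field distance estimated as the first 1D autocorrelation peak and the
#' spacing recovered by the model fit, across cells.
#'
#' @param distances A tibble/data.frame with columns `acorr` and `fit`
#'   (cm), one row per cell.
#' @return A tibble: `n`, `r`, `z`, `t`, `p_value`.
#' @export
compare_distance_methods <- function(distances) {
  d <- tibble::as_tibble(distances)
  d <- d[is.finite(d$acorr) & is.finite(d$fit), ]
  if (nrow(d) < 3) stop("need at least 3 cells with both estimates")
  r <- cor(d$acorr, d$fit)
  n <- nrow(d)
  tval <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  tibble::tibble(n = n, r = r, z = fisher_z(r), t = tval,
                 p_value = 2 * stats::pt(-abs(tval), n - 2))
}
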