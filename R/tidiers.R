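## broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy glance
NULL

#' Tidy and glance methods
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model-level summary. Methods exist for model fits
#' (`gt_fit`), studies (`gt_study`), shuffle and jitter nulls, gridness
#' results and tuning curves.
#'
#' @param x A fitted gridtrack object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.gt_fit
NULL

#' @rdname tidy.gt_fit
#' @export
tidy.gt_fit <- function(x, ...) {
  tibble::tibble(term = c("width", "first_offset", "spacing"),
                 estimate = c(x$params$width, x$params$first_offset,
                              x$params$spacing))
}

#' @rdname tidy.gt_fit
#' @export
glance.gt_fit <- function(x, ...) {
  tibble::tibble(frame = x$frame, ssd = x$ssd, n_spikes = x$n_spikes,
                 generations = length(x$trace), seed = x$seed)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_study <- function(x, ...) x$cells

#' @rdname tidy.gt_fit
#' @export
glance.gt_study <- function(x, ...) {
  tb <- x$cells
  tibble::tibble(
    n_cells = nrow(tb),
    accuracy = mean(tb$true_class == tb$label),
    threshold_path_integrated = x$thresholds[["path_integrated"]],
    threshold_travelled = x$thresholds[["travelled"]],
    threshold_time = x$thresholds[["time"]],
    seed = x$seed)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_shuffle <- function(x, ...) {
  tibble::tibble(statistic = x$scores)
}

#' @rdname tidy.gt_fit
#' @export
glance.gt_shuffle <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, percentile = x$percentile,
                 n = length(x$scores), n_per_cell = x$n_per_cell,
                 seed = x$seed)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_jitter <- function(x, ...) tibble::tibble(statistic = x$null)

#' @rdname tidy.gt_fit
#' @export
glance.gt_jitter <- function(x, ...) {
  tibble::tibble(frame = x$frame, threshold = x$threshold,
                 observed = x$observed, percentile = x$percentile,
                 n = length(x$null), exceeds = x$observed >= x$threshold,
                 seed = x$seed)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_gridness <- function(x, ...) {
  if (is.null(x$rotations)) return(tibble::tibble(term = character(0),
                                                  estimate = numeric(0)))
  tibble::tibble(term = names(x$rotations),
                 estimate = unname(x$rotations))
}

#' @rdname tidy.gt_fit
#' @export
glance.gt_gridness <- function(x, ...) {
  tibble::tibble(score = x$score, valid = x$valid,
                 r_inner = x$r_inner, r_outer = x$r_outer)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_hd_tuning <- function(x, ...) x$curve

#' @rdname tidy.gt_fit
#' @export
glance.gt_hd_tuning <- function(x, ...) {
  tibble::tibble(vector_length = x$vector_length, pfd = x$pfd,
                 peak_rate = x$peak_rate, mean_rate = x$mean_rate)
}

#' @rdname tidy.gt_fit
#' @export
tidy.gt_speed_tuning <- function(x, ...) x$curve

#' @rdname tidy.gt_fit
#' @export
glance.gt_speed_tuning <- function(x, ...) {
  tibble::tibble(r = x$r, z = as.numeric(x$z), slope = x$slope,
                 intercept = x$intercept, n_bins = x$n_bins)
}
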