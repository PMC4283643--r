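# Tracer-positive classification and manual-count calibration.

#' Classifier thresholds for retrograde tracer detection
#'
#' Defaults are the published rule: a neuron contains retrograde tracer
#' if its integrated intensity in the tracer channel exceeds 250,000 and
#' its maximum pixel intensity there exceeds 150 (8-bit pixels, 0-255).
#' Both comparisons are strict ("exceeds"); boundary equality is negative.
#'
#' @param integrated_threshold Integrated-intensity threshold.
#' @param max_pixel_threshold Maximum-pixel-intensity threshold (<= 255).
#' @param tracer_channel Channel role the rule applies to.
#' @return A list of class `"classifier_params"`.
#' @export
classifier_params <- function(integrated_threshold = 250000,
                              max_pixel_threshold = 150,
                              tracer_channel = "tracer_red") {
  check_number(integrated_threshold, "integrated_threshold", min = 1e-12)
  check_number(max_pixel_threshold, "max_pixel_threshold", min = 1e-12,
               max = 255)
  structure(list(integrated_threshold = integrated_threshold,
                 max_pixel_threshold = max_pixel_threshold,
                 tracer_channel = tracer_channel),
            class = "classifier_params")
}

#' Classify cells as retrograde-tracer positive
#'
#' A cell is positive iff, in the tracer channel, integrated intensity
#' strictly exceeds `integrated_threshold` AND maximum pixel intensity
#' strictly exceeds `max_pixel_threshold`.
#'
#' @param cells Feature tibble from [extract_features()] (needs
#'   `<channel>_integrated` and `<channel>_max` columns).
#' @param params A [classifier_params()].
#' @return Logical vector, one flag per cell.
#' @export
classify_tracer_positive <- function(cells, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  ic <- paste0(params$tracer_channel, "_integrated")
  mc <- paste0(params$tracer_channel, "_max")
  if (!all(c(ic, mc) %in% names(cells))) {
    stop_cf("feature table lacks %s / %s columns for channel '%s'",
            ic, mc, params$tracer_channel)
  }
  cells[[ic]] > params$integrated_threshold &
    cells[[mc]] > params$max_pixel_threshold
}

#' Fit a manual-vs-automated count calibration
#'
#' Ordinary least squares of manual counts (response) on automated counts
#' (predictor), fitted per animal. Automated counting systematically
#' undercounts, so the regression's x-intercept (-intercept/slope) is
#' negative and its magnitude, `offset_added`, is the correction later
#' added to every automated count on the analysis inclusion list.
#'
#' @param pairs Data frame with columns `manual` and `automated` (>= 3
#'   rows, nonzero variance in `automated`).
#' @return A list of class `"calibration_model"`: `slope`, `intercept`,
#'   `r_value`, `p_value`, `x_intercept`, `offset_added`, `n`, `usable`
#'   (`FALSE` when the slope is not positive, in which case the model
#'   must not be used for adjustment).
#' @export
fit_calibration <- function(pairs) {
  if (!all(c("manual", "automated") %in% names(pairs))) {
    stop_cf("pairs must have columns 'manual' and 'automated'")
  }
  m <- as.numeric(pairs$manual); a <- as.numeric(pairs$automated)
  if (length(m) < 3) stop_cf("need at least 3 manual/automated pairs")
  if (var(a) <= 0) stop_cf("automated counts have zero variance")
  fit <- lm(m ~ a)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r <- cor(m, a)
  # two-sided p for the slope
  p <- if (length(m) > 2 && is.finite(r) && abs(r) < 1) {
    tstat <- r * sqrt((length(m) - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = length(m) - 2)
  } else 0
  usable <- is.finite(slope) && slope > 0
  if (!usable) {
    warning("calibration slope is not positive; model flagged unusable for adjustment")
  }
  x_int <- if (is.finite(slope) && slope != 0) -intercept / slope else NA_real_
  structure(list(
    slope = slope, intercept = intercept,
    r_value = r, p_value = p,
    x_intercept = x_int,
    offset_added = if (usable) max(0, -x_int) else NA_real_,
    n = length(m),
    usable = usable
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> manual ~ automated (n = %d)\n",
                     "  slope %.3f, intercept %.3f, r %.3f, p %.3g\n",
                     "  x-intercept %.3f -> offset added %.3f%s\n"),
              x$n, x$slope, x$intercept, x$r_value, x$p_value,
              x$x_intercept, x$offset_added,
              if (x$usable) "" else "  [UNUSABLE]"))
  invisible(x)
}

#' Apply the calibration offset to automated counts
#'
#' Adds `offset_added` to the automated count of every ROI on the
#' inclusion list; ROIs off the list are untouched and the adjustment
#' never decreases a count. A positive x-intercept (offset 0) leaves all
#' counts unchanged, with a message.
#'
#' @param counts Tibble with columns `roi` and `count`.
#' @param model A usable [fit_calibration()] model.
#' @param included_rois ROI names to adjust; defaults to all.
#' @return `counts` with an `adjusted` column.
#' @export
apply_calibration <- function(counts, model, included_rois = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (!model$usable) stop_cf("calibration model is flagged unusable (slope <= 0)")
  if (!all(c("roi", "count") %in% names(counts))) {
    stop_cf("counts must have columns 'roi' and 'count'")
  }
  offset <- model$offset_added
  if (offset <= 0) {
    message("x-intercept is nonnegative; adjustment of 0 applied")
    offset <- 0
  }
  included_rois <- included_rois %||% counts$roi
  counts$adjusted <- counts$count +
    ifelse(counts$roi %in% included_rois, offset, 0)
  counts
}
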