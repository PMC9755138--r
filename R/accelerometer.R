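# Accelerometer activity metrics: active/resting classification at the
# behavioural threshold, QC axis correlation, and the two activity
# components analysed seasonally.

#' Classify accelerometer samples as active or resting
#'
#' Values below 28 (on the 0-255 logger scale) are resting; values at or
#' above 28 are active. Analyses use the x-axis only; the y-axis is
#' retained for QC (the two are nearly redundant).
#'
#' @param value Integer accelerometer means in `[0, 255]`.
#' @param threshold Activity threshold (default 28).
#' @return Logical vector, TRUE = active.
#' @export
classify_active <- function(value, threshold = 28) {
  if (any(value < 0 | value > 255, na.rm = TRUE))
    stop("accelerometer values must lie in [0, 255]")
  value >= threshold
}

#' Pearson correlation between accelerometer axes
#'
#' QC statistic justifying the x-axis-only analysis.
#'
#' @param samples data.frame with `act_x` and `act_y`.
#' @return Pearson r, or NA (with a warning) when an axis has zero
#'   variance.
#' @export
axis_correlation <- function(samples) {
  if (nrow(samples) < 2L) stop("need at least two samples")
  if (stats::sd(samples$act_x) == 0 || stats::sd(samples$act_y) == 0) {
    warning("zero variance on an axis; correlation undefined")
    return(NA_real_)
  }
  stats::cor(samples$act_x, samples$act_y)
}

#' Activity components per stratum
#'
#' For each animal x calendar month x light period stratum: (1) the
#' proportion of time active (share of 5-min samples at or above the
#' threshold) and (2) the activity rate when active (mean of the active
#' sample values, 28-255). Each 5-min sample is assigned to the period
#' containing its timestamp. Empty strata are omitted; strata with no
#' active samples carry `rate_when_active = NA`.
#'
#' @param samples Accelerometer table: `animal_id`, `timestamp` (UTC),
#'   `act_x` (and optionally `act_y`).
#' @param lon,lat Site coordinates for the period classification.
#' @param threshold Activity threshold (default 28).
#' @param axis Which axis to analyse (default `"act_x"`).
#' @param tz_offset_hours Civil offset used for the calendar month
#'   (default 8, the study site).
#' @return data.frame with `animal_id`, `month`, `period`, `n`,
#'   `prop_active`, `rate_when_active`.
#' @export
activity_components <- function(samples, lon, lat, threshold = 28,
                                axis = "act_x", tz_offset_hours = 8) {
  v <- samples[[axis]]
  act <- classify_active(v, threshold)
  month <- local_month(samples$timestamp, tz_offset_hours)
  period <- classify_period(samples$timestamp, lon, lat)
  key <- interaction(samples$animal_id, month, period, drop = TRUE)
  rows <- lapply(split(seq_along(v), key), function(idx) {
    a <- act[idx]
    data.frame(
      animal_id = samples$animal_id[idx[1]],
      month = month[idx[1]],
      period = as.character(period[idx[1]]),
      n = length(idx),
      prop_active = mean(a),
      rate_when_active = if (any(a)) mean(v[idx][a]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal_id, out$month, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}
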