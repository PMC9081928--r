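#' Area-under-the-threshold cooling dose in degree-minutes
#'
#' The hypothermia "dose" is the region bounded below a fixed temperature
#' threshold and above the time-temperature curve, computed as a per-reading
#' rectangle sum with the nominal 5-minute sampling interval:
#' `AUC_x = 5 * sum_i max(x - T_i, 0)`. Readings are used exactly as
#' recorded -- no trapezoid rule, no interpolation at threshold crossings.
#' Series with fewer readings than the full 3-hour window (36 sub-baseline
#' slots) are summed over what exists, with a warning.
#'
#' @param series A [temperature_series()].
#' @param threshold Threshold in degrees C, in (0, 45). The conventional
#'   doses are AUC34 (`threshold = 34`) and AUC30 (`threshold = 30`).
#' @param interval_min Sampling interval Delta in minutes (fixed nominal
#'   value, default 5).
#' @return Degree-minutes (>= 0).
#' @export
#' @examples
#' s <- temperature_series("p1", "control", seq(0, 180, 5), rep(37, 37))
#' compute_auc(s, 34)  # 0: never below threshold
compute_auc <- function(series, threshold, interval_min = 5) {
  stopifnot(inherits(series, "temperature_series"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 45)
    stop("threshold must be a single value in (0, 45) degrees C", call. = FALSE)
  if (length(series$temps) == 0)
    stop("compute_auc: empty series", call. = FALSE)
  if (length(series$temps) < 36)
    warning(sprintf("series %s has %d readings (< 36); AUC summed over available readings",
                    series$animal_id, length(series$temps)),
            call. = FALSE)
  interval_min * sum(pmax(threshold - series$temps, 0))
}

#' Per-animal cooling-dose parameters
#'
#' Derives the full set of cooling parameters from one temperature series:
#' AUC34 and AUC30 (degree-minutes), the temperature nadir (raw minimum, no
#' smoothing), the cooling time (span of readings more than 0.5 degrees C
#' below the first reading; a metadata perfusion log would override this but
#' is not part of the series), the time from cooling start to the first
#' reading below 30 degrees C, and -- when a setup time is supplied -- the
#' total time to below 30 (setup + time to <30).
#'
#' @param series A [temperature_series()].
#' @param setup_time Minutes from reperfusion to start of perfusion, or `NA`
#'   when unknown.
#' @return One-row data frame with columns `animal_id, group, auc34, auc30,
#'   temp_nadir, cooling_time, setup_time, time_below_30,
#'   total_time_to_below_30`. A series that never drops below 30 reports
#'   `time_below_30 = NA` (absence, not an error).
#' @export
#' @examples
#' s <- temperature_series("p1", "control", seq(0, 180, 5), rep(37, 37))
#' compute_dose(s)$auc34
compute_dose <- function(series, setup_time = NA_real_) {
  stopifnot(inherits(series, "temperature_series"))
  temps <- series$temps
  times <- series$times
  nadir <- min(temps)

  baseline <- temps[1]
  cooled <- which(temps < baseline - 0.5)
  if (length(cooled)) {
    cooling_time <- times[max(cooled)] - times[min(cooled)]
    cool_start <- times[min(cooled)]
  } else {
    cooling_time <- 0
    cool_start <- NA_real_
  }

  below30 <- which(temps < 30)
  time_below_30 <- if (length(below30) && !is.na(cool_start))
    times[min(below30)] - cool_start else NA_real_
  total_time <- if (!is.na(setup_time) && !is.na(time_below_30))
    setup_time + time_below_30 else NA_real_

  data.frame(
    animal_id = series$animal_id, group = series$group,
    auc34 = compute_auc(series, 34),
    auc30 = compute_auc(series, 30),
    temp_nadir = nadir,
    cooling_time = cooling_time,
    setup_time = setup_time,
    time_below_30 = time_below_30,
    total_time_to_below_30 = total_time,
    stringsAsFactors = FALSE
  )
}

#' Cooling doses for a list of series
#'
#' @param series_list List of [temperature_series()].
#' @param setup_times Numeric vector of setup times (minutes), recycled `NA`
#'   if absent; matched by position.
#' @return Data frame, one row per animal (see [compute_dose()]).
#' @export
compute_doses <- function(series_list, setup_times = NULL) {
  if (length(series_list) == 0)
    stop("compute_doses: no series supplied", call. = FALSE)
  if (is.null(setup_times)) setup_times <- rep(NA_real_, length(series_list))
  out <- do.call(rbind, Map(compute_dose, series_list, setup_times))
  rownames(out) <- NULL
  out
}

#' Five-number summary of cooling-dose parameters
#'
#' Median, first and third quartile, minimum and maximum for each cooling
#' parameter, matching the "Median (Q1, Q3) ... Min, Max" presentation of
#' per-animal hypothermia summaries. Quartiles use linear interpolation
#' between order statistics (R's default type 7).
#'
#' @param doses Data frame from [compute_doses()].
#' @param parameters Character vector of dose columns to summarise.
#' @return Data frame `parameter, n, median, q1, q3, min, max`.
#' @export
summarize_doses <- function(doses,
                            parameters = c("setup_time", "time_below_30",
                                           "cooling_time", "total_time_to_below_30",
                                           "temp_nadir", "auc34", "auc30")) {
  if (is.null(doses) || nrow(doses) == 0)
    stop("summarize_doses: empty dose table", call. = FALSE)
  parameters <- intersect(parameters, names(doses))
  rows <- lapply(parameters, function(p) {
    v <- doses[[p]][is.finite(doses[[p]])]
    if (!length(v)) {
      data.frame(parameter = p, n = 0L, median = NA_real_, q1 = NA_real_,
                 q3 = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(parameter = p, n = length(v), median = q[2], q1 = q[1],
                 q3 = q[3], min = min(v), max = max(v))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
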