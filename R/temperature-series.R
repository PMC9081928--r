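#' Construct a temperature time series for one animal
#'
#' A `temperature_series` holds one probe's time-stamped brain temperature
#' readings for one animal, starting at reperfusion. Times must be strictly
#' increasing and temperatures finite; the nominal sampling interval is
#' 5 minutes and deviations are flagged (not rejected).
#'
#' @param animal_id Animal identifier.
#' @param group Cohort label, `"control"` or `"hypothermia"`.
#' @param times Minutes since reperfusion, strictly increasing.
#' @param temps Temperatures in degrees C, same length as `times`.
#' @param probe Probe label (default `"nasal"`).
#' @param metadata Optional named list of provenance (e.g. sampled simulation
#'   parameters).
#' @return An object of class `temperature_series`.
#' @export
#' @examples
#' s <- temperature_series("p1", "control", seq(0, 180, 5), rep(37, 37))
#' s$irregular_sampling
temperature_series <- function(animal_id, group, times, temps,
                               probe = "nasal", metadata = list()) {
  group <- match.arg(group, c("control", "hypothermia"))
  times <- as.numeric(times)
  temps <- as.numeric(temps)
  if (length(times) < 1) stop("temperature_series: need at least one reading", call. = FALSE)
  if (length(times) != length(temps))
    stop("temperature_series: times and temps differ in length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(temps)))
    stop("temperature_series: times and temps must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("temperature_series: times must be strictly increasing", call. = FALSE)
  irregular <- length(times) > 1 && any(abs(diff(times) - 5) > 1e-8)
  structure(
    list(animal_id = as.character(animal_id), group = group, probe = probe,
         times = times, temps = temps,
         irregular_sampling = irregular, metadata = metadata),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("temperature_series %s [%s/%s]: %d readings, %g-%g min, nadir %.1f C\n",
              x$animal_id, x$group, x$probe, length(x$times),
              min(x$times), max(x$times), min(x$temps)))
  invisible(x)
}

#' Split a long-format temperature table into per-animal series
#'
#' @param temps_df Data frame with columns `animal_id`, `group`, `probe`,
#'   `time_min`, `temp_c` (the `temperatures.csv` layout).
#' @return Named list of [temperature_series()], one per animal.
#' @export
series_from_table <- function(temps_df) {
  need <- c("animal_id", "group", "probe", "time_min", "temp_c")
  missing <- setdiff(need, names(temps_df))
  if (length(missing))
    stop("temperature table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(temps_df, temps_df$animal_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    temperature_series(d$animal_id[1], as.character(d$group[1]),
                       d$time_min, d$temp_c, probe = as.character(d$probe[1]))
  })
  out[order(names(out))]
}
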