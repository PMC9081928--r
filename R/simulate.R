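#' Simulate one animal's brain temperature series
#'
#' Controls sit at baseline with truncated Gaussian noise (never below
#' 34 degrees C, so their AUC34 is exactly zero by construction).
#' Hypothermia animals stay at baseline until a sampled setup time, then
#' descend exponentially toward a sampled nadir,
#' `T(t) = nadir + (baseline - nadir) * exp(-(t - t_setup)/tau)`,
#' for the sampled cooling duration. If cooling ends before the 180-minute
#' recording window the series holds the last cooled temperature (rewarming
#' is not modelled). Readings are taken every 5 minutes from 0 to 180
#' (37 points) and clipped to (15, 40) degrees C.
#'
#' Sampling uses the RNG state in effect; cohort-level wrappers seed
#' per-animal substreams. Pass `params` to fix the sampled setup time,
#' cooling duration and nadir.
#'
#' @param config A [sim_config()].
#' @param group `"control"` or `"hypothermia"`.
#' @param animal_id Identifier for the series.
#' @param params Optional named list `(setup_time, cooling_duration, nadir)`
#'   overriding the sampled values (hypothermia only).
#' @return A [temperature_series()]; sampled parameters are stored in
#'   `$metadata`.
#' @export
#' @examples
#' set.seed(1)
#' s <- simulate_temperature_series(sim_config(), "hypothermia")
#' s$metadata$nadir
simulate_temperature_series <- function(config, group, animal_id = "sim1",
                                        params = NULL) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  if (!is.character(group) || length(group) != 1 ||
      !group %in% c("control", "hypothermia"))
    stop("group must be \"control\" or \"hypothermia\"", call. = FALSE)

  times <- seq(0, 180, by = 5)
  n <- length(times)
  base <- config$baseline_temp_c
  noise <- if (config$temp_noise_sd_c > 0)
    stats::rnorm(n, 0, config$temp_noise_sd_c) else numeric(n)

  if (group == "control") {
    # truncate noise so controls never drop below 34 C: AUC34 identically 0
    temps <- pmax(base + noise, 34)
    meta <- list(group = "control", baseline = base)
  } else {
    if (is.null(params)) {
      params <- list(
        setup_time = stats::runif(1, config$setup_time_range_min[1],
                                  config$setup_time_range_min[2]),
        cooling_duration = stats::runif(1, config$cooling_duration_range_min[1],
                                        config$cooling_duration_range_min[2]),
        nadir = stats::runif(1, config$nadir_range_c[1], config$nadir_range_c[2])
      )
    }
    tau <- config$descent_time_constant_min
    cool_end <- min(180, params$setup_time + params$cooling_duration)
    profile <- vapply(times, function(t) {
      if (t < params$setup_time) return(base)
      te <- min(t, cool_end)
      if (tau <= 0) return(params$nadir)  # step-function limit
      params$nadir + (base - params$nadir) * exp(-(te - params$setup_time) / tau)
    }, numeric(1))
    temps <- profile + noise
    meta <- c(params, list(tau = tau, cool_end = cool_end, baseline = base))
  }
  temps <- pmin(pmax(temps, 15), 40)
  temperature_series(animal_id, group, times, temps, metadata = meta)
}

#' Simulate injury outcomes from cooling doses
#'
#' Applies the generative quadratic `a + b*AUC34 + c*AUC34^2` plus Gaussian
#' noise, clipping at zero (infarct measures are non-negative). Control
#' animals have AUC34 = 0, so their mean outcome equals the intercept `a`.
#' The number of clipped draws is attached as attribute `n_clipped`.
#'
#' @param doses Data frame of cooling doses (needs columns `animal_id`,
#'   `group`, `auc34`), e.g. from [compute_doses()].
#' @param config A [sim_config()]; uses `outcome_model` and
#'   `outcome_noise_sd`. Sampling uses the RNG state in effect.
#' @return Data frame `animal_id, group, outcome` with attribute `n_clipped`.
#' @export
simulate_outcomes <- function(doses, config) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  om <- config$outcome_model
  mu <- om[["a"]] + om[["b"]] * doses$auc34 + om[["c"]] * doses$auc34^2
  noise <- if (config$outcome_noise_sd > 0)
    stats::rnorm(length(mu), 0, config$outcome_noise_sd) else numeric(length(mu))
  raw <- mu + noise
  clipped <- raw < 0
  out <- data.frame(animal_id = doses$animal_id, group = doses$group,
                    outcome = pmax(raw, 0), stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates temperature series for every animal (per-animal RNG substreams
#' derived deterministically from the config seed and animal index), computes
#' cooling doses, then draws the three injury outcomes. The total-pathology
#' volume follows the configured quadratic in AUC34 directly; MRI percent is
#' the same dose signal scaled to the MRI range (factor 0.0265, the ratio of
#' the control medians 0.05 / 1.89) with proportionally scaled noise; the
#' largest-pathology volume is a uniform fraction (0.45-0.65) of the total,
#' guaranteeing `largest <= total`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with elements `series` (list of
#'   [temperature_series()]), `temperatures` (long data frame), `doses`
#'   (from [compute_doses()]), `outcomes` (data frame `animal_id, group,
#'   mri_pct, total_path_cm3, largest_path_cm3`), `provenance` (per-animal
#'   true parameters), `n_clipped`, and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_control = 2, n_hypothermia = 3, seed = 7))
#' coh$doses$auc34
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  groups <- c(rep("control", config$n_control),
              rep("hypothermia", config$n_hypothermia))
  n <- length(groups)
  if (n == 0) stop("simulate_cohort: empty cohort", call. = FALSE)
  ids <- sprintf("pig%02d", seq_len(n))

  series <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(animal_seed(config$seed, i))
    series[[i]] <- simulate_temperature_series(config, groups[i], ids[i])
  }
  names(series) <- ids

  temps_df <- do.call(rbind, lapply(series, function(s) {
    data.frame(animal_id = s$animal_id, group = s$group, probe = s$probe,
               time_min = s$times, temp_c = s$temps, stringsAsFactors = FALSE)
  }))
  rownames(temps_df) <- NULL

  setup <- vapply(series, function(s)
    if (!is.null(s$metadata$setup_time)) s$metadata$setup_time else NA_real_,
    numeric(1))
  doses <- compute_doses(series, setup_times = setup)

  # outcomes: one substream for the whole outcome stage
  set.seed(animal_seed(config$seed, n + 1L))
  total <- simulate_outcomes(doses, config)
  mri_scale <- 0.0265
  cfg_mri <- config
  cfg_mri$outcome_model <- config$outcome_model * mri_scale
  cfg_mri$outcome_noise_sd <- config$outcome_noise_sd * mri_scale
  mri <- simulate_outcomes(doses, cfg_mri)
  frac <- stats::runif(n, 0.45, 0.65)
  outcomes <- data.frame(
    animal_id = doses$animal_id, group = doses$group,
    mri_pct = pmin(mri$outcome, 100),
    total_path_cm3 = total$outcome,
    largest_path_cm3 = frac * total$outcome,
    stringsAsFactors = FALSE
  )

  prov <- data.frame(
    animal_id = ids, group = groups,
    setup_time = setup,
    cooling_duration = vapply(series, function(s)
      if (!is.null(s$metadata$cooling_duration)) s$metadata$cooling_duration
      else NA_real_, numeric(1)),
    nadir = vapply(series, function(s)
      if (!is.null(s$metadata$nadir)) s$metadata$nadir else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(prov) <- NULL

  structure(list(series = series, temperatures = temps_df, doses = doses,
                 outcomes = outcomes, provenance = prov,
                 n_clipped = attr(total, "n_clipped") + attr(mri, "n_clipped"),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%d control, %d hypothermia), seed %d\n",
              nrow(x$outcomes), sum(x$outcomes$group == "control"),
              sum(x$outcomes$group == "hypothermia"), x$config$seed))
  cat(sprintf("  AUC34 range (hypothermia): %.0f-%.0f deg-min; %d clipped outcome draw(s)\n",
              min(x$doses$auc34[x$doses$group == "hypothermia"]),
              max(x$doses$auc34[x$doses$group == "hypothermia"]), x$n_clipped))
  invisible(x)
}

#' Simulate a paired brain temperature / tissue-oxygen series
#'
#' Emulates the single-animal experiment in which brain tissue oxygen
#' declined in parallel with parenchymal temperature during selective
#' cooling: temperature descends linearly over the window and
#' `pO2 = intercept + slope * temperature + noise`.
#'
#' @param n_points Number of paired readings (>= 3; Pearson correlation is
#'   undefined below that).
#' @param slope mmHg per degree C.
#' @param intercept mmHg.
#' @param noise_sd mmHg, SD of additive Gaussian noise on pO2.
#' @param temp_range Length-2 numeric, degrees C spanned by the temperature
#'   ramp (default 37 down to 23).
#' @return Data frame `time_min, temp_c, po2_mmhg`.
#' @export
simulate_temp_po2_series <- function(n_points, slope, intercept, noise_sd,
                                     temp_range = c(37, 23)) {
  if (n_points < 3)
    stop("simulate_temp_po2_series: need n_points >= 3 (correlation undefined)",
         call. = FALSE)
  temp <- seq(temp_range[1], temp_range[2], length.out = n_points)
  noise <- if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else numeric(n_points)
  data.frame(time_min = seq(0, by = 5, length.out = n_points),
             temp_c = temp,
             po2_mmhg = intercept + slope * temp + noise)
}

#' Write a simulated cohort to CSV/JSON artifacts
#'
#' Writes `temperatures.csv`, `outcomes.csv` and `provenance.json` into
#' `dir`. Identical seed and config give byte-identical files.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(temperatures = file.path(dir, "temperatures.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             provenance = file.path(dir, "provenance.json"))
  utils::write.csv(cohort$temperatures, paths["temperatures"], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths["outcomes"], row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cohort$config), animals = cohort$provenance,
         n_clipped = cohort$n_clipped),
    paths["provenance"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
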