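#' Simulation configuration for a synthetic hypothermia cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults emulate the study design the analysis targets: 13 normothermic
#' controls and 17 selectively cooled animals, brain temperature recorded
#' every 5 minutes for up to 180 minutes, nadir / setup-time / cooling-time
#' ranges matching the published per-animal summaries, and injury outcomes
#' following a U-shaped quadratic in AUC34 with its vertex at 515
#' degree-minutes and an intercept equal to the control-group total-pathology
#' median (1.89 cm^3).
#'
#' @param n_control Number of control (normothermic) animals.
#' @param n_hypothermia Number of hypothermia-treated animals.
#' @param baseline_temp_c Pre-cooling brain temperature, degrees C.
#' @param nadir_range_c Length-2 numeric, (low, high) degrees C; per-animal
#'   target nadirs are drawn uniformly from this range.
#' @param setup_time_range_min Length-2 numeric, minutes from reperfusion to
#'   the start of cooled-blood perfusion.
#' @param cooling_duration_range_min Length-2 numeric, minutes of cooled-blood
#'   perfusion.
#' @param descent_time_constant_min Time constant (minutes) of the
#'   exponential approach to the nadir. The default 20 min makes the
#'   37 -> <30 degree crossing take about 15 minutes for a typical nadir,
#'   matching the published median time to <30 degrees C.
#' @param temp_noise_sd_c SD (degrees C) of additive Gaussian measurement
#'   noise on each temperature reading.
#' @param outcome_model Length-3 numeric `c(a, b, c)`: the generative
#'   quadratic `E(Y|x) = a + b*x + c*x^2` relating the total-pathology
#'   outcome (cm^3) to AUC34 dose x (degree-minutes). The default has its
#'   vertex (injury-minimizing dose) at -b/(2c) = 515 degree-minutes.
#' @param outcome_noise_sd SD (outcome units) of additive Gaussian outcome
#'   noise. The default keeps clipping at zero below 5 percent of draws.
#' @param seed Integer seed; all sampling is reproducible given the seed.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_hypothermia
sim_config <- function(n_control = 13,
                       n_hypothermia = 17,
                       baseline_temp_c = 37,
                       nadir_range_c = c(20.3, 27.5),
                       setup_time_range_min = c(22, 144),
                       cooling_duration_range_min = c(36, 150),
                       descent_time_constant_min = 20,
                       temp_noise_sd_c = 0.3,
                       outcome_model = c(a = 1.89, b = -0.00412, c = 4e-06),
                       outcome_noise_sd = 0.45,
                       seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control),
    n_hypothermia = as.integer(n_hypothermia),
    baseline_temp_c = baseline_temp_c,
    nadir_range_c = as.numeric(nadir_range_c),
    setup_time_range_min = as.numeric(setup_time_range_min),
    cooling_duration_range_min = as.numeric(cooling_duration_range_min),
    descent_time_constant_min = descent_time_constant_min,
    temp_noise_sd_c = temp_noise_sd_c,
    outcome_model = stats::setNames(as.numeric(outcome_model), c("a", "b", "c")),
    outcome_noise_sd = outcome_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop("sim_config: ", msg, call. = FALSE)
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
  stop_if(cfg$n_control < 0 || cfg$n_hypothermia < 0,
          "cohort sizes must be non-negative")
  stop_if(!rng_ok(cfg$nadir_range_c), "nadir_range_c must be (low, high) with low <= high")
  stop_if(!rng_ok(cfg$setup_time_range_min), "setup_time_range_min must be (low, high)")
  stop_if(!rng_ok(cfg$cooling_duration_range_min),
          "cooling_duration_range_min must be (low, high)")
  stop_if(cfg$nadir_range_c[1] <= 0 || cfg$nadir_range_c[2] >= cfg$baseline_temp_c,
          "nadir_range_c must lie within (0, baseline_temp_c)")
  stop_if(cfg$temp_noise_sd_c < 0, "temp_noise_sd_c must be >= 0")
  stop_if(cfg$outcome_noise_sd < 0, "outcome_noise_sd must be >= 0")
  stop_if(length(cfg$outcome_model) != 3 || anyNA(cfg$outcome_model),
          "outcome_model must be three finite coefficients (a, b, c)")
  stop_if(cfg$descent_time_constant_min < 0,
          "descent_time_constant_min must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  animals: %d control + %d hypothermia\n", x$n_control, x$n_hypothermia))
  cat(sprintf("  baseline %.1f C, nadir U(%.1f, %.1f) C, tau %.1f min\n",
              x$baseline_temp_c, x$nadir_range_c[1], x$nadir_range_c[2],
              x$descent_time_constant_min))
  cat(sprintf("  setup U(%g, %g) min, cooling U(%g, %g) min\n",
              x$setup_time_range_min[1], x$setup_time_range_min[2],
              x$cooling_duration_range_min[1], x$cooling_duration_range_min[2]))
  om <- x$outcome_model
  cat(sprintf("  outcome quadratic: a=%.4g b=%.4g c=%.4g (vertex %.1f deg-min)\n",
              om[1], om[2], om[3],
              if (om[3] > 0) -om[2] / (2 * om[3]) else NA_real_))
  cat(sprintf("  noise: temp %.2f C, outcome %.3g; seed %d\n",
              x$temp_noise_sd_c, x$outcome_noise_sd, x$seed))
  invisible(x)
}

# Deterministic per-animal substream seed derived from (master seed, index).
# Kept below 2^31 - 1 so it is always a valid R integer seed.
animal_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6) * 1913 + index * 7919 + 17) %% 2147483562L
}
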