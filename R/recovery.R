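#' Constructed U-shaped demonstration cohort configuration
#'
#' A [sim_config()] whose hypothermia doses straddle the injury-minimizing
#' vertex while staying below the dose at which the quadratic re-crosses the
#' control level. On such a cohort the within-hypothermia correlation of
#' AUC34 with outcome is positive (most animals sit on the rising limb)
#' while the all-animal correlation -- controls included at dose zero -- is
#' negative: the sign-reversal signature of a U-shaped dose-response.
#' Relative to the defaults, the setup-time window is narrowed to (50, 140)
#' minutes, cooling runs the full 150 minutes, nadirs span (22, 26) degrees
#' C and the outcome noise SD is 0.25.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
ushape_demo_config <- function(seed = 1L) {
  sim_config(setup_time_range_min = c(50, 140),
             cooling_duration_range_min = c(150, 150),
             nadir_range_c = c(22, 26),
             outcome_noise_sd = 0.25,
             seed = seed)
}

#' Coverage simulation for the vertex bootstrap interval
#'
#' Repeatedly simulates a cohort, fits the quadratic dose-response of the
#' chosen outcome on AUC34 (controls at dose zero) and asks whether the
#' studentized bootstrap interval for the injury-minimizing dose covers the
#' generative truth `-b/(2c)`. The empirical coverage should match the
#' nominal level.
#'
#' @param config A [sim_config()]; its `outcome_model` defines the true
#'   vertex.
#' @param n_repeats Number of simulated cohorts.
#' @param B Bootstrap replicates per cohort.
#' @param level Nominal confidence level.
#' @param seed Master seed; repeat r uses a derived substream.
#' @param outcome Outcome column fitted (default `total_path_cm3`, the
#'   outcome the generative quadratic acts on directly).
#' @return List: `coverage` (fraction of repeats whose interval covers the
#'   truth), `n_covered`, `n_with_interval` (repeats where the interval was
#'   defined), `n_repeats`, `truth`, and the per-repeat estimates.
#' @export
vertex_coverage_sim <- function(config, n_repeats = 500, B = 999,
                                level = 0.95, seed = 1L,
                                outcome = "total_path_cm3") {
  om <- config$outcome_model
  if (om[["c"]] <= 0) stop("config outcome model is not U-shaped", call. = FALSE)
  truth <- -om[["b"]] / (2 * om[["c"]])
  covered <- defined <- logical(n_repeats)
  est <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- animal_seed(seed, r * 101L)
    coh <- simulate_cohort(cfg)
    dall <- impute_control_doses(
      merge(coh$doses, coh$outcomes[, c("animal_id", outcome)], by = "animal_id"))
    bt <- bootstrap_quadratic(dall$auc34, dall[[outcome]],
                              targets = "minimizing_dose",
                              level = level, B = B,
                              seed = animal_seed(seed, r * 101L + 1L))
    iv <- bt$intervals$minimizing_dose
    est[r] <- iv$estimate
    defined[r] <- is.finite(iv$lower) && is.finite(iv$upper)
    covered[r] <- defined[r] && iv$lower <= truth && truth <= iv$upper
  }
  list(coverage = mean(covered[defined]),
       n_covered = sum(covered), n_with_interval = sum(defined),
       n_repeats = n_repeats, truth = truth, estimates = est)
}
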