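test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_control = -1), "non-negative")
  expect_error(sim_config(nadir_range_c = c(27, 22)), "low <= high")
  expect_error(sim_config(nadir_range_c = c(20, 38)), "within")
  expect_error(sim_config(temp_noise_sd_c = -0.1), ">= 0")
  expect_error(sim_config(outcome_noise_sd = -1), ">= 0")
})

test_that("zero-noise control series sit exactly at baseline", {
  cfg <- sim_config(temp_noise_sd_c = 0)
  s <- simulate_temperature_series(cfg, "control")
  expect_length(s$temps, 37)
  expect_equal(s$times, seq(0, 180, 5))
  expect_true(all(s$temps == cfg$baseline_temp_c))
})

test_that("step-function limit: tau -> 0 gives baseline then nadir", {
  cfg <- sim_config(temp_noise_sd_c = 0, descent_time_constant_min = 0)
  s <- simulate_temperature_series(
    cfg, "hypothermia",
    params = list(setup_time = 40, cooling_duration = 140, nadir = 24))
  expect_equal(s$temps[s$times < 40], rep(37, 8))
  expect_equal(s$temps[s$times >= 40], rep(24, 29))
})

test_that("invalid group labels are rejected", {
  expect_error(simulate_temperature_series(sim_config(), "sham"), "control")
})

test_that("sampled parameters land in the configured ranges and match provenance", {
  cfg <- sim_config(seed = 1)
  coh <- simulate_cohort(cfg)
  hy <- coh$provenance[coh$provenance$group == "hypothermia", ]
  expect_true(all(hy$nadir >= cfg$nadir_range_c[1] & hy$nadir <= cfg$nadir_range_c[2]))
  expect_true(all(hy$setup_time >= cfg$setup_time_range_min[1] &
                    hy$setup_time <= cfg$setup_time_range_min[2]))
  expect_true(all(hy$cooling_duration >= cfg$cooling_duration_range_min[1] &
                    hy$cooling_duration <= cfg$cooling_duration_range_min[2]))
  # the computed nadir can only undershoot the sampled target by noise
  for (id in hy$animal_id) {
    s <- coh$series[[id]]
    expect_gte(min(s$temps), s$metadata$nadir - 5 * cfg$temp_noise_sd_c)
    expect_lte(min(s$temps), cfg$baseline_temp_c)
  }
})

test_that("control animals never contribute positive AUC34", {
  coh <- simulate_cohort(sim_config(seed = 23, temp_noise_sd_c = 2))
  ctrl <- coh$doses[coh$doses$group == "control", ]
  expect_true(all(ctrl$auc34 == 0))
  expect_true(all(ctrl$auc30 == 0))
})

test_that("outcomes follow the generative quadratic exactly at zero noise", {
  # direct evaluation: a + b*500 + c*500^2 = 2 - 2 + 1
  cfg <- sim_config(outcome_model = c(2, -0.004, 4e-06), outcome_noise_sd = 0)
  doses <- data.frame(animal_id = c("a", "b"), group = c("hypothermia", "control"),
                      auc34 = c(500, 0))
  out <- simulate_outcomes(doses, cfg)
  expect_equal(out$outcome, c(1, 2))
  expect_identical(attr(out, "n_clipped"), 0L)

  # zero-noise cohort: OLS recovers (a, b, c) to 6+ significant digits
  cfg0 <- sim_config(temp_noise_sd_c = 0, outcome_noise_sd = 0, seed = 5)
  coh <- simulate_cohort(cfg0)
  d <- impute_control_doses(merge(coh$doses,
                                  coh$outcomes[, c("animal_id", "total_path_cm3")],
                                  by = "animal_id"))
  f <- fit_quadratic(d$auc34, d$total_path_cm3)
  expect_equal(f$a, cfg0$outcome_model[["a"]], tolerance = 1e-8)
  expect_equal(f$b, cfg0$outcome_model[["b"]], tolerance = 1e-8)
  expect_equal(f$c, cfg0$outcome_model[["c"]], tolerance = 1e-8)
})

test_that("zero-noise outcomes are minimized at the dose nearest the vertex", {
  cfg <- sim_config(temp_noise_sd_c = 0, outcome_noise_sd = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  vertex <- -cfg$outcome_model[["b"]] / (2 * cfg$outcome_model[["c"]])
  hy <- merge(coh$doses, coh$outcomes[, c("animal_id", "total_path_cm3")],
              by = "animal_id")
  hy <- hy[hy$group == "hypothermia", ]
  expect_equal(hy$animal_id[which.min(hy$total_path_cm3)],
               hy$animal_id[which.min(abs(hy$auc34 - vertex))])
})

test_that("clipping at zero is counted", {
  cfg <- sim_config(outcome_model = c(0.01, 0, 0), outcome_noise_sd = 1, seed = 3)
  doses <- data.frame(animal_id = sprintf("a%d", 1:100),
                      group = "hypothermia", auc34 = 0)
  set.seed(3)
  out <- simulate_outcomes(doses, cfg)
  expect_true(all(out$outcome >= 0))
  expect_gt(attr(out, "n_clipped"), 20)
})

test_that("identical seed and config give byte-identical CSV artifacts", {
  cfg <- sim_config(n_control = 3, n_hypothermia = 4, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in c("temperatures.csv", "outcomes.csv", "provenance.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("cohort outcomes respect structural invariants", {
  coh <- simulate_cohort(sim_config(seed = 14))
  expect_true(all(coh$outcomes$largest_path_cm3 <= coh$outcomes$total_path_cm3 + 1e-12))
  expect_true(all(coh$outcomes$mri_pct >= 0 & coh$outcomes$mri_pct <= 100))
  expect_true(all(coh$temperatures$temp_c > 14.999 & coh$temperatures$temp_c < 40.001))
})

test_that("paired temperature/pO2 series exercise the correlation contract", {
  # noise-free: |r| is exactly 1 with the sign of the slope
  p <- simulate_temp_po2_series(50, slope = 3, intercept = -40, noise_sd = 0)
  expect_equal(as.numeric(pearson_r(p$temp_c, p$po2_mmhg)), 1)
  p2 <- simulate_temp_po2_series(50, slope = -3, intercept = 120, noise_sd = 0)
  expect_equal(as.numeric(pearson_r(p2$temp_c, p2$po2_mmhg)), -1)
  # zero slope: correlation vanishes at large n
  set.seed(21)
  p3 <- simulate_temp_po2_series(1e4, slope = 0, intercept = 60, noise_sd = 5)
  expect_lt(abs(pearson_r(p3$temp_c, p3$po2_mmhg)), 0.05)
  expect_error(simulate_temp_po2_series(2, 1, 0, 0), "n_points >= 3")
})
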