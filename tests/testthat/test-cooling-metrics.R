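test_that("AUC is a rectangle sum with the closed-form special cases", {
  # never below threshold: dose is exactly zero
  expect_identical(compute_auc(const_series(37), 34), 0)
  # one-term sum: 5 * (34 - 29)
  s1 <- temperature_series("p1", "hypothermia", 0, 29)
  expect_equal(suppressWarnings(compute_auc(s1, 34)), 25)
  # constant series closed form: 5 * 36 * (30 - 24)
  s36 <- const_series(24, group = "hypothermia", n = 36)
  expect_equal(compute_auc(s36, 30), 1080)
})

test_that("AUC matches a brute-force rectangle-sum oracle on random series", {
  set.seed(402)
  for (i in 1:1000) {
    n <- sample(36:40, 1)
    temps <- runif(n, 18, 39)
    s <- temperature_series(paste0("r", i), "hypothermia",
                            seq(0, by = 5, length.out = n), temps)
    thr <- runif(1, 25, 40)
    expect_identical(compute_auc(s, thr), oracle_auc(temps, thr))
  }
})

test_that("AUC is monotone in threshold and shifts linearly when all readings are below", {
  set.seed(7)
  temps <- runif(37, 20, 36)
  s <- temperature_series("m", "hypothermia", seq(0, 180, 5), temps)
  aucs <- vapply(seq(25, 40, by = 0.5), function(th) compute_auc(s, th), numeric(1))
  expect_true(all(diff(aucs) >= 0))
  # all readings below threshold 38: lowering every reading by delta adds 5*n*delta
  delta <- 1.25
  s_low <- temperature_series("m", "hypothermia", s$times, temps - delta)
  expect_equal(compute_auc(s_low, 38) - compute_auc(s, 38), 5 * 37 * delta)
  # and never more than that for any threshold
  for (th in c(26, 30, 34))
    expect_lte(compute_auc(s_low, th) - compute_auc(s, th), 5 * 37 * delta + 1e-9)
})

test_that("AUC input contract: bad thresholds error, short series warn", {
  s <- const_series(37)
  expect_error(compute_auc(s, 0), "threshold")
  expect_error(compute_auc(s, 45), "threshold")
  expect_warning(compute_auc(const_series(30, n = 10), 34), "< 36")
})

test_that("compute_dose reproduces the control convention and the step construction", {
  ctrl <- compute_dose(const_series(37))
  expect_equal(ctrl$auc34, 0)
  expect_equal(ctrl$auc30, 0)
  expect_equal(ctrl$temp_nadir, 37)
  expect_equal(ctrl$cooling_time, 0)
  expect_true(is.na(ctrl$time_below_30))

  st <- compute_dose(step_series(t_step = 40, low = 24), setup_time = 43)
  expect_equal(st$temp_nadir, 24)
  # cooling detected at the first sub-(baseline - 0.5) reading, t = 40,
  # which is also the first sub-30 reading
  expect_equal(st$time_below_30, 0)
  expect_equal(st$cooling_time, 140)
  expect_equal(st$total_time_to_below_30, 43 + 0)
  expect_equal(st$auc34, 5 * 29 * 10)   # 29 readings at 24 C, excursion 10
})

test_that("a series never below 30 reports time_below_30 as absent, not an error", {
  d <- compute_dose(step_series(low = 31))
  expect_true(is.na(d$time_below_30))
  expect_equal(d$auc30, 0)
  expect_gt(d$auc34, 0)
})

test_that("auc30 never exceeds auc34 and nadir bounds the series", {
  set.seed(88)
  for (i in 1:50) {
    temps <- runif(37, 18, 39)
    s <- temperature_series("x", "hypothermia", seq(0, 180, 5), temps)
    d <- compute_dose(s)
    expect_lte(d$auc30, d$auc34)
    expect_equal(d$temp_nadir, min(temps))
  }
})

test_that("dose summaries match a sort-based quartile oracle", {
  expect_equal(
    unlist(summarize_doses(data.frame(auc34 = 3), "auc34")[, c("median", "q1", "q3", "min", "max")]),
    c(median = 3, q1 = 3, q3 = 3, min = 3, max = 3))
  tab <- summarize_doses(data.frame(auc34 = c(1, 2, 3, 4, 5)), "auc34")
  expect_equal(tab$median, 3)
  expect_equal(tab$min, 1)
  expect_equal(tab$max, 5)

  set.seed(12)
  coh <- simulate_cohort(sim_config(seed = 12))
  hy <- coh$doses[coh$doses$group == "hypothermia", ]
  tab <- summarize_doses(hy)
  for (i in seq_len(nrow(tab))) {
    v <- hy[[tab$parameter[i]]]
    v <- v[is.finite(v)]
    expect_equal(tab$median[i], oracle_quantile7(v, 0.5))
    expect_equal(tab$q1[i], oracle_quantile7(v, 0.25))
    expect_equal(tab$q3[i], oracle_quantile7(v, 0.75))
  }
  expect_error(summarize_doses(data.frame()), "empty")
})

test_that("simulated cohort doses match independent re-summation of the CSV", {
  coh <- simulate_cohort(sim_config(n_control = 3, n_hypothermia = 5, seed = 31))
  tmp <- withr::local_tempdir()
  write_cohort(coh, tmp)
  csv <- read.csv(file.path(tmp, "temperatures.csv"))
  for (id in unique(csv$animal_id)) {
    sub <- csv[csv$animal_id == id, ]
    expect_equal(coh$doses$auc34[coh$doses$animal_id == id],
                 oracle_auc(sub$temp_c, 34))
    expect_equal(coh$doses$auc30[coh$doses$animal_id == id],
                 oracle_auc(sub$temp_c, 30))
    expect_equal(coh$doses$temp_nadir[coh$doses$animal_id == id],
                 min(sub$temp_c))
  }
})
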