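test_that("noise-free quadratics are interpolated exactly", {
  x <- c(0, 1, 2, 3, 4)
  f <- fit_quadratic(x, 1 - 2 * x + x^2)
  expect_equal(f$a, 1, tolerance = 1e-10)
  expect_equal(f$b, -2, tolerance = 1e-10)
  expect_equal(f$c, 1, tolerance = 1e-10)
  expect_equal(f$minimizing_dose, 1, tolerance = 1e-8)
})

test_that("linear data give c ~ 0 and no minimizing dose", {
  x <- c(0, 1, 2, 3, 5)
  f <- fit_quadratic(x, 3 + 0.5 * x)
  expect_lt(abs(f$c), 1e-10)
  expect_true(is.na(f$minimizing_dose))
  md <- minimizing_dose(f)
  expect_true(is.na(md))
  expect_match(attr(md, "reason"), "concavity")
})

test_that("rank-deficient or tiny designs are rejected", {
  expect_error(fit_quadratic(c(1, 1, 2, 2), c(1, 2, 3, 4)), "3 distinct")
  expect_error(fit_quadratic(1:3, 1:3), "n >= 4")
})

test_that("fast OLS kernel agrees with lm on random designs", {
  set.seed(55)
  for (i in 1:50) {
    x <- runif(20, 0, 1200)
    y <- 2 - 0.004 * x + 4e-6 * x^2 + rnorm(20, 0, 0.4)
    f <- fit_quadratic(x, y)
    k <- cooldose:::quad_ols(x, y)
    expect_equal(unname(k$coef), c(f$a, f$b, f$c), tolerance = 1e-9)
    expect_equal(k$vcov, f$vcov, tolerance = 1e-8)
  }
})

test_that("minimizing dose equals grid argmin for random convex fits", {
  set.seed(73)
  for (i in 1:25) {
    x <- runif(15, 0, 1000)
    y <- runif(1, 0.5, 3) - runif(1, 0.002, 0.006) * x +
      runif(1, 2e-6, 8e-6) * x^2 + rnorm(15, 0, 0.2)
    f <- fit_quadratic(x, y)
    if (is.na(f$minimizing_dose)) next
    lo <- min(x) - 500; hi <- max(x) + 500
    grid_min <- oracle_grid_argmin(f$a, f$b, f$c, lo, hi)
    expect_equal(f$minimizing_dose, grid_min, tolerance = (hi - lo) / 200000)
  }
})

test_that("shift and dose-rescaling equivariance", {
  set.seed(91)
  x <- runif(30, 0, 1200)
  y <- 2 - 0.004 * x + 4e-6 * x^2 + rnorm(30, 0, 0.3)
  f <- fit_quadratic(x, y)
  fs <- fit_quadratic(x, y + 5)
  expect_equal(fs$a, f$a + 5)
  expect_equal(fs$b, f$b)
  expect_equal(fs$c, f$c)
  expect_equal(fs$minimizing_dose, f$minimizing_dose)
  s <- 3.5
  fr <- fit_quadratic(s * x, y)
  expect_equal(fr$b, f$b / s)
  expect_equal(fr$c, f$c / s^2, tolerance = 1e-9)
  expect_equal(fr$minimizing_dose, s * f$minimizing_dose, tolerance = 1e-6)
})

test_that("fitted U grows surer with sample size under a U-shaped truth", {
  cfg <- sim_config(n_control = 200, n_hypothermia = 300, seed = 6)
  coh <- simulate_cohort(cfg)
  d <- impute_control_doses(merge(coh$doses,
                                  coh$outcomes[, c("animal_id", "total_path_cm3")],
                                  by = "animal_id"))
  f <- fit_quadratic(d$auc34, d$total_path_cm3)
  expect_gt(f$c, 0)
  expect_gt(f$c / f$analytic_se_c, 5)  # decisively convex at n = 500
})

test_that("bootstrap on noise-free data collapses to the point estimate", {
  x <- rep(c(0, 100, 300, 600, 900, 1100), 3)
  y <- 2 - 0.004 * x + 4e-6 * x^2
  bt <- bootstrap_quadratic(x, y, B = 300, seed = 2)
  for (nm in c("b_at_origin", "concavity_c", "minimizing_dose")) {
    iv <- bt$intervals[[nm]]
    expect_equal(iv$lower, iv$estimate, tolerance = 1e-9)
    expect_equal(iv$upper, iv$estimate, tolerance = 1e-9)
  }
  expect_equal(bt$intervals$minimizing_dose$estimate, 500, tolerance = 1e-6)
})

test_that("bootstrap is reproducible for a fixed seed and respects its contract", {
  set.seed(111)
  x <- runif(30, 0, 1200)
  y <- 2 - 0.004 * x + 4e-6 * x^2 + rnorm(30, 0, 0.4)
  b1 <- bootstrap_quadratic(x, y, B = 400, seed = 9)
  b2 <- bootstrap_quadratic(x, y, B = 400, seed = 9)
  expect_identical(b1$intervals, b2$intervals)
  expect_error(bootstrap_quadratic(x, y, B = 400), "seed")
  expect_error(bootstrap_quadratic(x, y, B = 100, seed = 1), "B >= 200")
  expect_error(bootstrap_quadratic(x[1:5], y[1:5], B = 400, seed = 1), "n >= 6")
  iv <- b1$intervals$minimizing_dose
  expect_lte(iv$lower, iv$estimate)
  expect_gte(iv$upper, iv$estimate)
  expect_lte(iv$n_degenerate, iv$n_replicates)
})

test_that("linear-truth data: c > 0 in about half the replicates, minimizer withheld", {
  set.seed(321)
  pos_frac <- replicate(60, {
    x <- runif(30, 0, 1000)
    y <- 1 + 0.001 * x + rnorm(30, 0, 0.3)
    bootstrap_quadratic(x, y, targets = "concavity_c", B = 200,
                        seed = sample.int(1e6, 1))$c_positive_fraction
  })
  expect_gt(mean(pos_frac), 0.3)
  expect_lt(mean(pos_frac), 0.7)

  # a decisively concave-down fit withholds the minimizer with a diagnostic
  set.seed(8)
  x <- runif(30, 0, 1000)
  y <- 1 + 0.004 * x - 4e-6 * x^2 + rnorm(30, 0, 0.2)
  bt <- bootstrap_quadratic(x, y, B = 300, seed = 5)
  expect_true(is.na(bt$intervals$minimizing_dose$lower))
  expect_false(is.null(bt$intervals$minimizing_dose$diagnostic))
})

test_that("predicted curve evaluates the quadratic and bands contain the fit", {
  set.seed(17)
  x <- runif(30, 0, 1200)
  y <- 2 - 0.004 * x + 4e-6 * x^2 + rnorm(30, 0, 0.4)
  bt <- bootstrap_quadratic(x, y, B = 400, seed = 3)
  f <- bt$fit
  expect_equal(predict_curve(f, 0)$fit, f$a)
  vx <- f$minimizing_dose
  expect_equal(predict_curve(f, vx)$fit, f$a - f$b^2 / (4 * f$c))
  grid <- seq(0, 1200, length.out = 50)
  pc <- predict_curve(f, grid, boot = bt)
  expect_true(all(pc$lower <= pc$fit & pc$fit <= pc$upper))
  expect_error(predict_curve(f, numeric(0)), "empty grid")
})
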