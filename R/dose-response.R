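# Quadratic dose-response: OLS fit, vertex inference, studentized bootstrap.

# Closed-form OLS for y ~ 1 + x + x^2. Returns coefficients, their
# covariance, residual SD and df, or NULL when the design is rank-deficient.
# Used in the bootstrap inner loop where lm() overhead would dominate.
quad_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x, x * x)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  coef <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(X, y))))
  resid <- y - drop(X %*% coef)
  df <- n - 3L
  sigma2 <- if (df > 0) sum(resid^2) / df else 0
  vcov <- chol2inv(ch) * sigma2
  list(coef = c(a = coef[1], b = coef[2], c = coef[3]),
       vcov = vcov, sigma = sqrt(sigma2), df = df)
}

# Delta-method SE of the vertex x* = -b/(2c):
# grad = (dx*/db, dx*/dc) = (-1/(2c), b/(2c^2)).
vertex_delta_se <- function(b, c, vcov_bc) {
  g <- c(-1 / (2 * c), b / (2 * c^2))
  v <- drop(t(g) %*% vcov_bc %*% g)
  if (v < 0) v <- 0
  sqrt(v)
}

#' Fit a quadratic dose-response curve by ordinary least squares
#'
#' Fits `E(Y|x) = a + b*x + c*x^2` with OLS, where `x` is the cooling dose
#' (AUC34 degree-minutes) and `Y` an injury outcome on its natural scale.
#' `b` is the change in outcome per unit dose at the origin (untreated vs
#' one-unit-treated animal), `c` the concavity (c > 0: U-shaped), and the
#' injury-minimizing dose is the vertex `-b/(2c)`, defined only when
#' `c > c_min`.
#'
#' @param dose Numeric dose values (degree-minutes).
#' @param outcome Numeric outcomes, same length.
#' @param c_min Positivity tolerance for the concavity below which the
#'   minimizer is reported absent (default 1e-12; a numerically-zero `c`
#'   from linear data must not produce a spurious vertex).
#' @return Object of class `quad_fit`: coefficients `a, b, c`, their
#'   analytic standard errors and covariance, `minimizing_dose` (`NA` when
#'   not U-shaped), `n`, `residual_sd`, and the underlying [stats::lm] fit.
#' @export
#' @examples
#' x <- 0:4; y <- 1 - 2 * x + x^2
#' fit_quadratic(x, y)$minimizing_dose  # 1
fit_quadratic <- function(dose, outcome, c_min = 1e-12) {
  ok <- is.finite(dose) & is.finite(outcome)
  dose <- dose[ok]; outcome <- outcome[ok]
  if (length(dose) < 4)
    stop("fit_quadratic: need n >= 4 complete observations", call. = FALSE)
  if (length(unique(dose)) < 3)
    stop("fit_quadratic: need >= 3 distinct dose values (rank-deficient design)",
         call. = FALSE)
  lmfit <- stats::lm(outcome ~ dose + I(dose^2))
  cf <- stats::setNames(unname(stats::coef(lmfit)), c("a", "b", "c"))
  # suppress summary.lm's "essentially perfect fit" chatter on noise-free data
  V <- unname(suppressWarnings(stats::vcov(lmfit)))
  se <- sqrt(diag(V))
  structure(list(
    a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
    analytic_se_a = se[1], analytic_se_b = se[2], analytic_se_c = se[3],
    vcov = V,
    minimizing_dose = if (cf[["c"]] > c_min) -cf[["b"]] / (2 * cf[["c"]]) else NA_real_,
    c_min = c_min,
    n = length(dose), residual_sd = suppressWarnings(stats::sigma(lmfit)),
    dose_range = range(dose), lm = lmfit
  ), class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("Quadratic dose-response fit (n = %d)\n", x$n))
  cat(sprintf("  a = %.4g (SE %.3g), b = %.4g (SE %.3g), c = %.4g (SE %.3g)\n",
              x$a, x$analytic_se_a, x$b, x$analytic_se_b, x$c, x$analytic_se_c))
  if (is.finite(x$minimizing_dose))
    cat(sprintf("  U-shaped (c > 0); minimizing dose %.1f degree-minutes\n",
                x$minimizing_dose))
  else
    cat("  not U-shaped (c <= 0); minimizing dose undefined\n")
  invisible(x)
}

#' Injury-minimizing dose of a fitted quadratic
#'
#' Solves `2*c*x + b = 0`: the vertex `-b/(2c)` when the concavity is
#' positive; absent (NA, with a `reason` attribute) otherwise -- absence is
#' a value, not an error.
#'
#' @param fit A `quad_fit` from [fit_quadratic()], or a list with `b` and
#'   `c` elements.
#' @return Degree-minutes, or `NA` with attribute `reason`.
#' @export
minimizing_dose <- function(fit) {
  c_min <- if (!is.null(fit$c_min)) fit$c_min else 1e-12
  if (!is.finite(fit$c) || fit$c <= c_min)
    return(structure(NA_real_,
                     reason = "concavity c <= 0: curve has no interior minimum"))
  -fit$b / (2 * fit$c)
}

#' Studentized bootstrap confidence intervals for the quadratic fit
#'
#' Ordinary non-parametric (pairs) bootstrap with studentized (bootstrap-t)
#' confidence intervals for the slope at the origin (`b_at_origin`), the
#' concavity (`concavity_c`) and the injury-minimizing dose
#' (`minimizing_dose`). Each replicate resamples (dose, outcome) pairs with
#' replacement and refits by OLS; the studentizing standard errors are the
#' analytic OLS SEs for b and c, and a delta-method SE for the vertex
#' (`SE^2 = g' V g` with `g = (-1/(2c), b/(2c^2))` and `V` the (b, c)
#' covariance block). Replicates whose resampled design has fewer than 3
#' distinct doses are discarded; replicates with `c <= c_min` are excluded
#' from the minimizer's distribution and counted as degenerate. When more
#' than half the usable replicates are degenerate the minimizer interval is
#' reported absent with a diagnostic. The fraction of replicates with
#' `c > 0` is reported as evidence of a U-shape.
#'
#' @param dose,outcome Numeric vectors (n >= 6).
#' @param targets Subset of `c("b_at_origin", "concavity_c",
#'   "minimizing_dose")`.
#' @param level Confidence level (default 0.95).
#' @param B Number of bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed (mandatory: bootstrap runs must be reproducible).
#' @param c_min Concavity positivity tolerance (default 1e-12).
#' @return Object of class `quad_boot`: the point fit, one
#'   `bootstrap_interval` per target (fields `estimate, lower, upper, level,
#'   n_replicates, n_degenerate, method`), `c_positive_fraction`, and the
#'   replicate coefficient matrix (for curve bands).
#' @export
bootstrap_quadratic <- function(dose, outcome,
                                targets = c("b_at_origin", "concavity_c",
                                            "minimizing_dose"),
                                level = 0.95, B = 2000, seed, c_min = 1e-12) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (missing(seed)) stop("bootstrap_quadratic: seed is required", call. = FALSE)
  ok <- is.finite(dose) & is.finite(outcome)
  dose <- dose[ok]; outcome <- outcome[ok]
  n <- length(dose)
  if (n < 6) stop("bootstrap_quadratic: need n >= 6", call. = FALSE)
  if (B < 200) stop("bootstrap_quadratic: need B >= 200", call. = FALSE)

  fit0 <- fit_quadratic(dose, outcome, c_min = c_min)
  se_b0 <- fit0$analytic_se_b
  se_c0 <- fit0$analytic_se_c
  x0 <- fit0$minimizing_dose
  se_x0 <- if (is.finite(x0))
    vertex_delta_se(fit0$b, fit0$c, fit0$vcov[2:3, 2:3]) else NA_real_

  set.seed(as.integer(seed))
  coefs <- matrix(NA_real_, B, 3)
  t_b <- t_c <- t_x <- rep(NA_real_, B)
  n_invalid <- 0L
  for (r in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- quad_ols(dose[idx], outcome[idx])
    if (is.null(f) || length(unique(dose[idx])) < 3) { n_invalid <- n_invalid + 1L; next }
    coefs[r, ] <- f$coef
    t_b[r] <- student_t(f$coef[["b"]], fit0$b, sqrt(f$vcov[2, 2]))
    t_c[r] <- student_t(f$coef[["c"]], fit0$c, sqrt(f$vcov[3, 3]))
    if (f$coef[["c"]] > c_min && is.finite(x0)) {
      xr <- -f$coef[["b"]] / (2 * f$coef[["c"]])
      t_x[r] <- student_t(xr, x0, vertex_delta_se(f$coef[["b"]], f$coef[["c"]],
                                                  f$vcov[2:3, 2:3]))
    }
  }
  n_used <- B - n_invalid
  alpha <- (1 - level) / 2

  ivl <- function(est, se, tstats, n_degenerate) {
    tq <- stats::quantile(tstats[is.finite(tstats)], c(1 - alpha, alpha),
                          names = FALSE, type = 7)
    res <- list(estimate = est, lower = est - tq[1] * se, upper = est - tq[2] * se,
                level = level, n_replicates = n_used,
                n_degenerate = n_degenerate, method = "studentized")
    if (is.finite(res$lower) && is.finite(res$upper) &&
        (res$lower > est || res$upper < est))
      message("studentized interval does not bracket the point estimate; reported as-is")
    structure(res, class = "bootstrap_interval")
  }

  out <- list()
  if ("b_at_origin" %in% targets) out$b_at_origin <- ivl(fit0$b, se_b0, t_b, 0L)
  if ("concavity_c" %in% targets) out$concavity_c <- ivl(fit0$c, se_c0, t_c, 0L)
  if ("minimizing_dose" %in% targets) {
    n_degen <- sum(is.na(t_x) & !is.na(coefs[, 1]))
    if (!is.finite(x0) || n_degen > n_used / 2) {
      out$minimizing_dose <- structure(
        list(estimate = x0, lower = NA_real_, upper = NA_real_, level = level,
             n_replicates = n_used, n_degenerate = n_degen,
             method = "studentized",
             diagnostic = if (!is.finite(x0))
               "point fit is not U-shaped (c <= c_min)"
             else sprintf("%d/%d replicates degenerate (c <= c_min); interval withheld",
                          n_degen, n_used)),
        class = "bootstrap_interval")
    } else {
      out$minimizing_dose <- ivl(x0, se_x0, t_x, n_degen)
    }
  }

  structure(list(fit = fit0, intervals = out,
                 c_positive_fraction = mean(coefs[, 3] > 0, na.rm = TRUE),
                 replicates = coefs[stats::complete.cases(coefs), , drop = FALSE],
                 B = B, n_invalid = n_invalid, level = level, seed = as.integer(seed)),
            class = "quad_boot")
}

# Studentized statistic with the zero-residual convention: exact refits of
# noise-free data give 0/0, which must collapse the interval to the point
# estimate rather than propagate NaN.
student_t <- function(est, ref, se) {
  d <- est - ref
  if (se == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / se
}

#' @export
print.quad_boot <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Bootstrap: B = %d (%d invalid), level %.0f%%, U-shape evidence P(c>0) = %.3f\n",
              x$B, x$n_invalid, 100 * x$level, x$c_positive_fraction))
  for (nm in names(x$intervals)) {
    iv <- x$intervals[[nm]]
    if (is.finite(iv$lower))
      cat(sprintf("  %-16s %.4g  [%.4g, %.4g]  (degenerate: %d)\n",
                  nm, iv$estimate, iv$lower, iv$upper, iv$n_degenerate))
    else
      cat(sprintf("  %-16s %s -- %s\n", nm,
                  if (is.finite(iv$estimate)) sprintf("%.4g", iv$estimate) else "absent",
                  if (!is.null(iv$diagnostic)) iv$diagnostic else "interval absent"))
  }
  invisible(x)
}

#' Fitted dose-response curve with pointwise bootstrap bands
#'
#' Evaluates `a + b*x + c*x^2` on a dose grid. When a [bootstrap_quadratic()]
#' result is supplied, pointwise percentile bands are taken across the
#' replicate curves and then widened (if needed) to contain the point-fit
#' curve at every grid point, so the band always covers the fit.
#'
#' @param fit A `quad_fit`.
#' @param grid Numeric dose grid (non-empty).
#' @param boot Optional `quad_boot` for bands.
#' @param level Band level (defaults to the bootstrap level or 0.95).
#' @return Data frame `dose, fit` and, with `boot`, `lower, upper`.
#' @export
predict_curve <- function(fit, grid, boot = NULL, level = NULL) {
  if (length(grid) == 0) stop("predict_curve: empty grid", call. = FALSE)
  yhat <- fit$a + fit$b * grid + fit$c * grid^2
  out <- data.frame(dose = grid, fit = yhat)
  if (!is.null(boot)) {
    if (is.null(level)) level <- boot$level
    alpha <- (1 - level) / 2
    reps <- boot$replicates
    G <- cbind(1, grid, grid^2)
    curves <- G %*% t(reps)                     # n_grid x n_replicates
    qs <- apply(curves, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    out$lower <- pmin(qs[1, ], yhat)
    out$upper <- pmax(qs[2, ], yhat)
  }
  out
}
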