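#' Pearson product-moment correlation
#'
#' Sample Pearson correlation with explicit preconditions: equal lengths of
#' at least 3 and non-zero variance in both vectors (a constant vector makes
#' the correlation undefined and raises an error rather than returning a
#' silent zero). Non-finite pairs are dropped pairwise.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`, with attribute `n`
#'   (pairs used).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("pearson_r: x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("pearson_r: need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("pearson_r: zero variance; correlation undefined", call. = FALSE)
  structure(stats::cor(x, y), n = length(x))
}

#' Fisher-z significance test for a Pearson correlation
#'
#' Tests `H0: rho = 0` by transforming with Fisher's z:
#' `z = atanh(r) * sqrt(n - 3)` is referred to the standard normal, giving
#' the two-sided p-value `2 * (1 - Phi(|z|))`. This is the normal-reference
#' Fisher test, not the t-based test of `cor.test`.
#'
#' @param r Pearson coefficient with `|r| < 1`.
#' @param n Number of pairs, `n >= 4`.
#' @return List `z, p`.
#' @export
#' @examples
#' fisher_z_test(0.48, 17)$p   # ~0.05
#' fisher_z_test(-0.59, 17)$p  # ~0.01
fisher_z_test <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("fisher_z_test: need |r| < 1 (|r| = 1 gives infinite z)", call. = FALSE)
  if (n < 4)
    stop("fisher_z_test: need n >= 4 for a finite test", call. = FALSE)
  z <- atanh(r) * sqrt(n - 3)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Impute control cooling doses by convention
#'
#' For whole-cohort correlations, control animals receive the conventional
#' dose characteristics AUC34 = 0, AUC30 = 0, cooling time = 0 and
#' temperature nadir exactly 37.0 degrees C.
#'
#' @param dose_outcome Joined doses + outcomes data frame with a `group`
#'   column.
#' @return The data frame with control rows imputed.
#' @export
impute_control_doses <- function(dose_outcome) {
  ctrl <- dose_outcome$group == "control"
  for (col in c("auc34", "auc30", "cooling_time"))
    if (col %in% names(dose_outcome)) dose_outcome[[col]][ctrl] <- 0
  if ("temp_nadir" %in% names(dose_outcome)) dose_outcome$temp_nadir[ctrl] <- 37
  dose_outcome
}

#' Correlation matrix between cooling parameters and outcomes
#'
#' One Pearson correlation per (cooling parameter, outcome) pair, each tested
#' with [fisher_z_test()]. With `cohort = "hypothermia"` only treated animals
#' enter (the within-cohort analysis); with `cohort = "all"` controls are
#' included with doses imputed by [impute_control_doses()] (the whole-cohort
#' analysis in which a U-shaped dose-response can reverse the correlation
#' signs). Rows with missing values are excluded pairwise; the count of
#' dropped rows is recorded per pair. Significance is flagged at p < 0.05,
#' unadjusted.
#'
#' @param dose_outcome Joined doses + outcomes data frame (needs `group`).
#' @param parameters Cooling-parameter column names (variable_x).
#' @param outcomes Outcome column names (variable_y).
#' @param cohort `"hypothermia"` or `"all"`.
#' @return Data frame `variable_x, variable_y, cohort, n, n_dropped, r, z,
#'   p, significant`.
#' @export
correlation_matrix <- function(dose_outcome,
                               parameters = c("auc30", "auc34", "cooling_time",
                                              "temp_nadir"),
                               outcomes = c("total_path_cm3", "largest_path_cm3",
                                            "mri_pct"),
                               cohort = c("hypothermia", "all")) {
  cohort <- match.arg(cohort)
  dat <- if (cohort == "all") impute_control_doses(dose_outcome)
         else dose_outcome[dose_outcome$group == "hypothermia", , drop = FALSE]
  missing <- setdiff(c(parameters, outcomes), names(dat))
  if (length(missing))
    stop("correlation_matrix: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  rows <- list()
  for (px in parameters) for (oy in outcomes) {
    x <- dat[[px]]; y <- dat[[oy]]
    ok <- is.finite(x) & is.finite(y)
    r <- pearson_r(x[ok], y[ok])
    ft <- fisher_z_test(as.numeric(r), attr(r, "n"))
    rows[[length(rows) + 1]] <- data.frame(
      variable_x = px, variable_y = oy, cohort = cohort,
      n = attr(r, "n"), n_dropped = sum(!ok),
      r = as.numeric(r), z = ft$z, p = ft$p,
      significant = ft$p < 0.05, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
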