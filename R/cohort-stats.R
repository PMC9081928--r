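#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided unpaired t-test with Welch's correction (Welch-Satterthwaite
#' degrees of freedom), the test used for control-vs-hypothermia outcome
#' comparisons. Thin wrapper over [stats::t.test()] with the degenerate
#' constant-data case handled by convention: if both groups have zero
#' variance and equal means, `t = 0, p = 1`.
#'
#' @param x,y Numeric outcome values for the two groups (each length >= 2).
#' @return List `t, df, p, mean_x, mean_y, n_x, n_y`.
#' @export
#' @examples
#' welch_t_test(c(1.9, 2.6, 1.0), c(0.8, 0.1, 1.3, 0.5))$p
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_test: each group needs >= 2 finite values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y),
                  n_x = length(x), n_y = length(y)))
    stop("welch_t_test: zero variance in both groups with unequal means",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y))
}

#' Per-group outcome summaries
#'
#' Median and quartiles per group and outcome, the "median (Q1-Q3)" layout
#' used for injury summaries, plus the Welch t-test p-value per outcome.
#' No multiple-testing adjustment is applied by default; `adjust = "holm"`
#' enables a Holm correction across outcomes.
#'
#' @param records Data frame with `group` and the outcome columns.
#' @param outcomes Character vector of outcome columns.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return Data frame `outcome, group, n, median, q1, q3, p_welch`
#'   (p repeated across the two group rows of an outcome).
#' @export
group_summary <- function(records,
                          outcomes = c("mri_pct", "total_path_cm3",
                                       "largest_path_cm3"),
                          adjust = "none") {
  outcomes <- intersect(outcomes, names(records))
  if (!length(outcomes)) stop("group_summary: no outcome columns found", call. = FALSE)
  groups <- unique(records$group)
  if (any(!table(records$group) >= 1) || length(groups) < 1)
    stop("group_summary: need at least one record per group", call. = FALSE)

  pvals <- vapply(outcomes, function(oc) {
    x <- records[[oc]][records$group == groups[1]]
    y <- if (length(groups) == 2) records[[oc]][records$group == groups[2]] else numeric(0)
    if (sum(is.finite(x)) >= 2 && sum(is.finite(y)) >= 2) welch_t_test(x, y)$p
    else NA_real_
  }, numeric(1))
  pvals <- stats::p.adjust(pvals, method = adjust)

  rows <- list()
  for (oc in outcomes) for (g in groups) {
    v <- records[[oc]][records$group == g]
    v <- v[is.finite(v)]
    if (!length(v)) stop("group_summary: empty group ", g, call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oc, group = g, n = length(v),
      median = q[2], q1 = q[1], q3 = q[3],
      p_welch = pvals[[oc]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
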