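#' Validate temperature and outcome tables
#'
#' Schema and range checks on the long-format temperature table and the
#' per-animal outcomes table: required columns, temperatures within
#' (10, 45) degrees C, non-negative volumes, MRI percent in [0, 100],
#' `largest_path_cm3 <= total_path_cm3`, recognised group labels, duplicate
#' animal ids in the outcomes table.
#'
#' @param temps_path Path to `temperatures.csv`.
#' @param outcomes_path Path to `outcomes.csv`.
#' @return Data frame `table, animal_id, issue` (zero rows when clean).
#' @export
validate_tables <- function(temps_path, outcomes_path) {
  issues <- list()
  add <- function(tbl, id, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      table = tbl, animal_id = id, issue = msg, stringsAsFactors = FALSE)

  for (p in c(temps_path, outcomes_path))
    if (!file.exists(p)) stop("validate_tables: cannot read ", p, call. = FALSE)
  temps <- utils::read.csv(temps_path, stringsAsFactors = FALSE)
  outc <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)

  need_t <- c("animal_id", "group", "probe", "time_min", "temp_c")
  for (col in setdiff(need_t, names(temps)))
    add("temperatures", NA, paste0("missing column: ", col))
  need_o <- c("animal_id", "group", "mri_pct", "total_path_cm3", "largest_path_cm3")
  for (col in setdiff(need_o, names(outc)))
    add("outcomes", NA, paste0("missing column: ", col))

  if (all(need_t %in% names(temps))) {
    bad <- which(!is.finite(temps$temp_c) | temps$temp_c <= 10 | temps$temp_c >= 45)
    for (i in bad)
      add("temperatures", temps$animal_id[i],
          sprintf("temperature %.1f C at t=%g outside (10, 45)",
                  temps$temp_c[i], temps$time_min[i]))
    badg <- unique(temps$animal_id[!temps$group %in% c("control", "hypothermia")])
    for (id in badg) add("temperatures", id, "unrecognised group label")
  }
  if (all(need_o %in% names(outc))) {
    for (i in which(outc$largest_path_cm3 > outc$total_path_cm3 + 1e-9))
      add("outcomes", outc$animal_id[i], "largest_path_cm3 > total_path_cm3")
    for (i in which(outc$mri_pct < 0 | outc$mri_pct > 100))
      add("outcomes", outc$animal_id[i], "mri_pct outside [0, 100]")
    for (i in which(outc$total_path_cm3 < 0 | outc$largest_path_cm3 < 0))
      add("outcomes", outc$animal_id[i], "negative pathology volume")
    dup <- unique(outc$animal_id[duplicated(outc$animal_id)])
    for (id in dup) add("outcomes", id, "duplicate animal_id")
    badg <- unique(outc$animal_id[!outc$group %in% c("control", "hypothermia")])
    for (id in badg) add("outcomes", id, "unrecognised group label")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(), animal_id = character(),
                  issue = character(), stringsAsFactors = FALSE)
}

#' Run the full cooling-dose analysis pipeline
#'
#' Orchestrates simulate (optional) -> cooling doses -> two-group comparison
#' -> correlation tables (hypothermia-only and all animals, with control
#' dose imputation) -> quadratic dose-response fits with studentized
#' bootstrap intervals, and writes every artifact plus a consolidated
#' markdown report. The run is a pure function of (inputs, config, seed):
#' identical configs give byte-identical outputs.
#'
#' @param config Named list (or path to a YAML/JSON file holding one) with
#'   elements: `out_dir` (required); either `simulate = TRUE` with an
#'   optional `sim` sub-list of [sim_config()] arguments, or `temps_path` /
#'   `outcomes_path` pointing at existing CSVs; `outcomes_to_fit` (default
#'   `c("mri_pct", "total_path_cm3")`); `bootstrap_B` (default 2000);
#'   `level` (default 0.95); `seed` (required).
#' @return Invisibly, a list with every intermediate table and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  if (is.null(config$seed)) stop("run_pipeline: config$seed is required", call. = FALSE)
  if (is.null(config$out_dir)) stop("run_pipeline: config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  B <- if (!is.null(config$bootstrap_B)) config$bootstrap_B else 2000
  level <- if (!is.null(config$level)) config$level else 0.95
  fit_outcomes <- if (!is.null(config$outcomes_to_fit)) config$outcomes_to_fit
                  else c("mri_pct", "total_path_cm3")

  # --- acquire data -------------------------------------------------------
  if (isTRUE(config$simulate) || is.null(config$temps_path)) {
    sim_args <- if (!is.null(config$sim)) config$sim else list()
    sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg)
    write_cohort(cohort, out_dir)
    temps_path <- file.path(out_dir, "temperatures.csv")
    outcomes_path <- file.path(out_dir, "outcomes.csv")
    doses <- cohort$doses
    outcomes <- cohort$outcomes
  } else {
    temps_path <- config$temps_path
    outcomes_path <- config$outcomes_path
    issues <- validate_tables(temps_path, outcomes_path)
    if (nrow(issues))
      stop("run_pipeline: input validation failed:\n",
           paste(utils::capture.output(print(issues)), collapse = "\n"),
           call. = FALSE)
    series <- series_from_table(utils::read.csv(temps_path, stringsAsFactors = FALSE))
    setup <- rep(NA_real_, length(series))
    if (!is.null(config$metadata_path) && file.exists(config$metadata_path)) {
      meta <- utils::read.csv(config$metadata_path, stringsAsFactors = FALSE)
      setup <- meta$setup_time_min[match(names(series), meta$animal_id)]
    }
    doses <- compute_doses(series, setup)
    outcomes <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("mri_pct", "total_path_cm3", "largest_path_cm3"),
                          names(outcomes))
  if (length(missing_cols))
    stop("run_pipeline: outcomes table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  utils::write.csv(doses, file.path(out_dir, "doses.csv"), row.names = FALSE)
  joined <- merge(doses, outcomes[, c("animal_id", "mri_pct", "total_path_cm3",
                                      "largest_path_cm3")], by = "animal_id")

  # --- analyses -----------------------------------------------------------
  dose_summary <- summarize_doses(doses[doses$group == "hypothermia", ])
  comparison <- group_summary(outcomes)
  cors_hypo <- correlation_matrix(joined, cohort = "hypothermia")
  cors_all <- correlation_matrix(joined, cohort = "all")
  utils::write.csv(rbind(cors_hypo, cors_all),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)

  fits <- list()
  dall <- impute_control_doses(joined)
  for (oc in fit_outcomes) {
    bt <- bootstrap_quadratic(dall$auc34, dall[[oc]], B = B, level = level,
                              seed = config$seed)
    grid <- seq(min(dall$auc34), max(dall$auc34), length.out = 101)
    curve <- predict_curve(bt$fit, grid, boot = bt)
    utils::write.csv(curve, file.path(out_dir, paste0("curve_", oc, ".csv")),
                     row.names = FALSE)
    fits[[oc]] <- bt
  }
  jsonlite::write_json(
    lapply(fits, function(bt) list(
      coefficients = list(a = bt$fit$a, b = bt$fit$b, c = bt$fit$c),
      minimizing_dose = bt$fit$minimizing_dose,
      intervals = lapply(bt$intervals, unclass),
      c_positive_fraction = bt$c_positive_fraction,
      n_invalid_replicates = bt$n_invalid)),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  jsonlite::write_json(
    split(comparison, comparison$outcome),
    file.path(out_dir, "group_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  report <- render_report(dose_summary, comparison, cors_hypo, cors_all, fits,
                          config$seed)
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(doses = doses, outcomes = outcomes, joined = joined,
                 dose_summary = dose_summary, comparison = comparison,
                 correlations_hypothermia = cors_hypo, correlations_all = cors_all,
                 fits = fits, out_dir = out_dir))
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package; use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

fmt_med <- function(m, q1, q3) sprintf("%.2f (%.2f-%.2f)", m, q1, q3)

render_report <- function(dose_summary, comparison, cors_hypo, cors_all, fits,
                          seed) {
  star <- function(p) ifelse(p < 0.05, "*", "")
  lines <- c(
    "# Cooling-dose analysis report",
    "",
    sprintf("Seed: %d", seed), "",
    "## Injury outcomes by group (median (Q1-Q3); Welch's t, unadjusted)", "")
  for (oc in unique(comparison$outcome)) {
    sub <- comparison[comparison$outcome == oc, ]
    cells <- vapply(seq_len(nrow(sub)), function(i)
      sprintf("%s %s", sub$group[i], fmt_med(sub$median[i], sub$q1[i], sub$q3[i])),
      character(1))
    lines <- c(lines, sprintf("- %s: %s; p = %.2g%s", oc,
                              paste(cells, collapse = " vs "),
                              sub$p_welch[1], star(sub$p_welch[1])))
  }
  lines <- c(lines, "", "## Cooling parameters (hypothermia animals)", "",
             "| parameter | median (Q1, Q3) | min, max |", "|---|---|---|")
  for (i in seq_len(nrow(dose_summary)))
    lines <- c(lines, sprintf("| %s | %.1f (%.1f, %.1f) | %.1f, %.1f |",
                              dose_summary$parameter[i], dose_summary$median[i],
                              dose_summary$q1[i], dose_summary$q3[i],
                              dose_summary$min[i], dose_summary$max[i]))
  cor_block <- function(tbl, title) {
    out <- c("", paste0("## ", title), "",
             "| parameter | outcome | n | r | p |", "|---|---|---|---|---|")
    for (i in seq_len(nrow(tbl)))
      out <- c(out, sprintf("| %s | %s | %d | %.2f | %.3f%s |",
                            tbl$variable_x[i], tbl$variable_y[i], tbl$n[i],
                            tbl$r[i], tbl$p[i], star(tbl$p[i])))
    out
  }
  lines <- c(lines,
             cor_block(cors_hypo, "Correlations, hypothermia cohort (Fisher z)"),
             cor_block(cors_all, "Correlations, all animals (controls imputed: AUC = 0, cooling time = 0, nadir 37 C)"),
             "", "## Quadratic dose-response fits (AUC34; studentized bootstrap CIs)", "")
  for (oc in names(fits)) {
    bt <- fits[[oc]]
    lines <- c(lines, sprintf("### %s", oc),
               sprintf("- coefficients: a = %.4g, b = %.4g, c = %.4g",
                       bt$fit$a, bt$fit$b, bt$fit$c),
               sprintf("- U-shape evidence: P(c > 0) = %.3f across replicates",
                       bt$c_positive_fraction))
    for (nm in names(bt$intervals)) {
      iv <- bt$intervals[[nm]]
      lines <- c(lines, if (is.finite(iv$lower))
        sprintf("- %s: %.4g, %.0f%% CI [%.4g, %.4g] (%d degenerate replicates)",
                nm, iv$estimate, 100 * iv$level, iv$lower, iv$upper, iv$n_degenerate)
        else sprintf("- %s: interval absent (%s)", nm,
                     if (!is.null(iv$diagnostic)) iv$diagnostic else "not U-shaped"))
    }
    lines <- c(lines, "")
  }
  lines
}
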