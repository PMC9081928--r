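#!/usr/bin/env Rscript
# Pearson correlations between cooling parameters and outcomes, tested via
# Fisher's z: once within the 17 treated animals, once across all 30 with
# controls imputed at AUC = 0, cooling time = 0, nadir 37 C. On the
# constructed U-shaped cohort the two tables disagree in sign -- the
# signature that motivates the quadratic model. Also the single-animal
# paired temperature / tissue-oxygen correlation.

suppressPackageStartupMessages(library(cooldose))

for (dir in c("results/cohort", "results/cohort_ushape")) {
  doses <- read.csv(file.path(dir, "doses.csv"))
  outcomes <- read.csv(file.path(dir, "outcomes.csv"))
  joined <- merge(doses, outcomes[, c("animal_id", "mri_pct", "total_path_cm3",
                                      "largest_path_cm3")], by = "animal_id")
  hypo <- correlation_matrix(joined, cohort = "hypothermia")
  all30 <- correlation_matrix(joined, cohort = "all")
  write.csv(rbind(hypo, all30), file.path(dir, "correlations.csv"),
            row.names = FALSE)
  cat("\n==", dir, "==\n")
  cat("Hypothermia cohort (n = 17):\n"); print(hypo, digits = 2)
  cat("All animals (n = 30, controls imputed):\n"); print(all30, digits = 2)
  r_h <- hypo$r[hypo$variable_x == "auc34" & hypo$variable_y == "total_path_cm3"]
  r_a <- all30$r[all30$variable_x == "auc34" & all30$variable_y == "total_path_cm3"]
  cat(sprintf("AUC34 vs total pathology: r = %.2f within treated, r = %.2f overall%s\n",
              r_h, r_a,
              if (sign(r_h) != sign(r_a)) "  <- sign reversal" else ""))
}

# paired temperature / pO2 series: parallel decline during cooling
set.seed(20240101)
pair <- simulate_temp_po2_series(25, slope = 2.2, intercept = -35, noise_sd = 4)
r <- pearson_r(pair$temp_c, pair$po2_mmhg)
ft <- fisher_z_test(as.numeric(r), attr(r, "n"))
write.csv(pair, "results/temp_po2.csv", row.names = FALSE)
cat(sprintf("\nTemperature vs pO2 (n = %d): Pearson r = %.2f, Fisher-z p = %.3g\n",
            attr(r, "n"), as.numeric(r), ft$p))
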