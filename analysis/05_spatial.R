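#!/usr/bin/env Rscript
# Spatial reproducibility: directional nearest-neighbor distances between
# cytotoxic (T_cyt) and regulatory (T_reg) T cells across the 15 replicate
# sections of the precision study. Reports per-section means, the
# cross-section CV per specimen, and the direction-asymmetry test.

suppressPackageStartupMessages(library(mifqc))
suppressPackageStartupMessages(library(dplyr))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config()
study <- simulate_precision_study(cfg, seed = seed)
gated <- gate_study(study, fit_local_thresholds(study))

rep <- distance_report(gated, "T_cyt", "T_reg")
dirs <- compare_directions(gated, "T_cyt", "T_reg")

write.csv(rep$sections, "results/05_nn_by_section.csv", row.names = FALSE)
write.csv(rep$cv, "results/05_nn_cv.csv", row.names = FALSE)
write.csv(rep$cv_by_run, "results/05_nn_cv_by_run.csv", row.names = FALSE)
write.csv(dirs, "results/05_direction_comparison.csv", row.names = FALSE)

cat("Cross-section CV of the mean nearest-neighbor distance (percent):\n")
print(rep$cv |> mutate(across(where(is.numeric), \(x) round(x, 1))))
cat("\nDirection comparison (pooled per-cell distances, Mann-Whitney):\n")
print(dirs |> mutate(across(where(is.numeric), \(x) signif(x, 3))))
cat("\nT_reg cells are the rarer phenotype, so the T_cyt -> T_reg distance\n",
    "is systematically the larger of the two directions; the estimates are\n",
    "nonetheless reproducible across sections and runs.\n")
if (length(rep$skipped_sections))
  cat("Sections skipped for missing phenotypes:",
      paste(rep$skipped_sections, collapse = ", "), "\n")
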