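#!/usr/bin/env Rscript
# Precision (reproducibility): intra-run vs inter-run CV of % positive cells
# in the 5-run x 3-replicate study, gated two ways on the *identical* cell
# tables: one fixed global threshold per marker, and per-run Otsu ("local")
# thresholds. The contrast isolates what re-thresholding buys back from
# batch-to-batch intensity variation.

suppressPackageStartupMessages(library(mifqc))
suppressPackageStartupMessages(library(dplyr))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config()
study <- simulate_precision_study(cfg, seed = seed)

glob <- gate_study(study, global_policy(default_global_thresholds(cfg$intensity)))
loc <- gate_study(study, fit_local_thresholds(study))

pr_g <- precision_report(glob)
pr_l <- precision_report(loc)

cvs <- bind_rows(
  pr_g$summary |> mutate(gating = "global"),
  pr_l$summary |> mutate(gating = "local"))
write.csv(cvs, "results/03_precision_cvs.csv", row.names = FALSE)
write.csv(bind_rows(pr_g$intra |> mutate(gating = "global"),
                    pr_l$intra |> mutate(gating = "local")),
          "results/03_precision_intra_by_run.csv", row.names = FALSE)
write.csv(loc$policy$thresholds, "results/03_local_thresholds.csv",
          row.names = FALSE)

wide <- cvs |>
  filter(specimen == "CT26") |>
  select(target, gating, intra_run_cv, inter_run_cv) |>
  tidyr::pivot_wider(names_from = gating,
                     values_from = c(intra_run_cv, inter_run_cv)) |>
  mutate(across(where(is.numeric), \(x) round(x, 1)))
cat("CT26 model, CV of % positive cells (percent):\n")
print(wide)
cat(sprintf(paste0(
  "Median intra-run CV: %.1f%% (global) vs %.1f%% (local).\n",
  "Median inter-run CV: %.1f%% (global) vs %.1f%% (local):\n",
  "re-thresholding per run removes the batch effect the global gate absorbs\n",
  "into the counts, without touching within-run agreement.\n"),
  median(pr_g$intra$cv_pct, na.rm = TRUE),
  median(pr_l$intra$cv_pct, na.rm = TRUE),
  median(pr_g$summary$inter_run_cv, na.rm = TRUE),
  median(pr_l$summary$inter_run_cv, na.rm = TRUE)))
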