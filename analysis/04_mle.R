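#!/usr/bin/env Rscript
# Multiplex labeling efficiency (MLE): per biomarker, the percentage of
# marker-positive cells that fall into a valid multi-marker T-cell
# phenotype. Computed on the high-density control specimen of the precision
# study under both gating strategies; a run is flagged when its mean MLE
# deviates from the study median by more than +/-10 points.

suppressPackageStartupMessages(library(mifqc))
suppressPackageStartupMessages(library(dplyr))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config()
study <- simulate_precision_study(cfg, seed = seed)

glob <- gate_study(study, global_policy(default_global_thresholds(cfg$intensity)))
loc <- gate_study(study, fit_local_thresholds(study))

mle_g <- mle_report(glob, control_specimen = "CT26")
mle_l <- mle_report(loc, control_specimen = "CT26")

write.csv(bind_rows(mle_g$sections |> mutate(gating = "global"),
                    mle_l$sections |> mutate(gating = "local")),
          "results/04_mle_sections.csv", row.names = FALSE)
write.csv(bind_rows(mle_g$markers |> mutate(gating = "global"),
                    mle_l$markers |> mutate(gating = "local")),
          "results/04_mle_by_marker.csv", row.names = FALSE)

cat("MLE across the 15 control sections (CT26), by gating strategy:\n")
print(bind_rows(mle_g$markers |> mutate(gating = "global"),
                mle_l$markers |> mutate(gating = "local")) |>
        select(gating, marker, median_mle, cv_mle) |>
        mutate(across(where(is.numeric), \(x) round(x, 1))))
cat(sprintf(paste0(
  "Flagged runs (mean MLE off the study median by > %d points): ",
  "%d under global gating, %d under local gating.\n"),
  mle_g$band, sum(mle_g$runs$flag), sum(mle_l$runs$flag)))
cat("A stable MLE across runs is the desk-side stand-in for a replicate\n",
    "precision study when only one control section per run is affordable.\n")
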