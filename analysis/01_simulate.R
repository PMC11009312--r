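#!/usr/bin/env Rscript
# Simulate the two serial-section study designs used throughout the
# analyses: the 5-run x 3-replicate precision study and the 5-section
# concordance (1-plex vs 4-plex) study, for three tumor models with high,
# medium and low T-cell density. Cell tables go to scratch/ (large); the
# design summary and ground-truth composition table go to results/.

suppressPackageStartupMessages(library(mifqc))
suppressPackageStartupMessages(library(dplyr))

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/studies", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config()  # 4 mm^2 field, CT26/4T1/B16F10 compositions

prec <- simulate_precision_study(cfg, seed = seed)
conc <- simulate_concordance_study(cfg, seed = seed)
write_study(prec, "scratch/studies/precision")
write_study(conc, "scratch/studies/concordance")

design <- bind_rows(
  prec$sections |> mutate(study = "precision"),
  conc$sections |> mutate(study = "concordance"))
write.csv(design, "results/01_study_design.csv", row.names = FALSE)

truth <- prec$cells |>
  left_join(prec$sections, by = "section_id") |>
  count(specimen, section_id, true_class) |>
  group_by(specimen, section_id) |>
  mutate(fraction = n / sum(n)) |>
  ungroup()
write.csv(truth, "results/01_ground_truth_composition.csv", row.names = FALSE)

cat("Precision study:", nrow(prec$sections), "sections,",
    nrow(prec$cells), "cells;",
    "run 1 holds serial sections",
    paste(sort(prec$sections$serial_index[prec$sections$run_id == "1" &
                 prec$sections$specimen == "CT26"]), collapse = ", "), "\n")
cat("Concordance study:", nrow(conc$sections), "sections;",
    "the 4-plex section sits at serial position",
    conc$sections$serial_index[conc$sections$assay == "multiplex"][1], "\n")
cat("Mean T-cell fraction per specimen:\n")
print(truth |>
  filter(true_class %in% c("T_cyt", "T_helper", "T_reg")) |>
  group_by(specimen, true_class) |>
  summarise(mean_fraction = round(mean(fraction), 4), .groups = "drop"))
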