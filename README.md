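# mifqc — validation statistics for multiplex immunofluorescence panels

Multiplex immunofluorescence (mIF) panels label several protein biomarkers
on one tissue section; per-cell image analysis then gates each marker and
calls combinatorial phenotypes (e.g. regulatory T cells as
CD3e+CD4+FoxP3+). Before such a panel is used in a study, two questions
must be answered quantitatively:

* **Accuracy (concordance)** — does the multiplex assay report the same
  % positive cells and mean intensity per biomarker as a 1-plex assay of
  the same biomarker on an adjacent serial section?
* **Precision (reproducibility)** — how much do % positive cells, derived
  phenotype fractions and cell–cell distance estimates vary across
  replicate sections within one staining run, and across runs?

`mifqc` implements the statistics of that validation workflow for anyone
who has per-cell segmentation exports (QuPath/HALO-style tables: centroid
coordinates in microns plus mean intensity per channel) and a study
manifest. It is aimed at imaging scientists and pathology labs qualifying
a panel, and ships a synthetic tissue-section generator so every analysis
is demonstrable and testable without slide scans.

## The statistics

* **Gating.** Cell `c` is positive for marker `m` iff
  `I(c, m) > t(s, m)`, strict, where the threshold scope `s` is either
  global (`*`, one fixed value per marker for all images) or a staining
  run (`local`). Local thresholds are recomputed per run by Otsu's
  method: 256 equal-width bins over the pooled per-cell intensity range,
  threshold at the bin edge maximizing the between-class variance
  `w0 w1 (mu0 - mu1)^2`. Min–max binning makes the threshold exactly
  scale-equivariant, so per-run multiplicative batch effects cannot move
  local-gated labels.
* **Coefficient of variation.** `CV = 100 * sd / mean` (sample sd),
  with a 25% working cutoff. Intra-run: CV across the replicate sections
  of one run. Inter-run: CV across all sections of all runs.
* **Concordance.** Bland–Altman relative difference
  `100 * (x_4plex - x_1plex) / ((x_4plex + x_1plex) / 2)`, with a ±20%
  working band and low-abundance annotation.
* **Multiplex labeling efficiency (MLE).** Per marker, the percentage of
  marker-positive cells falling into a valid multi-marker phenotype that
  includes the marker, e.g.
  `MLE(CD3e) = 100 * (#T_cyt + #T_helper + #T_reg) / #CD3e+` with
  T_helper counted as CD3e+CD4+FoxP3−. A batch-fidelity metric for runs
  without technical replicates; runs deviating more than ±10 points from
  the study median are flagged.
* **Spatial reproducibility.** Directional nearest-neighbor distances
  (the A→B distance is, per reference A cell, the Euclidean distance to
  the closest B cell), their per-section means, the cross-section CV,
  and a Mann–Whitney comparison of the two directions.

## Worked example

The numbered scripts under `analysis/` run the whole validation on
simulated studies (three tumor models of high/medium/low T-cell density,
5 runs × 3 replicate serial sections, per-run channel gains). For example
`Rscript analysis/03_precision.R` prints, for the high-density model:

```
CT26 model, CV of % positive cells (percent):
  target   intra_run_cv_global intra_run_cv_local inter_run_cv_global
1 CD3e                     2.2                2.1                17
2 CD4                      2.4                4.5                47.9
3 CD8a                     6.7                6.6                24.4
4 FoxP3                    9.3                6.1                42.5
5 T_cyt                    8.4                8.8                21.5
6 T_helper                 7.6                8.8                25.3
7 T_reg                   15.2               13.7                33.9
Median intra-run CV: 7.5% (global) vs 8.1% (local).
Median inter-run CV: 37.2% (global) vs 9.1% (local)
```

Read: with one fixed threshold per marker, replicate sections within a
run agree (intra-run CV well under 25%) but runs disagree wildly
(inter-run CV up to ~48%) because each run's staining intensity differs;
regating the *identical* cell tables with per-run Otsu thresholds
collapses the inter-run CV to ~9% without touching intra-run agreement.
`analysis/04_mle.R` shows the same contrast through the MLE (6 runs
flagged under global gating, 0 under local), and `analysis/05_spatial.R`
shows that mean T_cyt→T_reg nearest-neighbor distances are reproducible
across sections (CV well under 20%) while being direction-asymmetric
because T_reg cells are rarer.

In code, the same pipeline is three calls:

```r
library(mifqc)
study <- simulate_precision_study(simulation_config(), seed = 1)
gated <- gate_study(study, fit_local_thresholds(study))
precision_report(gated)$summary
```

or end to end with `run_validation_pipeline(pipeline_config(seed = 1), "out/")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline quantities from scratch by running the
code above: the two definitional MLE cases on constructed cell tables,
the median intra-run and inter-run CV of the simulated precision study
under global gating, the cross-section CV of the mean T_cyt→T_reg
nearest-neighbor distance, and the largest 1-plex vs 4-plex relative
difference for CD3e in the simulated concordance design, writing one JSON
object with one entry per quantity.
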