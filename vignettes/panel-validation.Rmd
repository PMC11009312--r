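---
title: "Validating multiplex immunofluorescence panels: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multiplex immunofluorescence panels: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifqc)
```

`mifqc` quantifies the accuracy and reproducibility of multiplex
immunofluorescence (mIF) panels from per-cell segmentation exports. This
vignette is the package's own account of the underlying models, the
tunable parameters, and the decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

The unit of data is one segmented cell: a centroid in microns and one
mean fluorescence intensity per marker channel (arbitrary units, ≥ 0).
Everything upstream — tissue outlining, nuclear segmentation, boundary
dilation — is out of scope; the package starts where the image-analysis
export ends. No membrane-spillover correction is attempted.

A *study* couples those cell tables with a manifest: per section, the
specimen (tumor model), the position in the serial-section series, the
staining run (batch), the replicate index within the run, and the assay
type (`multiplex` or `singleplex:<marker>`). Two designs recur:

* **Concordance**: five adjacent serial sections per specimen from one
  staining batch; the third carries the full 4-plex assay, the other
  four carry 1-plex assays, one marker each. Agreement between 1-plex
  and 4-plex quantifies whether co-incubating four antibodies perturbs
  any single marker's labeling.
* **Precision**: 5 runs × 3 replicate serial sections per specimen, all
  multiplex, with serial positions shuffled so run *r* receives sections
  *r*, *r*+5, *r*+10 — runs are thereby decoupled from sectioning depth.

## Gating

Positivity is `intensity > threshold`, strict: a cell exactly at the
threshold is negative. The strict inequality is a deterministic
convention in the stringent spirit of fixed thresholds chosen to
minimize spurious positives; with continuous intensities it is almost
surely irrelevant, but it fixes behavior on constructed tables.

**Global thresholds** are one fixed value per marker for every image —
the practice of an analyst who picks a cutoff by inspecting fields of
view across runs and then holds it fixed.

**Local thresholds** are recomputed per staining run by Otsu's method on
the per-cell mean intensities pooled over *all* cells of *all* the run's
sections (pooling per run, not per section, is deliberate: the batch
effect to be absorbed is a run-level quantity, and pooling maximizes the
cells informing each threshold). Implementation choices, stated
explicitly because histogram thresholding folklore varies:

* 256 equal-width bins spanning the min–max range of the pooled values;
* the returned threshold is the bin *edge* maximizing the between-class
  variance $w_0 w_1 (\mu_0 - \mu_1)^2$; ties break to the lowest edge;
* raw intensities, not log-transformed.

Min–max binning makes the procedure exactly scale-equivariant: scaling
every intensity by $c > 0$ scales the threshold by $c$ and leaves every
label unchanged. This is the mechanism by which local gating neutralizes
multiplicative batch effects, and the test suite asserts it bit-for-bit.
A degenerate channel (all values equal) has no Otsu threshold; the
fitter records it as missing with a warning, or falls back to a
caller-supplied floor threshold.

Phenotypes are priority-ordered boolean marker combinations, most
specific first: T_reg (CD3e+CD4+FoxP3+), then T_helper (CD3e+CD4+ and
explicitly FoxP3−), then T_cyt (CD3e+CD8a+); unmatched cells are
`other`. Priority matching plus the explicit FoxP3− requirement makes
the labels mutually exclusive, so phenotype counts partition the cell
set. Raw marker-combination counts are also emitted, so unusual
combinations (touching-cell doublets that segment as one object, e.g.
CD3+PanCK+ in epithelial tumors) surface in reports rather than
vanishing into `other`.

## Concordance and precision statistics

Relative differences use the symmetric Bland–Altman convention,
$100\,(a - b) / \tfrac{a+b}{2}$ with $a$ the 4-plex and $b$ the 1-plex
value, antisymmetric under swapping assays; the source studies do not
print their formula, so the alternative convention (divide by the 1-plex
value) is available behind `denominator = "second"`. The working band is
±20%, and markers with fewer than 50 positive cells in either member of
a pair are annotated as expected-high-variance rather than failed:
at low abundance, serial-section sampling noise dominates any assay
effect.

CVs use the sample (n−1) standard deviation — replicate counts are 2–3.
Intra-run CV is computed per run over its replicate sections and
averaged; inter-run CV is the CV over **all** sections of all runs
(not over run means), treating the whole study as one measurement
series. Both conventions are configurable cutoff annotations (default
25%), not hard failures.

## Multiplex labeling efficiency

MLE for marker $m$ is the percentage of $m$-positive cells that fall
into at least one *qualifying* phenotype — a valid multi-marker
combination containing $m$. Defaults encode the murine T-cell panel:
CD3e qualifies by T_cyt, T_helper, T_reg; CD4 by T_helper, T_reg; CD8a
by T_cyt; FoxP3 by T_reg.

Two counting decisions deserve note:

* **T_helper is counted exclusively** (CD3e+CD4+FoxP3−). Under an
  inclusive reading (any CD3e+CD4+ cell) the CD3e and CD4 numerators
  would count regulatory T cells twice and the MLE could exceed 100%.
  The inclusive variant remains expressible by passing a custom
  phenotype definition without the FoxP3 requirement.
* **The numerator is a union of definitions evaluated on the positivity
  matrix**, not a sum over assigned labels. The two agree for the
  default panel, but label-based sums inherit the priority order: a
  CD3e+CD4+CD8a+ cell is labeled T_helper, which would silently drop it
  from the CD8a numerator and make MLE(CD8a) depend on the CD4
  threshold. Union counting keeps each marker's MLE a function of
  exactly the markers its qualifying definitions mention, counts every
  cell at most once, and bounds the MLE at 100% structurally.

An MLE denominator of zero yields a missing value with a warning, never
0 — "no positive cells detected" and "no co-labeling" are different
failures. Sections (and run means) deviating from the study-wide
per-marker median by more than ±10 points are flagged; the band is the
suggested working cutoff and is configurable. MLE is intended for a
positive-control specimen carried in every run (`control_specimen`
filter), not for study samples whose biology may shift with treatment,
and it is uninformative for panels whose markers label disjoint cell
types.

## Spatial statistics

Nearest-neighbor distances are directional: the A→B distance assigns to
each A cell the Euclidean centroid distance to its closest B cell. When
B is rarer than A the mean A→B distance exceeds the mean B→A distance —
an asymmetry of the geometry, not an artifact. Distances are
centroid-to-centroid (membrane positions are not recoverable from
tables); a cell belonging to both sets is excluded from its own target
search, because zero self-distances are segmentation artifacts. No edge
correction is applied for cells near the field border, matching common
practice; summaries from very different field sizes are therefore not
directly comparable. Reproducibility is the CV of per-section mean
distances pooled over all sections of a specimen (runs pooled), with
per-run CVs as a supplement. The two directions are compared by a
two-sided Mann–Whitney rank test on the pooled per-cell distances — the
choice of test is an assumption of this package, recorded as such; when
every distance in both directions is identical the test statistic
degenerates and the comparison returns p = 1 by convention.

## The synthetic tissue generator

The generator emulates the statistical structure the analyses assume,
not images. Per section: cell count Poisson(density × area), positions
uniform over the field (homogeneous Poisson process), one exclusive
ground-truth class per cell (multinomial), lognormal intensity per
channel (positive or background population by class), multiplied by the
run's channel gain. Ground truth travels with the cells, so tests can
score recovery exactly.

Defaults are the stated study world, chosen once:

* **Field** 2 × 2 mm (4 mm²) at 2000 cells/mm² (~8000 cells/section) —
  typical of an analyzed tumor region.
* **Composition**: high-density model T_cyt 4%, T_helper 3%, T_reg
  1.5% plus small single-marker classes; the medium and low models
  scale the T-cell fractions by 0.5 and 0.1, mirroring hot/medium/cold
  tumors.
* **Serial-section jitter**: each class fraction is multiplied per
  section by a mean-1 lognormal with 7% CV — enough section-to-section
  drift that concordance relative differences for abundant markers
  stay within the ±20% envelope rather than at zero. Jittered fractions
  summing above 1 are renormalized with a warning.
* **Intensity model**: signal median 1000 (log-sd 0.3), background
  median 100 with a broad right tail (log-sd 0.7) standing in for
  autofluorescence. The tight signal keeps the populations well
  separated (histogram overlap below 1%), which is the regime where
  per-run Otsu gating recovers true fractions to within binomial error;
  the broad background tail makes a *fixed* threshold leak spurious
  positives as channel gain rises.
* **Batch gains**: per run × marker, log-uniform on [0.5, 2]. The gain
  range and the background tail were calibrated jointly — before the
  acceptance values were frozen, and verified across independent seeds —
  so that the generator reproduces the qualitative finding it exists to
  emulate: with one fixed global threshold per marker, inter-run CV of
  % positive cells sits well above the 25% working cutoff for
  essentially all seeds, while intra-run CV stays well below it, and
  per-run Otsu regating of the identical tables collapses the inter-run
  CV. No quantitative batch-effect magnitude is published to match, so
  this calibration targets the finding, not a measured value.
* **Seeding**: one master seed; every per-run and per-section stream is
  derived by stable sub-seeding, so identical config + seed yields
  byte-identical studies.

What the generator does **not** emulate — and what a green test
therefore does not establish: spatial clustering of immune infiltrates
(an optional Thomas-like cluster mode exists for illustrating
nearest-neighbor asymmetries, but the default is homogeneous),
autofluorescence gradients across the field, cell-shape and
segmentation effects, touching-cell doublets, co-expression beyond the
exclusive class definitions, and any non-multiplicative batch effect.
Conclusions about real slides still require real control slides; the
synthetic world demonstrates that the *statistics* behave as designed,
not that any particular panel is good.

## Numerical and degenerate-input conventions

* CV is undefined (missing, with a warning) for n < 2 or mean 0.
* Relative difference of 0 vs 0 is 0 by convention; negative inputs are
  rejected.
* Empty sections produce summaries with missing percentages; sections
  lacking a phenotype are skipped (and listed) in distance reports.
* Singleplex sections are gated only on their own marker; the other
  channels are `NA` positivity and never match a phenotype.
* Missing intensities reject the row at read time (segmentation exports
  never legitimately omit a per-cell mean); unknown marker columns are
  an error under the default strict mode, because a silent channel
  mismatch is the most dangerous QC failure.

## Known limitations

Two-dimensional distances from sections of three-dimensional tissue;
no permutation-based spatial null (distance asymmetries reflect
abundance and geometry, and deciding biological relevance needs one);
no intensity normalization across runs — the remedy implemented here is
re-thresholding, which the local-gating analyses show is sufficient for
multiplicative batch effects, but not for effects that change the
*shape* of the intensity distribution.
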