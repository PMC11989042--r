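---
title: "Quantifying proliferation and stemness organization in stratified squamous epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proliferation and stemness organization in stratified squamous epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratiquant)
```

## The analysis problem

Stratified squamous epithelium (esophagus, oral mucosa) is organized as a
basal cell layer attached to the basement membrane, one to two parabasal
layers above it, and differentiating suprabasal layers. Multiplex cyclic
immunofluorescence makes it possible to measure a dozen or more protein
markers in the same cells in situ, preserving the spatial context that
dissociation-based methods (scRNA-seq, flow cytometry) lose.
`stratiquant` turns a multichannel section image into per-cell,
per-marker statistics that describe how proliferation and stemness are
organized across those layers:

* In **humans**, the basal layer is a quiescent stem cell compartment:
  it expresses MECP2 and XPC highly (an abrupt, roughly 16-fold and
  5-fold drop, respectively, from basal to suprabasal cells) and shows
  little proliferation, while the parabasal (transit-amplifying)
  compartment proliferates.
* In **mice and rats**, proliferation is restricted to the basal layer
  and MECP2/XPC are low and flat (about 5-fold and 11-fold lower in
  mouse basal cells than in human basal cells).
* **Dogs** resemble humans and carry two basal subpopulations split by
  FTH1 expression.
* In the human **normal → dysplasia → carcinoma** progression, the
  MECP2–XPC proximity ligation signal (PLA puncta per cell) drops from
  normal basal cells through low- and high-grade dysplasia, with a
  recovery in carcinoma.

No public per-cell tables or images accompany these observations, so the
package ships a synthetic-section generator whose packaged profiles
*encode* the printed organization numbers. Every pipeline stage is then
testable end to end: the generator provides ground truth, and the
pipeline must recover the encoded values through segmentation, geometry
and gating — not merely read them back.

## Pipeline stages

1. **Segmentation** (`segment_nuclei()`, `extract_cell_table()`):
   Gaussian smoothing (sigma 1 px), global Otsu threshold,
   distance-transform watershed to split touching nuclei (merge
   tolerance of one distance unit, seed radius 2 px), removal of
   objects under 15 px, and re-attachment of watershed fragments below
   25 px to the nearest touching label. Per-cell expression is the
   *mean* intensity over the nuclear mask — each cell contributes one
   expression value per marker. The original workflow segmented cells
   manually; an algorithmic stand-in cannot reproduce expert judgement,
   so `read_label_tiff()` accepts externally produced masks and the
   whole downstream chain runs unchanged on them. Nuclear masks are
   used for all markers (the measured compartment is a documented
   divergence from a whole-cell reading).
2. **Membrane geometry** (`estimate_membrane()`, `assign_layers()`,
   `detect_delaminating()`): the basement membrane is the lower
   boundary of the thresholded structural-marker (KRT14) mask, one
   y-value per image column, smoothed with a running median (width 31).
   The signed distance `d = membrane_y(x) − y_cell` (positive above the
   membrane, in µm) assigns layers: stromal (`d < 0`), basal (`0 ≤ d ≤`
   one nucleus diameter, 3.6 µm at the packaged geometry), parabasal
   (two further diameters), suprabasal beyond. `d = 0` is basal: the
   boundary belongs to the epithelium. A **delaminating** cell is one
   whose mask still reaches within 3 px of the membrane but whose
   centroid sits more than half a median nucleus diameter above the
   local basal plane (the running median of basal centroid heights in a
   ±50 px window) — an operationalization of a definition that the
   source describes only verbally.
3. **Dual normalization** (`normalize_reference_protein()`,
   `normalize_to_stroma()`): per-cell division by histone H1 (the
   in-situ analogue of a housekeeping normalizer), and division by the
   per-section stromal median of the same marker (stromal cells as
   internal reference cells; the stromal median maps to 1 exactly).
   Both are invariant to global channel gain. Raw, H1- and
   stroma-normalized fold changes are all reported because the original
   figures use the normalizations interchangeably; the packaged
   profiles encode ratios at the raw-mean level and the recovery tests
   apply the same normalization to numerator and denominator.
4. **Gating** (`place_gate()`): the visual rule "the lowest level of
   expression of clearly positive cells" maps to the crossing of a
   two-component Gaussian mixture fitted to log intensities — the
   lowest value more likely positive than negative. Degenerate fits
   (component weight < 5 % or means closer than 0.25 log units) fall
   back to an Otsu threshold on log values and are tagged, with a
   warning. Gates are fitted on epithelial (non-stromal) cells.
   EGFR-"high" uses the same machinery: its upper mixture component is
   the "high" population.
5. **Quantification** (`capture_stats()`, `fold_change()`,
   `delamination_stats()`, `cluster_basal()`): basal capture
   percentages (how much of the basal layer a marker identifies),
   double-positive concordance (judged against basal *origin*, so a
   delaminating basal cell that has left the plane still counts),
   fold changes as ratios of group means *and* medians (the mean ratio
   is primary, because the generator encodes arithmetic-mean ratios and
   the printed fold changes do not state their estimator) with a seeded
   percentile bootstrap, delaminating-cell proliferation percentages,
   and seeded Gaussian-mixture clustering of basal cells with
   per-cluster medians so an FTH1-high/low split is identifiable.
6. **PLA** (`detect_puncta()`, `progression_summary()`):
   difference-of-Gaussians band-pass, local maxima above a prominence
   threshold with a 3 px minimum separation, assignment to the
   enclosing label or the nearest label within 2 px (puncta sit on the
   cell, not strictly inside the nucleus). Group summaries report
   median/IQR and Student's t-tests (equal variances) against normal
   basal cells, starred at p ≤ 0.05, with a Holm-adjusted column
   reported alongside but not used for starring — matching the original
   statistical conventions. When sample identifiers are available the
   tests run on per-sample means, the unit of the original
   quantification.

## The synthetic-section generator

`synthesize_section()` renders a 2-D section (physical sections are thin
enough that the original quantification is 2-D): a sinusoidal basement
membrane (amplitude 12 px, wavelength 500 px at baseline row 140), a
sparse stroma below it, one basal row, two parabasal rows and five
suprabasal rows above it, with a minimum nucleus spacing enforced
globally so nuclei never interpenetrate. Nuclei are uniform-intensity
discs (radius 3.2–4 px at 0.5 µm/px); the structural marker additionally
fills a cytoplasmic territory disc per epithelial cell, which produces
the contiguous epithelial band that membrane estimation needs.
Delaminating cells replace a fraction of basal slots and are rendered as
vertically elongated comet-shaped nuclei spanning from the membrane
upward — still membrane-connected, centroid displaced out of the basal
plane, which is exactly the signature the detector tests for. Per-cell
intensities are log-normal (CV 0.35) around per-layer mixture means;
positivity is Bernoulli per marker; PLA puncta are Poisson counts
rendered as Gaussian spots (sigma 1.1 px). Camera noise is Gaussian read
noise (SD 2) plus a signal-dependent term (variance 0.02 × signal), and
images are quantized to 16-bit integer counts — which also makes the
TIFF round trip exact.

The packaged profiles hard-anchor the printed organization numbers
(`inst/extdata/profiles.yaml` is the single editable source):

* human basal/suprabasal mean ratios: MECP2 1600/100 = 16, XPC
  660/132 = 5 (exact at the parameter level);
* human/mouse basal ratios: MECP2 1600/320 = 5, XPC 660/60 = 11;
* human basal positivity: XPC 0.8824, ITGB1 0.6706, KRT15 0.6353,
  EGFR-high 0.6235;
* human delaminating cells: 5 per 100 basal cells; MCM2/PCNA positive
  with probability 0.40, Ki67 0.20, PHH3 absent from the panel;
* mouse: proliferation probability exactly 0 outside the basal layer;
* dog: basal FTH1 mixture 800/100 (8-fold) at fraction 0.5.

All remaining parameters (variances, stromal levels, parabasal values,
non-printed positivity fractions) are plausible defaults chosen once:
stromal expression is present for every marker except TP63 (which is
epithelium-specific), parabasal XPC sits below the gate region so that
XPC double-positives are of basal origin (the reported concordance is
100 %), and monkey/rat/dog values interpolate the described qualitative
organization. The default field is 6000 × 210 px, giving ≥ 500 basal
cells per section (≈ 4,000 cells total) so that capture percentages are
stable; no source states cells-per-field, so this is a package choice.

**What the generator does not emulate.** Real sections have rete
ridges rather than a clean sinusoid, touching and overlapping nuclei in
3-D, cycle-to-cycle registration error, photobleaching, autofluorescence
structure, and biological covariance between markers beyond the encoded
mixtures. Passing recovery tests therefore demonstrates that the
*pipeline* is correct and unbiased under a faithful organization model —
not that segmentation or gating would reach the same accuracy on real
tissue. The segmentation stage in particular is exercised only against
the generator's nucleus model; on real images the external-mask route is
the benchmarked path.

## PLA progression design

The progression cohort simulator (`simulate_pla_cohort()`) uses the
quantified cohort sizes (25 normal, 14 LGD, 19 HGD, 9 SCC samples;
normal contributes basal and suprabasal groups) with per-cell Poisson
counts at the packaged rates (NB 6.0, NS 1.2, LGD 3.2, HGD 1.8,
SCC 5.7 puncta/cell) and a log-normal between-sample rate multiplier
(CV 0.3). Two design points deserve explanation:

* **The SCC rate encodes a recovery to near-normal.** The reported
  result is that the PLA signal drops significantly from normal basal
  cells to NS, LGD and HGD, but *not* to SCC, at these sample sizes. A
  t-test on 25-vs-9 samples cannot be non-significant if the SCC rate
  sat just above HGD's, so the carcinoma profile encodes the recovery
  as a return close to the normal rate while still exceeding HGD — the
  only parameterization consistent with the reported test pattern.
* **A null comparison is "significant" 5 % of the time by
  construction.** The replication property requires the three true
  reductions to test significant in every one of ten seeded cohorts,
  and the near-null SCC comparison to be non-significant in at least
  eight of ten with the recovery direction (SCC mean > HGD mean) in
  all — an exact "all ten" requirement on a null comparison would fail
  in roughly 40 % of honest replications at alpha = 0.05.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixels, x = column, y = row increasing
  downward; "above the membrane" is smaller y; output distances are in
  µm (pixel × 0.5 µm). CSVs document this convention.
* Membrane estimation interpolates across empty-column gaps up to
  50 px and errors on wider gaps, on images with no epithelial signal,
  and on images whose epithelial mask reaches the bottom almost
  everywhere (no stroma to normalize against).
* Membrane lookup uses half-up rounding of x, keeping distances
  invariant to integer horizontal translation (banker's rounding would
  break ties differently after a shift).
* Gating requires ≥ 50 values and errors on constant input; stromal
  normalization requires ≥ 20 stromal cells; clustering requires
  ≥ 20·k cells; all thresholds are arguments.
* Cells whose H1 intensity is non-positive are dropped from
  reference-protein normalization with a warning; delamination flags
  are `NA` (with a warning) where no basal cells exist in the local
  window; groups with fewer than two test units are excluded from
  t-tests with a warning.
* Bootstrap CIs, mixture fits, clustering and every generator draw are
  seeded; identical seeds give bit-identical sections and byte-identical
  pipeline reports.

## Problem sizes used by the tests and the acceptance script

Recovery runs use ten full-size sections per species (≥ 500 basal cells
each, ≈ 10 s per section to synthesize and analyze); unit and property
tests use 1500 px fields (≈ 135 basal cells, ≈ 1000 cells) or synthetic
fixtures built in code. The delamination proliferation percentage pools
roughly 250–300 delaminating cells across the ten sections, so its
binomial standard error is about 3 percentage points — recovered values
in the mid-to-high 30s against an encoded 40 % are expected behaviour,
and the ground-truth draw itself fluctuates by the same amount.

## Known limitations

* Nuclear masks stand in for whole-cell segmentation; membrane-bound
  markers (ITGB1, EGFR) are quantified at the nucleus in both the
  generator and the pipeline, which is internally consistent but not a
  claim about real staining geometry.
* The delamination detector depends on nuclear membrane contact; a real
  delaminating cell keeps contact through cytoplasm that a nuclear mask
  may not capture. The generator encodes the comet-shaped nuclear
  elongation that makes the definition recoverable from nuclear masks.
* Puncta counting undercounts at high spot density (overlapping puncta
  within the 3 px separation merge); at the encoded rates (≤ 6 per
  cell) this mainly affects the brightest cells, and the progression
  statistics are computed from simulated counts, not from rendered
  images.
* `venn_counts()` stops at five sets (the figure it mirrors uses up to
  five); larger collections need an upset-style summary.
* The marker-list consensus rule ("in at least two datasets of the
  species, absent from every list of the other") is one defensible
  reading of a selection rule whose exact membership computation is not
  published; `min_datasets` is an argument.
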