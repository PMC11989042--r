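# stratiquant

Single-cell, in-situ quantification of proliferation and stemness
organization in stratified squamous epithelium from multiplex
immunofluorescence section images.

Stratified squamous epithelia (esophagus, oral mucosa) stack a basal
stem cell layer on the basement membrane, parabasal layers above it and
differentiating suprabasal layers on top. Species differ sharply in how
proliferation and stemness markers are organized across those layers:
human basal cells form a quiescent, MECP2-high/XPC-high stem cell
compartment with proliferation shifted to the parabasal
(transit-amplifying) cells, while rodents confine proliferation to the
basal layer and express little MECP2/XPC. `stratiquant` is for
microscopists and computational biologists who want to turn multichannel
section images (or fully ground-truthed synthetic sections) into the
per-cell statistics behind such comparisons:

* nuclear segmentation (smoothing → Otsu → distance-transform
  watershed) and per-cell mean intensities, with an escape hatch for
  externally produced (e.g. manual) label masks;
* basement-membrane estimation from a structural channel (KRT14) and
  layer assignment by signed membrane distance
  `d = y_membrane(x) − y_cell` (stromal `d < 0`; basal within one
  nucleus diameter; parabasal within two more; suprabasal beyond);
* delamination detection — a cell whose mask still touches the
  membrane (within 3 px) while its centroid has moved more than half a
  nucleus diameter above the local basal plane;
* dual normalization: per-cell histone-H1 ratios (reference protein)
  and per-section stromal-median ratios (reference cells);
* positivity gating at the crossing of a two-component Gaussian
  mixture on log intensities (Otsu fallback for degenerate fits),
  basal-marker capture and double-positive concordance, fold changes
  (mean- and median-ratios with bootstrap CIs), delaminating-cell
  proliferation state, Gaussian-mixture clustering of basal
  subpopulations (e.g. the FTH1-high/low split in dog);
* PLA (proximity ligation assay) puncta counting per cell and
  normal → dysplasia → carcinoma progression statistics (median/IQR,
  Student's t vs normal basal, per-sample units, the carcinoma
  "recovery" flag);
* cross-dataset marker-list logic for scRNA-seq comparisons: consensus
  sets, species-specific sets, Venn region counts (TSV/GMT input).

A synthetic-section generator (`synthesize_section()`) renders
multichannel 16-bit sections with complete ground truth from packaged
species/condition profiles (`human`, `mouse`, `rat`, `monkey`, `dog`,
`human_lgd`, `human_hgd`, `human_scc`). The profiles encode the
organization numbers the analysis is known for — a 16-fold (MECP2) and
5-fold (XPC) basal→suprabasal drop in humans, 5-/11-fold human-over-
mouse basal ratios, basal capture fractions of 88.24 % (XPC), 67.06 %
(ITGB1), 63.53 % (KRT15), 40 % MCM2-positive delaminating cells — so
every stage can be validated by parameter recovery through the full
image-analysis chain.

## Worked example

```r
library(stratiquant)

hp <- default_profile("human")
section <- synthesize_section(hp, section_geometry(width = 1500), seed = 42)
section
#> <synthetic_section> profile 'human', seed 42
#>   1500 x 210 px, 15 channels: DNA, MECP2, XPC, TP63, ITGB1, KRT15, EGFR,
#>   FTH1, MCM2, PCNA, Ki67, KRT10_13, H1, KRT14, PLA
#>   cells: 975 (basal=136, parabasal=150, stromal=166, suprabasal=523),
#>   7 delaminating

ana <- analyze_section(section)      # segment -> membrane -> layers -> delamination
cells <- ana$cells

fold_change(cells, "MECP2", a = "basal", b = "suprabasal", seed = 42)
#> <fold_change> MECP2: basal / suprabasal
#>   mean ratio 15.1 (95% CI 14.1-16.2), median ratio 15.2
#>   n = 129 vs 523, means 1492 vs 98.62

gates <- gate_markers(cells, c("XPC", "ITGB1", "KRT15", "MCM2"))
capture_stats(cells, gates, markers = c("XPC", "ITGB1", "KRT15"))
#> <capture_stats> basal cells: 129
#>  marker n_basal n_positive percent
#>     XPC     129        115  89.15%
#>   ITGB1     129         81  62.79%
#>   KRT15     129         85  65.89%
#> double-positive pairs:
#>  marker_a marker_b n_double frac_double_basal
#>       XPC    ITGB1       76                 1
#>       XPC    KRT15       81                 1

delamination_stats(cells, gates)
#> <delamination_stats> 7 delaminating cells
#>  marker percent
#>    MCM2   42.9%
#>    PCNA     N/A
#>    PHH3     N/A
#>    Ki67     N/A
```

The fold change estimates the encoded 16-fold MECP2 drop from the
rendered image through segmentation, membrane geometry and layer
assignment (15.1 on this single small field; ten full-size sections
average within a few percent of 16). The capture table reads as "XPC
positivity identifies 89 % of the cells the geometry calls basal", and
every XPC/ITGB1 double-positive cell is of basal origin. Delaminating
cells are rare (≈ 5 per 100 basal cells), so their MCM2-positive
percentage is quoted from pooled sections in the full analysis.

Higher-level drivers: `run_pipeline()` executes configurable stages over
a seed list and writes cell tables (CSV) and a stats report (JSON);
`replicate_scenarios()` runs the five packaged study scenarios
(organization fold changes, basal capture, delamination, dog basal
clustering, PLA progression) and prints recovered-vs-encoded values.
`simulate_pla_cohort()` + `progression_summary()` reproduce the PLA
progression statistics on the quantified cohort design (25/25/14/19/9
samples).

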