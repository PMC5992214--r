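# retinaquant

Quantitative retinal biomarkers of Alzheimer's pathology from confocal
microscopy, for the 3xTg-AD mouse model.

The retina is accessible nervous tissue in which Alzheimer's-type changes —
amyloid-beta plaques, phospho-tau tangles, apoptotic ganglion neurons,
astrogliosis, and microglial activation — appear before cognitive symptoms.
This package implements the measurement pipeline for those readouts from
calibrated multi-channel confocal z-stacks, plus a seeded synthetic-stack
generator with exact ground truth so every operator can be validated
without animal data. It is aimed at groups quantifying immunofluorescence
in retinal (or brain) slices who want the whole chain — image operators,
single-cell morphometry, field-level measures, group statistics — scripted,
seeded, and tested.

## What it computes

| Readout | Definition |
|---|---|
| Microglia density | $n_{\text{cells}} / (A \cdot t) \times 10^9$ cells/mm³ for field area $A$ (µm²) and slice thickness $t$ (µm) |
| Neurodegeneration | caspase-3⁺ ganglion neurons as % of all ganglion neurons; a neuron is positive if a caspase punctum lies within 5 µm of its nucleus |
| Astrogliosis | thresholded GFAP area / total area |
| Morphometry | per-cell skeleton counts (branches, endpoints, junctions, triple junctions), soma area, arborization area (convex hull of process tips), and the morphological index = arborization/soma area |
| Aggregate volumetry | 3D 26-connected components; $V = n_{\text{vox}}\,dx\,dy\,dz$; equivalent diameter $(6V/\pi)^{1/3}$ with floors 0.58 µm (Aβ) / 0.68 µm (pTau); IL/OL layer assignment by centroid |
| Statistics | two-way (genotype × stage) type II ANOVA, Holm–Sidak step-down adjustment, Pearson correlation |

Skeletonization is homotopic Guo–Hall thinning (Rcpp) with junction-cluster
merging; thresholding offers Otsu (256-bin), fixed, and a robust
median + 8·MAD background mode for channels that may contain no signal.

## Worked example

```r
library(retinaquant)

# one synthetic 3xTg-like field with ground truth
pr <- stage_presets()
sp <- retinaquant:::preset_field_spec(pr[pr$genotype == "3xTg" & pr$stage == "pre", ],
                                      seed = 42)
f <- generate_field(sp)

# single-cell morphometry from the Iba1 projection
rec <- analyze_field_morphometry(max_projection(f$stack, "Iba1"))
colMeans(rec[, c("n_branches", "n_endpoints", "morphological_index")])
#>          n_branches         n_endpoints morphological_index
#>           27.500000           16.166667           25.327249

# field-level biomarker panel
sm <- summarize_field(f$stack, f$truth$ganglion_nuclei, f$truth$layer_boundaries)
sm$measurement
#>   n_microglia microglia_density_mm3 caspase_pct gfap_fraction n_abeta n_ptau
#> 1           6              78125.05    6.666667     0.2023062       3      3
```

The six cells average 27.5 skeleton branches and a morphological index of
~25 (ramified, surveilling phenotype); density is the 6 cells over the
160 × 160 µm × 3 µm field volume; 6.7% caspase⁺ is 2 of 30 ganglion
neurons; the GFAP fraction recovers the preset target 0.20; and three Aβ
plus three pTau aggregates pass the diameter floors — matching this
field's ground truth (`f$truth`) exactly.

The full study-shaped run (16 fields per genotype × stage, measurement
tables, ANOVA + pairwise CSVs, provenance block):

```r
report <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

A thin CLI over the same functions is installed at
`inst/cli/retinaquant.R` (`simulate | morphometry | quantify | stats | run`).

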