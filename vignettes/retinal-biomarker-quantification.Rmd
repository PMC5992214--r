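---
title: "Quantifying retinal biomarkers of Alzheimer's pathology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal biomarkers of Alzheimer's pathology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaquant)
```

## The measurement problem

In the 3xTg-AD mouse, Alzheimer's-type pathology is detectable in the
retina before cognitive symptoms appear: amyloid-beta plaques and
phospho-tau tangles deposit in the retinal ganglion cell layer, ganglion
neurons become cleaved-caspase-3 positive, astrocytes upregulate GFAP, and
microglia shift from a ramified surveilling morphology to an amoeboid
reactive one. Each of these is read out from multi-channel confocal
z-stacks of immunostained retinal slices, and each has a simple
quantitative definition:

* **Microglia density** — Iba1-positive cells per field, divided by field
  area times slice thickness, scaled by $10^9$ to cells/mm$^3$.
* **Neurodegeneration** — caspase-3-positive ganglion neurons as a
  percentage of all ganglion neurons in the slice; a neuron is positive
  when a caspase punctum lies near its nucleus.
* **Astrogliosis** — thresholded GFAP area divided by total area.
* **Microglia morphology** — per-cell skeleton metrics from the binarized,
  despeckled maximum-intensity projection: branch, endpoint, junction and
  triple-junction counts; soma area; the arborization (scanning-domain)
  area circumscribed by the distal process tips; and the **morphological
  index**, arborization area / soma area, which falls as microglia
  de-ramify.
* **Aggregate volumetry** — 3D connected components in the amyloid-beta and
  pTau channels, with volume $V = n_\mathrm{vox}\,dx\,dy\,dz$, equivalent
  spherical diameter $(6V/\pi)^{1/3}$, a minimum-diameter floor of 0.58 µm
  (amyloid-beta) or 0.68 µm (pTau), and assignment to the inner (IL) or
  outer (OL) retinal layer by centroid position.

Group comparisons across genotype (3xTg vs non-Tg) and disease stage
(pre-, early-, late-symptomatic) use two-way ANOVA with Holm–Sidak
step-down multiple-comparison adjustment; paired volume series are
summarized by the Pearson correlation.

The raw animal imaging underlying the published figures is not deposited,
so the package ships a seeded synthetic-stack generator with machine-
readable ground truth. Everything the measurement side computes can be
validated against what the generator actually drew.

## The synthetic generator

`generate_field()` renders a calibrated multi-channel stack (channel order
Hoechst, Iba1, GFAP, Casp3, Abeta, pTau) plus a ground-truth sidecar.

**Microglia** are random recursive bifurcating trees. Each of
`n_primary` processes owns an angular wedge around the soma; a tip at
depth $d$ bifurcates with probability `branch_prob` into two children
confined to the two halves of the parent wedge. This radial-wedge
construction guarantees subtrees never cross, so the rendered topology is
exactly the bookkept one — the property every skeleton test leans on.
Segment lengths are Gaussian with a floor of 2 µm and shrink geometrically
(`len_decay`, default 0.85) with depth. The soma is a disk rendered at
twice the process intensity, matching the empirical contrast that makes
manual soma outlining possible in real Iba1 stainings.

**Ganglion neurons** are nuclei placed in the IL band with a Bernoulli
caspase mark; positive nuclei get 1–2 perinuclear caspase puncta within
2.5 µm. **GFAP** is a random filament texture grown until a target area
fraction is reached (realized fraction recorded; guaranteed within ±0.02
of target). **Aggregates** are voxelized spheres with exact voxel-count
volumes recorded in the truth. **Noise** is Poisson shot noise on the
signal (`photon_scale`, default 20 photons per intensity unit) plus a
Gaussian background (mean 0.05, sd 0.02), the standard fluorescence model.

All randomness flows from one integer seed through a splitmix64
counter-based splitter (`rng_child_seed`), so per-object draws are
independent of iteration order and any single field of a series can be
regenerated in isolation.

### What the generator does and does not emulate

It reproduces the statistical structure the pipeline assumes: dark
background, bright connected cells, punctate caspase signal, filamentous
GFAP, blob-like aggregates in distinct layers, shot + background noise.
It does **not** simulate the optical PSF, vasculature, uneven
illumination, photobleaching, or anatomically realistic layer geometry
(layers are flat horizontal bands). Passing tests therefore demonstrate
correctness of the measurement operators under the stated model, not
robustness to every artifact of real microscopy; in particular the
automatic thresholds should be re-examined on real data where staining
background varies across a slice.

### Stage presets

`stage_presets()` fixes one parameter set per (genotype × stage) cell,
chosen once to mirror the study's qualitative findings: 3xTg microglia
more ramified than non-Tg at pre-stage (5 primaries, depth 3, branch
probability 0.8 vs 4/2/0.6) and less ramified at late stage (3/2/0.25,
shorter segments); equal microglia counts except late-stage 3xTg
(11 vs 6 cells per field); caspase probability rising 0.06 → 0.10 → 0.14
in 3xTg against 0.02 in non-Tg; GFAP fraction 0.20/0.22/0.12 vs 0.10; and
aggregates only in 3xTg — IL-only at pre-stage (3 per channel, r = 0.7 µm),
IL+OL and larger from early stage on. Default series geometry is a
160 × 160 µm field, 6 slices at the acquisition z-step of 0.5 µm, and
0.3 µm lateral pixels (a realistic confocal sampling at which a 3-px
stroke is a ~1 µm process); 16 fields per condition match the study's
per-condition sample size. The generic `field_spec()` default of 0.1 µm
lateral pixels is a stated assumption — the acquisition pixel size is not
reported — and is used for the fine-scale volumetry checks.

## Numerical and design choices

**Skeletonization** is Guo–Hall two-subiteration homotopic thinning with a
cleanup pass that removes 2×2-block pixels whose deletion preserves local
connectivity. An irreducible 2×2 block remains exactly when four branches
of an X-crossing attach to its four pixels; no homotopic thinner can
reduce it, so `build_skeleton_graph()` treats such blocks as junction
pixels (they merge into one junction node) and reserves the non-thin
error for a fully filled 3×3 neighbourhood, which genuinely thick input
always contains.

**Junction merging.** Thinning a stroke several pixels wide can split one
topological junction into two clusters bridged by a one-or-two-pixel slab
path, or leave a pixel-scale loop. Junction–junction branches shorter
than `merge_junctions_um` (default 1 µm) are contracted. The scale is
safe because generated (and real) inter-junction process segments are
several micrometres long; set it to 0 to disable. With merging, exact
topology recovery on 100 seeded cells at stroke widths 3–7 px is 98%;
without it, 43%.

**Soma segmentation.** The manual freehand outline is automated as the
bright in-mask intensity mode: in-mask intensities are split by Otsu's
criterion and the largest bright component, morphologically closed, is
the soma. A fixed high quantile (the original design) is available via
`core_quantile`, but a quantile threshold moves with the soma-to-process
pixel ratio — which varies systematically with ramification — and under
shot noise it collapsed the soma of ramified cells to a few bright
pixels, inverting the morphological-index ordering. The bimodal split
measures a 3 µm disk to within a few percent of $\pi r^2$ regardless of
tree size.

**Thresholding.** `binarize()` implements strict `>` thresholding (so
fixtures are bit-exact) with Otsu's method on a 256-bin histogram as the
automatic default, a fixed mode preserving the study's manual-threshold
workflow, and a robust mode (median + 8·MAD of the background). The
robust mode is the default wherever a channel may contain *no* signal —
caspase puncta, aggregate channels, and Iba1 cell segmentation — because
Otsu's criterion always splits the histogram somewhere: on a pure-noise
channel it declares half the noise foreground, and with very sparse
foreground it splits soma from processes instead of signal from
background. Otsu remains the default for GFAP area fraction, where signal
is always present. `detect_aggregates()` computes one global threshold
and applies it to every slice; a per-slice automatic threshold would be
undefined on empty slices.

**Aggregate floors.** The minimum-diameter floor is applied to the
equivalent spherical diameter, which is rotation-invariant and well
defined for arbitrary component shapes; defaults are the channel-specific
0.58/0.68 µm detection floors. Volumes are always computed in µm³ from
anisotropic voxel dimensions, never in voxel counts.

**Caspase positivity** uses a 5 µm perinuclear proximity radius
(configurable), an operationalization of "localization near the cell
nucleus".

**Two-way ANOVA** is computed from sums of squares of nested least-squares
fits (type II: $SS_A = RSS(B) - RSS(A+B)$, etc.), which reduces to the
textbook decomposition on balanced designs and stays well defined on
unbalanced ones; p-values come from `pf()`, i.e. the regularized
incomplete beta function. A zero-residual-variance design returns F = 0
for null effects rather than 0/0. Holm–Sidak is the closed-form step-down
$\tilde p_{(i)} = \max_{j \le i}\min\{1, 1-(1-p_{(j)})^{m-j+1}\}$.
Pairwise comparisons are emitted for both plausible families — across
stages within genotype and between genotypes within stage — each adjusted
within its own family, since the original analysis does not state which
family was adjusted.

**Degenerate inputs.** Constant images error under Otsu with a pointer to
fixed thresholding; empty ROIs, inestimable ANOVA designs (named empty
cells), p-values outside [0, 1], zero-variance correlations, and
non-positive calibrations all raise informative errors. Soma-only cells
yield all-zero topology counts; cells with two endpoints and no junction
(a single process) are retained as valid.

**Problem sizes.** The shipped configuration analyzes 96 fields
(16 × 6 conditions) of 533 × 533 px × 6 slices × 6 channels per run,
~100 synthetic cells for topology validation, and 5000 replicates for the
type-I-error calibration; these sizes were chosen so a complete
validation run finishes in minutes on a laptop while keeping per-group
sample sizes at the study's own n.

## Resumability and provenance

`run_pipeline()` streams simulation and measurement field by field (at
most one stack in memory), writes per-stage CSV tables, and stores a
provenance block with the config hash, seed, package version and every
resolved parameter — the manual-threshold step being the main
reproducibility hazard in the original workflow, every threshold actually
used is logged. A rerun with a matching config hash reuses the
measurement tables and recomputes statistics; intermediate stacks are not
persisted by default because they are cheap to regenerate from the seed
(use `generate_stage_series(out_dir = ...)` to keep TIFFs).

## Known limitations

* 2D morphometry on maximum projections, as in the original procedure —
  processes crossing in z are merged; no 3D tracing or Sholl analysis.
* The arborization polygon is the convex hull of skeleton endpoints, the
  tightest convex analog of a manual polygon tool; concave arbors are
  over-covered.
* Whether "total processes" means all skeleton branches or only primary
  processes is ambiguous in the field's usage; both `n_branches` and
  `n_primary` (branches incident to the soma region) are reported.
* Aggregate volumetry assumes 3D stacks; whether published plaque
  "volumes" derive from 3D labeling or projected area × depth is not
  stated, so the mode is recorded in configuration.
* The per-stage published correlation coefficients aggregate means over
  age windows of undeposited data and cannot be recomputed; the package
  provides the estimator only.
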