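---
title: "Segmenting demyelinating lesions by their lipid fingerprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting demyelinating lesions by their lipid fingerprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidseg)
```

## The analysis problem

Focal injection of lysophosphatidylcholine (LPC) into mouse spinal cord
produces a demyelinating lesion with a characteristic architecture: a
fully demyelinated lesion core, a surrounding peri-lesion ring populated
by activated microglia/macrophages where demyelination is ongoing, and
uninvolved white and grey matter. Negative-mode MALDI imaging mass
spectrometry (10 µm/pixel, m/z 550–1000) measures one lipid mass spectrum
per tissue pixel; the question is whether each histological domain
carries a reproducible lipid fingerprint, and whether that fingerprint
can be isolated *computationally*, by clustering pixels on their spectra
alone.

`lipidseg` implements the full chain: spectral preprocessing, divisive
correlation-based segmentation with recursive re-segmentation,
region-fingerprint statistics, and m/z-based lipid annotation — together
with a synthetic, ground-truth-labelled section generator so every stage
is testable end to end without instrument data.

## Preprocessing

The reduction chain is: **align → TIC-normalize → average → pick peaks →
reduce**.

* **Alignment** (`align_spectra`). Each pixel's spectrum is given a rigid
  parts-per-million shift, estimated by maximizing normalized
  cross-correlation against the cohort mean spectrum over a grid
  (default ±10 ppm in 0.5 ppm steps) with parabolic sub-grid refinement,
  in two passes (the reference is recomputed from corrected spectra
  between passes). Estimates under half a grid step are snapped to zero
  so already-aligned spectra are never resampled. Two caveats are
  inherent to mean-referenced alignment: a drift common to all pixels is
  unobservable, and estimates saturate (and are flagged) at the search
  bound.
* **TIC normalization** (`tic_normalize`) scales each pixel to unit
  summed intensity; all-zero pixels are flagged rather than failing.
* **Peak picking** (`pick_peaks`) operates on the average spectrum only:
  local maxima after 3-point moving-average smoothing, kept when the
  apex exceeds 0.5 % of the base peak (`threshold_fraction = 0.005`).
* **Reduction** (`reduce_cube`) extracts, per pixel and peak, the maximum
  intensity within ±5 ppm of the peak centre (`tol_ppm`, matching an
  instrument resolution of ~60,000); overlapping windows resolve to the
  nearest centre.
* **Tissue detection**: pixels are kept when their pre-normalization TIC
  exceeds Otsu's threshold on log-TIC (a fixed-quantile rule is also
  available); a unimodal guard keeps everything when there is no
  background mode.

## DHC-RC segmentation

Segmentation is divisive hierarchical clustering with rank-competing
random walkers. A split works on the pixel–pixel Pearson correlation
matrix of the fingerprint image:

1. **Seeds**: the globally least-correlated pixel pair, plus restarts
   (half drawn from the bottom 1 % of pair correlations, half uniformly);
   for small sets every pair is tried.
2. **Rank-compete growth**: two walkers repeatedly claim the unassigned
   pixel with the highest mean correlation to their current region.
3. **Polish**: single-move hill climbing on the objective
   *mean within-group correlation − mean between-group correlation*
   (within-pairs pooled across both groups).
4. The best bipartition over all seed candidates wins; ties break to the
   lowest pixel index, so runs are deterministic given the seed.

Two design choices deserve explanation because the verbal description of
the algorithm leaves them open:

* **Feature standardization.** Raw TIC-scaled fingerprints of *all*
  tissue pixels correlate above ~0.85 simply because they share the
  overall lipid profile; the dynamic range left for region contrast is
  small. `dhc_rc_segment` therefore z-scores each peak across pixels
  before computing correlations (`walker_config(standardize = TRUE)`).
  Mean fingerprints and colours always come from the unstandardized
  features. Because standardization is recomputed *within the selection*
  on `resegment`, isolating the lesion and re-analysing it genuinely
  increases the contrast between core and margin — this is the
  mechanistic reason the segregate-and-re-analyse strategy resolves the
  peri-lesion ring that a deeper initial segmentation would scatter.
* **Which leaf to split next.** The classical rule — split the leaf with
  the lowest mean within-correlation — systematically prefers the
  *largest homogeneous* region: its standardized mean sits nearest the
  image mean, so its within-correlation is noise-dominated and low, and
  white matter ends up split into meaningless fragments while a mixed
  core+margin segment survives. The default is therefore a greedy gain
  rule: tentatively split every splittable leaf and commit the split
  with the highest objective. The classical rule remains available as
  `walker_config(select = "cohesion")`.
* **Minimum segment size.** The mean-correlation objective can always be
  inflated by peeling a handful of outlier pixels into a micro-segment.
  Bipartitions leaving a side below 15 % of the set being split are
  rejected (`min_size_frac`), reflecting that tissue domains are
  substantial; sets of ≤ 20 pixels are split unconstrained, which keeps
  the small-instance behaviour identical to exhaustive search.

Colours follow the correlation-ordered scale: the two segments with the
least-correlated mean fingerprints take the ends of the colour bar (0
and 1) and the rest are placed by a one-dimensional embedding along the
line through those extremes, so colour proximity encodes fingerprint
similarity.

Above 20,000 retained pixels (`max_exact`) the split runs exactly on a
seeded subsample and remaining pixels join the segment whose mean
fingerprint they correlate with best; all analyses in this package's
tests are below that threshold and therefore exact.

## Region statistics

`region_fingerprint` averages the annotated-species intensities over a
region's pixels and renormalizes to relative abundances. Downstream:

* **Comparisons** (`compare_regions`): two-sided Welch t-tests *across
  sections* — animals, not pixels, are the unit of replication, since
  pixel-level tests would inflate significance by five orders of
  magnitude. Stars follow the printed convention `*` p < 0.05, `**`
  p < 0.01, `***` p < 0.0001 (the unusual third threshold is applied as
  printed; `star_code` accepts an override). No multiple-testing
  correction is applied to the stars; a Benjamini–Hochberg column is
  emitted alongside.
* **PCA** (`pca_scores`): mean-centred, unscaled by default; component
  signs are fixed (largest-magnitude loading positive) so score plots are
  reproducible.
* **Classification** (`classify_regions`): a 500-tree random forest with
  sqrt(p) features per split, evaluated strictly out of fold with
  leave-one-section-out cross-validation (all three regions of a held-out
  section leave together, so no animal contributes to both training and
  test). Precision, sensitivity and one-vs-rest specificity derive from
  the pooled out-of-fold confusion matrix, which is stored in the report.

## Annotation

Peaks are matched against a bundled library of 45 species over the
classes PC, PC-E (ether), PE, PE-E, PI, PS, PG, SM and sulfatide (ST),
as deprotonated `[M−H]⁻` ions within ±5 ppm. Masses are computed from
class backbone compositions (diacyl glycerophospholipids; d18:1-type
sphingoids; ether species −O +2H) and verified in the tests against an
independent atomic-mass summation to < 0.5 mDa. Negative mode keeps the
adduct table to `[M−H]⁻` alone. All annotations carry confidence tier
`"mz-only"`; PS matches additionally carry a caution flag because PI
fragmentation overlaps the PS m/z region, and direct PS/PI co-matches
are flagged on both candidates.

## The synthetic section generator

`build_phantom` rasterizes a parametric section: an elliptical tissue
area, a ventral grey-matter band, and an elliptical lesion core wrapped
by a peri-lesion ring, with seeded jitter of the lesion centre and axes
so replicate "animals" have heterogeneous lesion geometries. Region
templates (`default_region_templates`) assign each region a
relative-abundance vector over the simulated species with the
demyelination trend directions: PC, PE, SM and PI (above all PI 38:4)
rise toward the core; ether-PC, sulfatides and PS fall; PE-E species
split (36:2e/40:6e down, 38:6e/38:7e/40:7e up, 36:5e maximal in the
ring); PG remodels; grey matter is PI-rich and sulfatide-poor.

Two calibration choices define the synthetic study conditions:

* **Core contrast.** The core is *completely* demyelinated, so its fold
  changes are strong (ST 0.25×, ether-PC 0.4×, PC 2.2×, PE 2.0×, SM
  2.2×, PI 38:4 3.0× vs white matter). With mild fold changes the core
  and ring fingerprints become nearly collinear and no
  correlation-driven method can segregate the core — contradicting the
  observed behaviour this generator is meant to emulate.
* **Ring position.** Each species sits at its own point of the
  white-matter→core trajectory: loss species are largely depleted
  already in the ring (exponent 0.75 on the core fold change, since
  demyelination is *active* there), accumulation species change late
  (exponent 0.30, phagocytic accumulation completes in the core). All
  stated trends stay monotone, but the ring acquires its own fingerprint
  direction instead of sitting on the straight line between white matter
  and core.

`simulate_cube` renders each pixel's template as Gaussian peaks
(constant FWHM 700/60,000 ≈ 0.0117 Da, i.e. resolution ~60,000 at m/z
700) on a shared axis built from fine local grids (σ/2 spacing, exactly
centred on each species m/z) plus a coarse 1 Da background grid. Noise
(`noise_model`) comprises a per-pixel log-normal TIC factor (CV 0.20), a
per-pixel Gaussian ppm drift (SD 3), per pixel-and-peak log-normal
intensity noise (CV 0.20), an additive baseline (10⁻⁴ of unit total) and
optional Poisson shot noise; inter-animal variability is log-normal
jitter on template abundances (CV 0.15), partly shared across the
regions of a section. These dispersion values are plausible for Orbitrap
MSI but are *not* measured from the study's instrument (no per-pixel
noise statistics are published); they are exposed in the configuration.

What the generator does **not** emulate: isotope envelopes, adduct
heterogeneity, matrix/suppression effects, resolution varying with m/z,
spatially correlated noise, partial-volume mixing at region boundaries,
and anatomically realistic (butterfly-shaped) grey matter. Passing tests
therefore demonstrate that the *algorithms* recover known structure
under controlled, MSI-like variability — not that real tissue would
behave identically.

## Numerical conventions and degenerate inputs

* Ties everywhere resolve to the lowest pixel index / lower region code,
  and every stochastic step is seeded; identical seed and input
  reproduce identical outputs bit for bit.
* All-zero pixels are flagged and excluded from correlation; constant
  fingerprints raise an error rather than propagating NaN correlations.
* A single segment gets colour 0.5; single-pixel segments cannot be
  split and report +Inf cohesion.
* `[M−H]⁻` = neutral monoisotopic mass − m(H) + m(e⁻).

## Problem sizes

The bundled tests and the acceptance script run the study design at desk
scale: 48 × 48-pixel sections (≈ 1,400 tissue pixels), nine sections,
three regions — chosen so a full cohort analysis completes in about two
minutes while every pixel count stays far below the exact-correlation
threshold. The paper-scale data (mm-sized sections at 10 µm/pixel) would
engage the subsampling path of `dhc_rc_segment`; nothing else changes.

## A worked example

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(n_sections = 3, width_px = 40,
                                    height_px = 40, seed = 1),
                    out_dir = tempfile("lipidseg_run"))
run$classification$per_class
head(run$comparisons$white_matter_vs_lesion_core)
plot(run$sections[[1]]$map_initial)
plot(run$pca)
```

## Known limitations

* The exact mechanics of the original DHC-RC algorithm are not published
  in full; this implementation follows the verbal description (minimum
  correlation seeds, competing walkers, correlation objective) and makes
  the open choices explicit and pluggable behind `walker_config`. Other
  resolutions of those choices could partition borderline pixels
  differently.
* Annotation is m/z-only; isomers within a sum composition (e.g. PI
  40:6 vs PI 18:0/22:6) are indistinguishable, and PS assignments are
  tentative by construction.
* Real-data mode requires the operator to choose which segments form the
  lesion before re-segmentation — in the original workflow that choice
  is guided by immunohistochemistry on the same section, and the package
  deliberately does not guess it.
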