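---
title: "Quantifying chromogenic colony-array screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromogenic colony-array screens: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromopin)
library(dplyr)
```

## The assay and the analysis problem

CPRG (chlorophenyl red-β-D-galactopyranoside) is a chromogenic
β-galactosidase substrate that an intact Gram-negative envelope excludes.
When an ordered deletion library carrying cytoplasmic LacZ is pinned onto
CPRG indicator agar, mutants that lyse or have permeable envelopes cleave
the substrate and turn red, while healthy colonies stay white. Screening a
whole library this way produces plate photographs of 384-pin (16 × 24)
colony arrays in which a small minority of colonies are pink to red, often
with a diffusing halo of red product around them; arrays are imaged at an
early time (end of vegetative growth) and again several hours later.

chromopin turns those photographs into statistics: per-colony redness
scores, replicate-averaged per-mutant scores, thresholded hit calls,
cross-condition comparisons, term enrichment, and — for
conjugation-based double-mutant screens — colony-size growth scores.
Because no public image set accompanies screens of this kind, the package
carries its own forward model: a synthetic plate generator with exact
ground truth against which every stage is validated.

## The forward model (synthetic plates)

A `plate_spec()` fixes the pinning geometry and imaging physics:

* **Geometry.** Pin centres on a rigid lattice (`pin_spacing`, default
  20 px), colony radii drawn from a normal distribution (mean 6 px, sd
  0.5), centres jittered isotropically (sd 1 px by default). Image
  dimensions are deterministic in the spec.
* **Background.** Agar intensity 0.55 with a linear gradient along x
  (2 × 10⁻⁴ per pixel) and a radial vignette (8% at the corners), plus
  i.i.d. Gaussian sensor noise (sd 0.01) — the non-uniformities of
  commodity plate photography.
* **Colour.** A colony with planted redness *r* is drawn at value 0.92
  with saturation `1 − exp(−r)` at hue 0° (Beer–Lambert-like pigment
  accumulation: linear in *r* when small, saturating when deep red).
  Pigment accumulates linearly with incubation time — redness at time *t*
  is `effect_size · t` — while colony geometry is held fixed across
  timepoints so colour effects are isolated from size effects.
* **Halo.** A red colony is surrounded by a radially decaying ring:
  amplitude 0.6 of the rim saturation, Gaussian width
  `halo_diffusion_sigma_per_hour · t` beyond the rim (default
  0.2 px/hour, so ~2.4 px at a 12 h early image and ~4.6 px at 23 h).
  With 20 px pin spacing and 6 px radii, the late-image halo reaches
  neighbouring cells and the early-image halo essentially does not —
  the geometry that motivates early-timepoint quantification.
* **Determinism.** All randomness flows from one integer seed through
  per-plate substreams (a hash of the seed with the plate key), so any
  image is reproducible bit-for-bit. Images are quantised to 8-bit sRGB
  in memory, so the rendered array equals its PNG round-trip exactly.

Overlapping discs (possible under heavy jitter) are composed by max-blend
and reported with a warning; truth positions outside the grid are errors.

What the generator does **not** emulate: colony morphology beyond discs
(lobes, satellites), specular highlights, condensation, plate-edge growth
advantage, camera colour calibration error, and spatially correlated
noise. Passing the recovery tests therefore shows the pipeline is correct
under the stated imaging model, not that it is robust to every artefact of
real plate photography.

## Grid fitting and segmentation

`fit_grid()` projects the background-subtracted value channel onto each
axis (after a small-angle rotation search over ±2°, sharpest-projection
criterion) and fits a **rigid lattice** — offset and spacing by exhaustive
search, exactly `rows` (`cols`) centres — followed by a local centroid
refinement of each centre line within a third of the spacing. Pinning
robots produce near-rigid arrays, so no per-row warp is modelled; the RMS
deviation of refined centres from the rigid lattice is reported as the fit
residual so violations are visible. Fits with rotation beyond ±5° or
without credible lattice contrast raise a structured
`chromopin_grid_fit_error` carrying the offending profile.

`segment_colony()` works inside the rectangular cell around each pin: the
border annulus of the cell (outer 15%, agar only) gives a per-channel
median background; foreground is the value-channel deviation above an
Otsu-derived split (EBImage's Otsu on the normalised deviation), and the
largest connected component touching the cell centre is kept. Components
below `min_area` (10 px) mark the cell empty. Segmentation runs on the
value channel, not on redness, so red colonies cannot be systematically
larger or smaller by construction.

## The CPRG score

The score formula used by the original screen's software is unpublished,
so this package defines one with the properties the published score
distributions display (zero-calibrated on white colonies, extensive, wide
dynamic range):

$$ w_{xy} = s_{xy}\, \exp\!\left(-\frac{\Delta(h_{xy}, h_{\mathrm{ref}})^2}{2\sigma_h^2}\right), \qquad
   C = \sum_{(x,y)\, \in\, \mathrm{mask}\, \cup\, \mathrm{halo}} \max(0,\, w_{xy} - w_{\mathrm{bg}}) $$

where pixels are converted to HSV (standard hexcone transform of sRGB),
\(\Delta\) is circular hue distance in degrees, \(h_{\mathrm{ref}} = 0°\)
(the red product), \(\sigma_h = 20°\), and \(w_{\mathrm{bg}}\) is the
redness of the cell's background estimate. A fully saturated red pixel
contributes exactly 1; achromatic pixels contribute 0, so an all-white
noiseless plate scores exactly 0 everywhere. The score is a sum, so it is
additive over disjoint regions and strictly increasing in pigment at fixed
geometry.

The halo annulus (default width 0.5 × pin spacing beyond the colony rim,
clipped to the cell rectangle so it stops before neighbouring cells)
carries genuine lysis signal and is included by default; `halo = FALSE`
scores colony pixels only, since whether the reference implementation
included halos is not documented. Likewise plate-median normalisation is
available but off by default.

Hue statistics are circular throughout (`mean_hue` is a saturation-
weighted circular mean and is reported missing for fully achromatic
regions).

## Timepoints, neighbour contamination, hit calling

Because the red product keeps diffusing, a late image can push colour into
the cells of a red colony's neighbours. Two mechanisms address this:

1. `select_timepoint()` picks the **earliest** image in which ≥ 90% of
   expected colonies are segmented at ≥ `min_area` — the earliest
   adequately grown image — and keeps later ones for QC.
2. `flag_neighbor_contamination()` flags a colony when an 8-neighbour
   scores above the hit threshold **and** the colony's halo-annulus
   redness is directional toward that neighbour (facing sector > 2× the
   opposite sector, measured on 8 45°-sectors of the annulus) **and** the
   neighbour outscores the colony 2-fold. The last condition encodes that
   colour only diffuses from redder to whiter colonies, and protects
   adjacent genuinely red colonies from flagging each other — without it,
   two planted red colonies side by side extinguish each other's hit
   calls. Flagged positions are excluded from hit calling.

Scores of the 2 replicate clones of each mutant are arithmetically
averaged (`average_replicates()`); a mutant with one available clone is
averaged over that clone and flagged rather than dropped, since library
dropouts are inevitable. A hit is a mutant whose averaged score is
**strictly** above the threshold ("scores above the cut-off"); ties at the
threshold are not hits.

The published cut-off (10^3.7 "units") is an instrument-specific constant
of the original analysis; it is accepted verbatim via the `threshold`
argument when reproducing published counts. For synthetic or re-imaged
data, `calibrate_threshold()` derives a cut-off from the score
distribution itself: over the central 90% quantile mass of `log(1 + S)`,
`tau = expm1(mean + z·sd)` with `z = 6` (expm1 being the exact inverse of
the `log1p` transform). The trimmed moments make the calibration
insensitive to the hit tail; `z = 6` places the cut-off far enough out
that only a small proportion of mutants score positively, mirroring the
specificity of the published assay.

`compare_conditions()` enumerates all `2^k − 1` membership classes of the
union of hits (the Venn breakdown) and reports the condition-specific
fraction, defined as hits positive in **exactly one** condition.
`enrich_terms()` is a plain hypergeometric upper-tail test per term with
Benjamini–Hochberg adjustment; the gene→term vocabulary is user-supplied,
the universe defaults to the mutants actually quantified (the screen's
sampling frame), and terms annotating fewer than 3 universe genes are
skipped. No GO DAG propagation is attempted.

## Genetic-interaction growth scores

For conjugation-built double-mutant arrays, the growth score of a gene is
the mean colony size of its replicates divided by the average size of
library clones: > 1 suppressive, < 1 negative. Three interpretation
choices the original description leaves open are handled explicitly:

* **Reference set.** The methods text compares double mutants to matched
  single mutants while the scoring footnote divides by the library
  average; these are not the same reference. Both modes are implemented
  (`reference = "library-mean"` (default, per the footnote) or
  `"matched-single"` with a singles table); the discrepancy is surfaced
  here rather than resolved.
* **Neutral band.** The literal >1/<1 rule classifies noise; a band of
  ±`epsilon` (default 0.2) around 1 is classed neutral, and
  `epsilon = 0` restores the strict rule.
* **Dead colonies.** Size-0 replicates are excluded from both numerator
  and library mean (lethal combinations would otherwise poison the
  reference); a gene with all replicates dead scores 0, class negative,
  flagged `lethal-candidate`.

Per-plate normalisation (divide by each plate's library mean before
pooling) removes shared plate effects; under the generative model
`size = base · fitness · interaction · exp(plate) · exp(noise)` it makes
the score an unbiased estimate of the interaction multiplier up to the
lognormal noise correction `exp(sd²/2)` (0.5% at the default noise sd
0.1). Border rows/columns can be excluded from the reference since border
colonies overgrow in pinned arrays. The 1536-format replicate count of
condensed screens is not standardised; the simulator defaults to 4.

## Numerical and degenerate-input choices

* Grid search over spacing uses 140 candidate spacings and offsets at
  spacing/20 steps; centre refinement falls back to the rigid lattice if
  refinement breaks monotonicity of the centres.
* Otsu thresholds are guarded by a minimum contrast (0.05 in value
  deviation) so noise-only cells segment as empty rather than as salt.
* `average_replicates()` drops empty-flagged positions before averaging;
  a mutant missing from a condition gets `n_clones = 0` and a missing
  score rather than 0.
* Hit calling with every score below threshold returns an empty hit set;
  `compare_conditions()` of all-identical hit sets reports a specific
  fraction of 0, of pairwise-disjoint sets 1.
* `growth_score()` errors when the library reference has no grown
  colonies (no meaningful denominator exists).

## Study conditions used by the validation suite

The test suite and the acceptance script fix their problem sizes as part
of the study design: 20 plates for grid recovery (jitter sd 3 px, noise sd
0.02), 384-colony plates with planted redness log-uniform on [0.03, 2]
(the score's informative range — below ~0.03 a colony is visually
indistinguishable from white at the default noise) for rank-fidelity
checks, five 384-mutant single-condition screens at 2% planted CPRG+ for
sensitivity/specificity, a 4-condition × 2-timepoint × 384-mutant screen
for the end-to-end run, and 200-gene × 4-replicate simulations (20 seeds)
for interaction recovery. The screen-scale score-table generator plants
per-condition hit counts uniform on [120, 200] out of 3985 mutants with a
75% condition-specific union — the composition reported for the published
screen — and is used to validate counting and comparison arithmetic at
realistic scale; it is a synthetic stand-in, not the published data.

## Known limitations

* The CPRG score is this package's definition, not the unpublished
  original; absolute "units" are not comparable across instruments, which
  is why threshold calibration is data-driven by default.
* The rigid-grid model does not handle per-row warp or barrel distortion;
  the fit residual exposes, but does not correct, such violations.
* Saturation-based scoring compresses above redness ≈ 2 (deep red
  colonies); ranks remain correct but effect-size estimation from colour
  alone is not attempted.
* A uniform brightness offset scales HSV saturation and hence the score
  by approximately `1 + offset/value`; invariance holds only for small
  offsets (≲ 2% score change for a 0.01 offset).
* Enrichment treats terms independently; correlated gene sets inflate
  the number of nominally significant terms, as in any flat
  hypergeometric screen analysis.
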