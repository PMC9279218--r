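---
title: "Perfusion-chaos fractal dimension mapping: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion-chaos fractal dimension mapping: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Pancreatic ductal adenocarcinoma (PDA) is systematically under-measured on
CT: the hypoperfused core is visible, but the proliferatively active rim
enhances almost like normal pancreas and disappears into the background.
The rim does differ in one respect — its neoangiogenic microvasculature
perfuses chaotically, so its enhancement *pattern* over space and over
contrast phases is rougher than that of regularly perfused tissue.

`fractalCT` quantifies that roughness with a blanket (Peleg-type) fractal
estimator extended to four dimensions. The co-registered unenhanced,
pancreatic-parenchymal and portal-venous phases are treated as one scalar
field over a 4D support (three spatial axes plus the phase axis). Two
blankets are moulded to the intensity graph and iteratively peeled away
from it:

* upper blanket: `u_0 = texture`,
  `u_e(x) = max(u_{e-1}(x) + 1, max_{y in N(x)} u_{e-1}(y))`
* lower blanket: mirrored with `-1` and `min`.

`N(x)` holds the 8 direct 4D neighbours (one step along a single axis; the
phase axis counts as a full fourth dimension). All boundaries, including
the phase axis, are mirror-padded. After `e` iterations the inter-blanket
volume `V(e) = sum(u_e - b_e)` has absorbed all texture detail finer than
scale `e`; the surface measure is the incremental volume

    A(e) = (V(e) - V(e-1)) / 2 ,   V(0) = 0 ,

averaged over phases, and the fractal dimension is

    FD = 4 - slope of log A(e) vs log e ,

clamped into [4, 5] — the graph of a 4D field embedded in 5D. A flat
texture gives `A(e) = N` (the region's voxel count) at every scale and
FD = 4 exactly; an uncorrelated-noise texture approaches FD = 5.

**Why the incremental measure.** The classical alternative
`A(e) = V(e) / (2e)` accumulates all scales below `e` into each measure
point. On exact 1D fractional Brownian motion (fGn synthesized by
circulant embedding, then cumulated — an oracle independent of this
package) it underestimates the graph dimension by up to 0.25 at H = 0.3,
with a bias that decays only logarithmically in `e`. The incremental form
isolates the detail added at each scale and recovers the same oracle's
dimension to within 0.01–0.08 over `e` in 1..8. We therefore use the
incremental form throughout.

## Intensity standardisation

Before fractal analysis each case is standardised:

1. **Alignment** (`alignPhases`): integer-voxel translation per phase,
   found by FFT cross-correlation of gradient-magnitude images within a
   ±10-voxel search window. Gradient magnitudes are used because tissue
   contrast inverts between unenhanced and enhanced phases, which defeats
   raw intensity correlation; edges stay put. Shifts with normalized
   correlation below 0.3 are not applied and flagged low-confidence.
   This is deliberately a fallback for near-registered data; deformable
   registration is out of scope and externally registered stacks pass
   through unchanged.
2. **Resampling** (`resampleIsotropic`): trilinear per phase onto an
   isotropic 0.7 mm grid (nearest-neighbour for masks, so no labels are
   invented); the physical extent is preserved within one voxel.
3. **Denoising** (`denoiseStack`): per phase, a 3D median filter of
   radius 2 voxels followed by a 3D bilateral filter with spatial sd 1
   voxel and range sd `2 × sd_muscle`, where `sd_muscle` is the HU
   standard deviation in an erector-spinae ROI (`estimateNoise`). Tying
   the photometric scale to the measured noise floor removes noise while
   sparing genuine tissue texture; the factor 2 is a config knob
   (`bilateralRangeFactor`). Mirror padding avoids edge darkening that
   would bias FD at the volume border. Constant volumes pass through
   bit-exactly (the bilateral accumulates deviations from the centre
   voxel).
4. **Portal-vein normalization** (`normalizeEnhancement`):
   `I = (I_voxel - I0) / (I_pv - I0) * 100` per contrast phase, where
   `I0` is the unenhanced and `I_pv` the phase's portal-vein mean. 0 and
   100 then mean "no enhancement" and "portal-vein enhancement",
   standardising circulation and injection-timing differences across
   patients. The unenhanced phase has no `I_pv` of its own (the
   denominator would vanish); it is mapped with the portal-venous
   denominator so the whole stack shares one scale (configurable via
   `unenhancedDenominator`). The vein ROI is reduced by its mean; the
   muscle ROI by its SD — the least surprising reductions for a
   reference level and a noise level respectively.

## The phase axis and per-region centring

After normalization each tissue still has a different bulk enhancement
level per phase (pancreas at roughly 0 / 56 / 29 normalized units across
the three phases). Along the phase axis the blanket reads those level
steps as a cliff at *every* voxel — about 50 units against texture of a
few units — which drowns the chaos signal entirely. The physical quantity
of interest is the enhancement *pattern*, not the kinetics, so both FD
estimators subtract each phase's mean over the evaluation region before
iterating: the ROI for `globalFD`, the local window for `localFDMap`
(`centerPhases = TRUE`, a knob). With centring, a tissue that enhances
coherently contributes nothing along the phase axis, while incoherent
voxel-to-voxel enhancement — perfusion chaos — remains. Spatial and phase
steps are otherwise treated as unit steps; no physical time scaling is
applied.

## Scales and windows

* `localFDMap` evaluates each voxel's immediate vicinity: a window of
  half-width 3 voxels spatially spanning all phases, scales `e` in 1..3.
  The window must satisfy `windowRadius >= max(scales)`.
* `globalFD` iterates blankets over the full grid and accumulates the
  surface measure over the ROI only, with default scales
  `1..min(4, extent/2)`. The cap of 4 keeps the regression in the
  texture-dominated regime: at larger scales the blanket of an
  anatomically adjacent structure (a vessel edge, the neighbouring
  region's texture) reaches into the ROI — the rim shell is itself only
  ~4 voxels thick — and the measure increasingly reflects neighbours
  rather than the region. On 32×32×32×8 fBm textures the default scales
  recover the theoretical graph dimension `5 - H` to within 0.08 for
  H in {0.3, 0.5, 0.7}.
* Out-of-range regression slopes are clamped into [4, 5] and counted
  (`clampedFraction`); discretization can push slopes slightly past the
  theoretical bounds, and uncorrelated noise sits at the upper bound.

Degenerate cases: a constant texture yields a zero-variance log-log fit,
reported as slope 0, FD = 4, R² = 1 (treated as a perfect fit rather than
undefined); surface measures must be positive for the fit to proceed, and
windows whose incremental measure collapses to zero fall back to FD 4.

## Size measurement

Segmentations are measured with the voxel-centre convention
(world = index × spacing; a single voxel has diameter 0, documented so
users expecting a +1-voxel extent can add it):

* `maskVolumeMl`: `count × voxel volume / 1000`, exact.
* `feretDiameter`: maximum pairwise distance between voxel centres. The
  search is reduced to per-grid-line extreme voxels — every convex-hull
  vertex is the first or last mask voxel on its own grid line — and
  verified against exhaustive search in the tests.
* `recistDiameter`: the same caliper restricted to axial slices,
  reflecting in-plane measurement convention. `feret >= recist` always.
* `segmentFDThreshold`: the 26-connected component of `{FD >= t}`
  containing a seed voxel — the reproducible automation of FD-guided
  manual segmentation (26-connectivity is permissive enough for thin
  rims). Externally drawn masks are first-class input throughout. No
  numeric default threshold is claimed; the phantom experiments place the
  threshold midway between background-mean and rim-mean local FD, and
  seed at the most chaotic core voxel, which is what a reader picking a
  conspicuous tumour point would do.

A caveat observed on the phantom: the Feret diameter of a threshold
segmentation is sensitive to any attached tentacle of halo voxels — a
single attached blob adds its full distance. Volume is much more stable
(phantom recovery to a few tenths of a mL).

## Agreement statistics

`blandAltman` uses the reference-minus-test convention and classical
1.96 · SD limits of agreement (not t-quantiles). Proportional bias is the
regression of difference on pairwise mean; the calibration line is test
on reference with normal-theory CIs, and because published agreement
tables differ in orientation the reverse regression's coefficients are
also reported. `rankTests` runs Kruskal–Wallis plus all pairwise
Mann–Whitney U tests (or Wilcoxon signed-rank when `paired = TRUE` — the
paired member of that family, resolving the ambiguity of a "pairwise rank
sum test for paired samples"), Bonferroni-corrected; p-values are exact
for groups of at most 10 without ties, otherwise normal approximation
with tie correction. `interReaderAgreement` reports per-case relative
discrepancy `|r1 - r2| / mean(r1, r2) × 100` — the pairwise-mean
denominator keeps it symmetric in the readers — with median, IQR and
Spearman's ρ. `varianceFTest` uses the larger-over-smaller variance ratio
with a two-sided F p-value.

## The synthetic phantom

`pdaPhantom` builds the geometry the method assumes: a mildly
hypo-enhancing ellipsoidal core (default semi-axes 14 × 11 × 9 mm, HU
39/100/84 per phase against background 40/110/90), a 3 mm rim shell
intensity-matched to background in every phase, background pancreas, a
portal-vein cylinder (45/160/200 HU) and a muscle box (50 HU), plus
global Gaussian noise (sd 5 HU) on a 96 × 96 × 64 grid at 0.7 mm.

Each region's texture is fractional-Brownian with two chaos controls:

* the **Hurst exponent** (spatial roughness; rim 0.25 < core 0.3 <
  background 0.65), and
* a **phase-decorrelation weight** `phaseChaos` — the share of texture
  variance drawn independently per phase. Background 0.25, core and rim
  1: normal pancreas enhances coherently, the tumour enhances
  incoherently voxel to voxel. This is the phantom's encoding of
  perfusion chaos, and it is also what survives the per-phase 3D
  denoising, exactly as temporal enhancement incoherence would in real
  data.

Textures are band-limited to wavelengths below 12 voxels (~8 mm) and
scaled by their standard deviation (amplitudes: background 6, core 7,
rim 12 HU). Organ-scale intensity trends are modelled by the piecewise
enhancement levels, not by the texture; full-band low-Hurst fields would
put most of their variance into a handful of organ-scale modes, making
regional amplitudes swing by a factor of two between seeds.

The rim carries **zero mean contrast**: it is invisible by intensity and
separable only through chaos — the core claim the pipeline is built on.
Under these defaults the full pipeline yields global FD near 4.43 (rim),
4.32 (core) and 4.07 (pancreas), reproducing the rim > core > pancreas
chaos gradient in 10/10 seeds, and FD-threshold segmentation recovers the
full tumour (Dice ≈ 0.87) where intensity thresholding recovers only the
core.

`fbmField` (the validation texture) is full-band spectral synthesis with
the fBm spectrum `S(f) ~ f^-(2H+d)`, with one alias replica per axis
folded back into the discrete spectrum — without aliasing the sampled
field is too smooth at unit lags and misses its nominal Hurst exponent —
and unit pooled lag-1 increment sd. For dimension-recovery experiments it
is scaled by 50: the blanket's vertical unit step quantizes textures of
order-1 amplitude, and a well-resolved gray scale (tens of levels per
unit lag, ordinary 8-bit-image territory) is required for the
self-similar regime to be measurable.

**What the phantom does not emulate:** organ anatomy and partial-volume
mixtures, beam hardening and structured CT noise, deformable inter-phase
motion, realistic enhancement kinetics beyond three piecewise levels, and
reader variability. Passing phantom tests therefore demonstrates that the
implementation detects designed-in chaos gradients through the full
pipeline — not that the clinical effect sizes would be reproduced in
patients.

## Problem sizes and determinism

The test-suite and acceptance experiments use the default 96 × 96 × 64
phantom for global-FD properties (10 seeds), a 48 × 48 × 36 phantom for
local-map and end-to-end experiments, 32 × 32 × 32 × 8 fBm textures
(5 seeds per Hurst value) for dimension recovery, and 1000 replicates for
the Kruskal–Wallis type-I-error simulation. Every stochastic component is
seeded; identical spec + seed reproduce phantoms bit-identically, and
`runPipeline` reruns are byte-identical in their FD-map and CSV outputs
(each artefact embeds the MD5 hash of its configuration).

## Known limitations

* Global FD of ROIs adjacent to strong intensity edges picks up edge
  transients at scales beyond the default cap; the scale range is
  configurable, and region interiors reproduce the flat-texture limit
  exactly.
* The blanket estimator's amplitude sensitivity means FD values are
  comparable only within one standardisation scheme — which is why the
  portal-vein normalization precedes it.
* The alignment fallback corrects integer shifts only; rotations or
  deformations require external registration.
* Exact replication of the published clinical agreement tables is out of
  scope: those numbers derive from a patient cohort that is not
  deposited. The package reproduces the method and its internal
  consistency properties, not the cohort.
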