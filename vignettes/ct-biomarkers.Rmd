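---
title: "Quantitative thoracic CT biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative thoracic CT biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctquant)
```

`ctquant` quantifies the four biomarker families used in cardiopulmonary CT
studies of COPD and coronary disease — lung densitometry, airway wall
morphometry, pulmonary vessel calibre profiling, and cardiac indices — and
validates every operator against a seeded synthetic thorax phantom whose
ground truth is known analytically. This vignette is the package's account
of the underlying methods: what each operator computes, the assumptions it
makes, the tunable parameters and why their defaults are what they are, and
what the phantom does and does not establish about real data.

## Data model and conventions

A `ct_volume` is a 3D array of Hounsfield units with voxel spacing
`(dx, dy, dz)` in mm; arrays follow R's column-major `[x, y, z]` layout, the
native layout of NIfTI images as RNifti exposes them. All voxel coordinates
are 1-based; physical coordinates put the centre of voxel `(1,1,1)` at the
origin.

Two principles run through the package:

* **Quantification always reads raw HU.** The model-input chain
  (`preprocess()`: Gaussian denoising, clamping to `[-1000, 400]` HU, affine
  normalization to `[0, 1]`) returns a *new* volume and never mutates its
  input. The 400 HU clamp would make the top Agatston density class
  (>= 400 HU, weight 4) unreachable, so calcium scoring on a preprocessed
  volume is a bug; `agatston_score()` warns when its input looks clamped.
* **Truth is defined on the voxelized geometry.** The phantom's expected
  values are voxel counts and recorded lesion parameters, not continuous
  closed forms, so mask-based recovery can be asserted *exactly* rather than
  "close to pi r^2 h". Closed forms appear only as secondary tolerance
  checks.

The smoothing width `gaussian_sigma` defaults to 1 (the low end of the
conventional 1-1.5 range, chosen to minimally blur thin airway walls) and is
interpreted in voxel units; pass `sigma_units = "mm"` to divide by the
spacing instead. Neither interpretation is asserted as more correct - on the
near-isotropic 1 mm grids this package targets the two coincide.

## Lung densitometry

`lung_metrics()` computes, over the lung mask on raw HU:

* **LAV%** — the percentage of lung voxels below the low-attenuation
  threshold. The threshold defaults to **-950 HU**, the field standard for
  inspiratory HRCT emphysema scoring; it is an explicit argument because it
  is a convention, not a derived quantity.
* **Perc15** — the HU value at the 15th percentile of the lung histogram.
  The convention is the *lower order statistic* at `ceiling(0.15 n)`: no
  interpolation, so the result is always an observed HU value and tests can
  assert it exactly.
* **MLD** — the mean HU over lung voxels. Weighting is by voxel count;
  spacing is uniform within a scan, so count and volume weighting coincide.

An empty mask yields flagged `NA` metrics, never zeros — a zero LAV% is a
valid clinical value and must not be conflated with "no lung found".

## Airway morphometry

`measure_cross_section()` implements full-width-half-maximum (FWHM) ray
casting, the standard operator when no commercial airway tool is specified:
64 rays are cast in the plane normal to the centreline through the given
lumen point, sampled every 0.1 mm by trilinear interpolation. Per ray, the
inner wall edge is the half-rise between the lumen HU and the peak wall HU;
the outer edge is the half-fall from the peak toward the parenchymal level
estimated from the ray's tail. Radii are averaged over rays and areas follow
the circular model `LA = pi r_l^2`, `WA = pi (r_o^2 - r_l^2)`,
`Pi = 2 pi r_l`. Elliptical fitting was considered and rejected: it adds
parameters that nothing in the validation data can constrain.

Preconditions are enforced, not assumed: the centre sample must be below
-900 HU (air-filled lumen), and the measurement is rejected when more than
25% of rays find no wall peak at least 100 HU above the lumen. A centre
placed in parenchyma (about -850 HU) fails the first check.

**Known limitation: thin walls at coarse voxels.** With a 1 mm wall on a
1 mm grid the sampled profile peak never reaches the true wall attenuation
(the wall is one voxel thick), and FWHM shows the literature-standard
wall-thickening bias of roughly +25% on WA. At 0.5 mm in-plane voxels — the
resolution airway reconstructions actually use — the same tube is recovered
to within ~4% on LA and ~2% on WA. `airway_tube_phantom()` therefore
defaults to 0.5 mm in-plane spacing, and the package's wall-measurement
checks run there. The mask-based path
(`measure_cross_section_mask()`), which counts voxels on a cross-sectional
slice, stays exact at any resolution and cross-checks the FWHM path.

**Pi10.** `pi10_regression()` fits ordinary least squares of `sqrt(WA)` on
the internal perimeter Pi across airways and reports the fitted `sqrt(WA)`
at Pi = 10 mm — the standard airway-remodelling summary. Whether a cohort
WA% should be averaged per airway or pooled over cross-sections is not
fixed by any convention we could verify; the package averages per airway
first. Degenerate fits (all Pi identical) raise an error rather than
returning NaN.

## Pulmonary vessels

`vessel_csa_profile()` assigns every vessel voxel a local cross-sectional
area: the binary mask is skeletonized by taking the 26-neighbourhood ridge
of its Euclidean distance transform, the local radius at a skeleton voxel is
its distance value **minus half a voxel**, and every vessel voxel inherits
`pi r^2` from its nearest skeleton voxel. The half-voxel correction exists
because the distance transform measures to the nearest *background voxel
centre* while the physical boundary sits about half a voxel closer; without
it a radius-1 mm digital cylinder is assigned a CSA above 5 mm^2 and the
small-vessel class collapses. The distance and nearest-feature transforms
are an exact separable (Felzenszwalb-Huttenlocher) implementation in
compiled code.

**BV5%** (`bv5_percent()`) is the percentage of total vessel volume in
voxels with CSA below 5 mm^2. The threshold name "below 5 mm" conflates
length and area units in common usage; this package reads it as **area
< 5 mm^2**, the standard BV5 definition, and uses total vessel volume (not
lung volume) as the denominator, matching "percentage of blood vessels".

**Fractal dimension** (`fractal_dimension()`) is 3D box counting:
`N(eps)` occupied boxes on a grid anchored at the array origin, and
`D = -slope` of the OLS fit of `log N` on `log eps`. Anchoring at the origin
with no offset averaging makes counts deterministic and test-exact: a solid
64-cube gives exactly `N = (64/eps)^3` and `D = 3`, a voxel line `D = 1`, a
voxel plane `D = 2`. Box sizes default to powers of two up to a quarter of
the shortest axis; box counting on *sparse* masks (thin trees) is noisy at
small sizes, which is why the tree-depth property is asserted as a trend
across well-separated depths, not strict monotonicity. The clinical
fractal-dimension ranges reported for patient vasculature depend on
segmentation style and scanner and are not reproduction targets for digital
phantoms.

## Cardiac indices

`agatston_score()` is the classic protocol: per axial slice, 8-connected
components of `{HU >= 130}` inside the coronary search region; lesions under
1 mm^2 are dropped; each lesion scores
`area x weight(peak HU) x (dz / 3 mm)` with weights 1-4 for peaks in
130-199 / 200-299 / 300-399 / >= 400 HU. The `dz/3` factor adapts the
original 3 mm-slice protocol to thin-slice acquisitions (0.75-1 mm); it is
on by default and configurable, since protocol variants differ here and no
single variant can be verified as "the" reference.

`lv_mass()` is voxel summation times the standard myocardial density
1.05 g/mL. `lv_function()` uses two static phases — end-diastolic and
end-systolic blood-pool masks — with `SV = EDV - ESV` and
`EF = 100 SV / EDV`; a gated multi-phase reconstruction reduces to exactly
this arithmetic once the extreme phases are identified, and two phases are
what a desk-scale phantom can carry. `ESV >= EDV` is an inconsistent-phase
error, not a warning.

## The synthetic thorax phantom

`generate_phantom()` paints, in order: a soft-tissue body (40 HU) over air,
two aerated lung ellipsoids (-850 HU), vessel cylinders or branching trees
(30 HU), z-aligned airway tubes (lumen -1000 HU, wall -100 HU), a prolate
left ventricle (contrast blood 300 HU, myocardium 80 HU), emphysema pockets
(-980 HU), and calcified plaques (130-450 HU squares). Defaults: a 128-cube
at 1 mm spacing, 30% emphysema fraction, EDV/ESV targets 120/48 mL with an
8 mm myocardial shell, three plaques of 4/9/1 mm^2 at 250/450/150 HU peaks
(the classic weight classes 2/4/1), and two airway tubes of 2 mm lumen /
1 mm wall. These are textbook-plausible magnitudes for a moderate-COPD,
calcium-positive thorax; they were fixed once when the generator was
designed.

Three generation details matter for exactness:

* **Exact-count selection.** The ED blood pool is the exact target number of
  voxels nearest the LV centre under a prolate ellipsoidal norm (ties broken
  by voxel index); ES is the concentric inner subset. EDV, ESV, SV and EF
  truth values therefore equal their targets exactly in voxel units.
  Emphysema similarly takes the exact target count of lung voxels nearest
  the seeded pocket centres, giving blob-like pockets and an exact LAV%.
* **Anti-aliased airway edges.** Airway lumen and wall are painted with
  sub-voxel coverage blending (supersampled footprint fractions) so that
  FWHM edge localization is meaningful; the truth masks remain binary
  centre-inclusion sets.
* **Priority carving.** The heart overwrites lung where they meet (as the
  real mediastinum does); the lung truth mask excludes heart and airway
  voxels, so every truth definition refers to the final painted geometry.

Noise is additive Gaussian (`degrade()`), seeded and reproducible; truth is
always computed from the noiseless volume, which is retained alongside a
noisy one.

**What the phantom does not emulate:** reconstruction kernels, beam
hardening, respiratory/cardiac motion, contrast-phase dynamics,
anatomically curved airways and vessel trees, and the texture of real
parenchyma. Passing the recovery suite therefore demonstrates that the
operators are *correct implementations of their definitions* — it does not
demonstrate segmentation accuracy on clinical scans, which is exactly why
clinical agreement statistics are out of scope here.

## Evaluation harness and trial statistics

`dice_iou()` uses the convention `dice = iou = 1` (flagged) when both masks
are empty — agreement on absence; other codebases return 0 or NaN, and the
flag lets callers apply either. `soft_dice_loss()` uses a smoothing epsilon
of 1e-7, which only matters in the empty-empty case. `regression_agreement()`
flags zero-variance series as undefined correlation rather than reporting 0.
`make_splits()` produces seeded, stratified 70/15/15 splits plus cyclic
5-fold assignments; `augment()` samples one transform per call (rotation
within +/-10 degrees, in-plane flips, crop scale 0.8-1.0, additive intensity
shift) and applies the identical geometric transform to volume (bilinear)
and mask (nearest-neighbour). "Horizontal/vertical" flips are mapped to the
two in-plane axes; through-plane flips are anatomically meaningless and
excluded. A multi-task reference trainer (shared encoder, per-branch heads)
was deliberately not implemented: the harness above is what desk-scale
validation exercises, and branch loss weights default to equal in
`combined_loss()` because no weighting scheme could be verified.

`sample_size_per_group()` evaluates `n = 2 sigma^2 (z_a + z_b)^2 / delta^2`
and applies a ceiling (43.56 becomes 44) — the conventional conservative
rounding. Both conventionally rounded quantiles (1.96, 0.84) and exact ones
(1.959964, 0.841621) give 44 on the reference inputs (sigma 5, delta 3).
`inflate_for_design()` reports the dropout-inflated size
`ceiling(n / (1 - d))` — 52 for n = 44 at 15% dropout — and accepts a fixed
per-stratum target as an *input* (50 per subgroup x 4 strata x 2 arms =
400): rounding 52 to a recruitment-friendly 50 is a design choice a tool
should surface, not arithmetic it should invent.

`bh_adjust()` is the Benjamini-Hochberg step-up rule
(`q_(i) = min_{j>=i} m p_(j)/j`, clipped at 1, returned in input order),
verified in the test suite against both a brute-force min-over-suffix oracle
and `stats::p.adjust`. `correlation_matrix()` computes pairwise-complete
Pearson or Spearman cells with BH q-values across all cells jointly, and
flags constant columns as undefined rather than zero.

## Numerical choices and problem sizes

Degenerate inputs fail loudly throughout: empty masks, inconsistent LV
phases, all-identical perimeters in the Pi10 fit, structures that do not fit
the phantom grid (the error names the offending structure). Ties in
exact-count selection are broken by voxel index, making every phantom a pure
function of its spec and seed.

The validation suite runs on a 128-cube default phantom (about 2 s to
generate), 64-cube digital solids for the exact fractal checks, and
1000-replicate oracle loops for the BH and Dice identities; the correlation
recovery uses n = 500 subjects, where the sampling error of r at
rho = -0.6 has SD about 0.03, so the +/-0.08 check is a 2.7-sigma band.
These sizes keep the whole suite under a minute of CPU beyond phantom
generation while leaving every assertion at its natural tolerance.
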