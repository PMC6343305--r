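---
title: "Trabecular morphometry from micro-CT and dental CBCT: models and methods"
author: "trabmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular morphometry from micro-CT and dental CBCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dental cone-beam CT (CBCT) images the jaw at ~0.1 mm voxels — chairside, at
low dose — but trabeculae in cancellous bone are 0.1–0.3 mm thick, so a CBCT
voxel routinely mixes bone and marrow. Binarizing such images and computing
the standard microarchitectural parameters (bone volume fraction BV/TV,
trabecular thickness TbTh, trabecular number TbN, trabecular separation TbSp)
against a micro-CT gold standard (~0.02 mm voxels) produces grossly inflated
BV/TV and TbTh and weak specimen-to-specimen correlation. A short ladder of
preprocessing steps applied to the CBCT image before binarization —
sharpening, despeckling, per-slice automatic thresholding, and removal of
voxels whose grayscale maps to zero bone mineral density — can restore much
of the correlation with the micro-CT reference, which is what matters when
CBCT is used to *rank* bone quality at implant sites.

`trabmorph` implements that pipeline end to end and, because the physical
specimens behind the original cohort are not available, pairs it with a
synthetic specimen generator with known ground truth so that every stage is
testable on a desk.

## The processing ladder

All filters are 2D and per slice (the workflow this mirrors processed slice
stacks in a 2D imaging tool); filter order is fixed: sharpen, then despeckle.

| Group | Input    | Steps |
|-------|----------|-------|
| G0    | micro-CT | global isodata threshold |
| G1    | CBCT     | global isodata threshold |
| G2    | CBCT     | sharpen → despeckle → global threshold |
| G3    | CBCT     | sharpen → despeckle → per-slice threshold |
| G4    | CBCT     | G3 → remove voxels at/below the zero-BMD grayscale |

*Sharpen* is the classic 3×3 kernel (centre 12, neighbours −1, divided by 4)
— the default sharpen of the common 2D tools; the source workflow names the
tool's default without printing a kernel, and this is that tool's documented
default. Edges are replicated and output is clipped to the volume's bit
range. *Despeckle* is the 3×3 median. Edge replication (rather than
shrinking or zero-padding) is our choice: it preserves the ROI size and adds
no artificial gradients.

*Isodata* (Ridler–Calvard) iterates `T ← (mean(values ≤ T) + mean(values >
T))/2` from the overall mean until the update falls below `1e-6·(max−min)`.
Foreground is strictly greater than `T`; ties go to background (a fixed
convention so masks are bit-exact). The per-slice variant computes one
threshold per z-slice; a constant slice inherits the nearest non-constant
slice's threshold. Because isodata is equivariant under affine intensity
maps with positive gain, per-slice thresholding exactly cancels any
per-slice affine distortion such as axial shading — while a global threshold
does not. That asymmetry, asserted as a test, is the mechanism behind G3's
advantage.

*Air removal* (G4) fits an ordinary least-squares line through the
hydroxyapatite-phantom calibration pairs (mean insert grayscale vs known
mineral density, mg HA/cm³). The fitted intercept is the grayscale of
zero-BMD material; every mask voxel whose (filtered) grayscale is at or
below that cutoff is deleted. The cutoff is the intercept exactly — no
safety margin, since the source workflow states none. Removal operates on
voxels, not whole slices: voxel-level removal is the only reading consistent
with a partial (not stepwise) BV/TV drop between G3 and G4. The comparison
uses the same filtered image the G3 threshold was computed from.

## Local thickness: the exact digital convention

TbTh and TbSp use the Hildebrand–Rüegsegger model-independent definition:
the thickness at a point is the diameter of the largest sphere fully
contained in the phase that covers the point; TbTh averages it over bone
voxels, TbSp over marrow voxels. TbN uses the ratio convention
`TbN = (BV/TV)/TbTh` (consistent with a reference cohort whose mean
`0.2385/0.20 ≈ 1.19/mm` matches its printed `1.18` to rounding).

The digital realisation is fixed exactly, because "exact" is what makes the
dual-route testing meaningful:

* `EDT(c)` is the exact Euclidean distance from voxel centre `c` to the
  nearest off-phase voxel centre, with everything outside the volume counted
  as off-phase (spheres must fit inside the ROI; no mirror padding). The
  squared transform is integer-valued and computed by the
  Felzenszwalb–Huttenlocher separable algorithm.
* The sphere centred at `c` has radius `r(c) = EDT(c) − 0.5` voxels and
  covers voxel `p` iff `‖p−c‖ ≤ r(c)`; the thickness at `p` is
  `max { 2·EDT(c) − 1 : c covers p }` voxels.

This convention makes the natural ground truths exact: an isolated voxel
measures 1 voxel, a solid 9³ cube measures 9 across its centre, a 5-voxel
slab measures 5 in its interior. Its known bias is even widths: every voxel
of a 2-voxel slab is face-adjacent to the off phase, so the slab measures
`2·1−1 = 1` voxel — the even-width quantisation shared by the digital
thickness implementations in the field's tools.

Both membership and the ridge pruning of the fast path use exact integer
predicates (`‖p−c‖ ≤ √R2 − ½ ⇔ t ≥ 0 ∧ R2 ≤ t², t = R2 + ¼ − d²`, all
integers below 2^53), so `local_thickness()` equals the brute-force
enumeration `brute_force_thickness()` bit for bit — asserted on 200 random
masks in the acceptance suite, plus complement symmetry (foreground
thickness of a mask equals background thickness of its complement) and
dilation monotonicity. The fast path prunes a sphere only when a
26-neighbour's sphere provably contains it (`√R2' ≥ √R2 + ‖δ‖`, checked in
integers); containment is transitive, so the pruned maximum is unchanged.

Cost: the foreground transform on a 100×100×250 ROI runs in ~2 s; the
background (TbSp) transform is the expensive one (~20 s at that size)
because marrow spheres are large. `compute_morphometry()` therefore takes a
`params` argument so cohort runs can skip transforms they do not need.

## The synthetic world

The generator emulates a cuboid cancellous-bone specimen cut from bovine
vertebrae, with a composite-resin anchor ball on its top surface, scanned
twice: micro-CT at 0.02 mm and dental CBCT at 0.10 mm.

**Trabecular structure** is a thresholded Gaussian random field: seeded white
noise smoothed with an isotropic Gaussian of SD `feature_sigma_mm` (default
0.1 mm, chosen so ground-truth TbTh lands near the 0.2 mm of real
vertebral trabeculae) and thresholded at the order statistic realising the
target BV/TV to within half a voxel's fraction. The two knobs —
quantile and correlation length — control BV/TV and TbTh independently; the
acceptance suite verifies ±0.5 percentage-point BV/TV recovery and strict
TbTh monotonicity over a feature-size sweep. Cohort targets are drawn
uniformly from 9–40 %, the measured range of the emulated micro-CT cohort.

**Voxel size** is 0.02 mm rather than the scanner's native 0.018 mm so the
CBCT downsample factor is the integer 5; block averaging with an integer
factor is exactly testable and 20 ≈ 18 μm for all phantom purposes.

**Intensities** put bone/marrow/air at 180/60/10 on an 8-bit scale with
per-voxel Gaussian texture noise (SD 5) and a mild micro-CT-level blur of
0.5 voxel.

**Air pockets.** An excised wet specimen is scanned in air: part of its pore
space is drained, and low-density content inside cancellous bone is exactly
what the G4 rule targets. Pockets are drawn from an independent Gaussian
random field at the trabecular correlation length, thresholded inside the
marrow to cover `air_fraction = 0.2` of the background. (A rule based on
*connected components* of the marrow phase was considered and rejected:
measured on generated phantoms, the marrow is essentially one connected
component — non-largest components total ~90 voxels in 5 million — so a
component rule selects nothing, G4 never removes anything, and the G3→G4
drop cannot exist.)

**CBCT degradation** is phenomenological, in this exact order: multiply by an
axial shading field `1 + a(2z/Z − 1)` spanning `1−a … 1+a` (default
`a = 0.15`); convolve with a Gaussian PSF; block-average by the downsample
factor; add Gaussian noise. No projection/reconstruction physics, no
beam hardening. The source device's PSF and noise magnitudes are not
published, so they were chosen once, for physical plausibility, and frozen:
`psf_sigma_mm = 0.15` (PSF FWHM ≈ 0.35 mm, enough that 0.1–0.3 mm
trabeculae become partial-volume mixtures at 0.1 mm voxels — the stated
failure mode of CBCT morphometry) and `noise_sigma = 8` against a
bone–marrow contrast of 120. These defaults reproduce the qualitative
group ordering (G1 correlation worst, G3 better, G4 best; CBCT TbTh above
micro-CT TbTh on every specimen; G4 BV/TV below G3), which is what the
acceptance suite asserts; they are not a model of the named scanner.

**Calibration phantom** inserts default to 0–800 mg HA/cm³ with a linear
grayscale response of slope 0.2 gv/(mg/cm³) and intercept 60 — i.e. zero-BMD
material reads like marrow, which is the physical point of the G4 rule.

**Anchor alignment.** The ball (grayscale 255, above everything else) is
rendered tangent to the top surface on the central axis. `locate_anchor()`
searches the upper third of the stack (where the ball sits), thresholds it
at the 0.995 quantile of that region's intensities, labels bright voxels
(6-connectivity), and requires exactly one candidate component (≥ 5 voxels;
smaller ones are noise). Restricting both the threshold and the search to
the upper third keeps the detector's margin proportional to the ball size
rather than the volume size, which matters on small desk-scale volumes. The ROI cuboid is
centred laterally on the ball's intensity-weighted centroid and extends
inward from the first slice below the ball. How the original workflow
derived the "central point" from the ball is not stated; centroid projection
is our interpretation. Voxel counts are computed independently at each
resolution from the physical extent (round half away from zero), mirroring
physical-ROI alignment: 4×4×10 mm is exactly 100×40×40 voxels at 0.1 mm and
500×200×200 at 0.02 mm.

## What a green test does and does not establish

The synthetic world reproduces: the resolution gap and its partial-volume
thickening, axial shading (the artifact per-slice thresholding provably
cancels), drained-pore air, and a linear density–grayscale response. It does
not model: cortical bone, soft tissue or wet-gauze wrapping, scatter, beam
hardening, reconstruction artifacts, anisotropic trabecular orientation, or
the real scanners' noise spectra. Green acceptance tests therefore establish
that the *pipeline* behaves as designed (exact morphometry, correct
statistics, and the qualitative preprocessing ordering under the stated
degradation), not that the original cohort's printed values are recovered —
those require the 30 physical specimens.

## Numerical choices

* Isodata convergence: `|ΔT| < 1e-6·(max−min)`; foreground strictly `> T`.
* mm→voxel conversions round half away from zero, everywhere.
* The sample SD (n−1) is used in summaries and the paired t-test.
* Paired t-test with zero-variance differences: p = 1 if all differences are
  0, else p = 0 (flagged); two-sided tests throughout, α = 0.05, no
  multiple-testing correction across the 16 comparisons.
* OLS calibration: note that perturbing the outer calibration points by
  (+e, −e) shifts the *intercept* by exactly +e (the invariant point of an
  OLS line under such perturbations is the fitted value at the mean density,
  not the intercept); the tests assert this derived behaviour.
* All generators draw from a private, named RNG stream seeded from their
  spec; child seeds are derived deterministically and stay below 2^31. Same
  seed ⇒ bit-identical volumes and byte-identical CSV reports.

## Known limitations

* The thickness convention restricts sphere centres to voxel centres, so
  even-width structures measure one voxel thin (see above); the bias is
  identical across compared groups.
* The brute-force oracle is guarded to ≤ 40³ voxels.
* TIFF support is uncompressed 8/16-bit grayscale; DICOM support is one
  explicit-VR little-endian series per directory — the dialects the
  package's own writers emit (no vendor compression, no multi-series
  directories).
* Group 0's binarization method for micro-CT is not specified in the source
  workflow; global isodata is used for symmetry with Group 1.
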