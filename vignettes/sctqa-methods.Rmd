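---
title: "Methods: CBCT-based quality assessment of synthetic CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBCT-based quality assessment of synthetic CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures in `sctqa`, the
assumptions behind them, and the design choices that were genuinely open
when the package was written.

## The problem

MRI-only radiotherapy replaces the planning CT with a synthetic CT (sCT)
derived from MRI. Once the CT is gone, routine verification of sCT
quality must rely on the cone-beam CT (CBCT) acquired for image
guidance. Two obstacles stand in the way:

* **Irrelevant anatomical change.** Bowel gas and the body outline
  differ between the MRI/sCT session and the CBCT session. These
  differences are real, but they say nothing about the quality of the
  sCT generation method, so they must be removed before comparing.
* **CBCT intensity miscalibration.** Scattered radiation shifts and
  compresses CBCT Hounsfield units relative to diagnostic CT, in a way
  that depends on the patient's own scattering geometry. A conventional
  calibration phantom (a plastic cylinder with density inserts) does not
  reproduce that geometry.

## Correction model

All comparisons are made on paired, co-gridded volumes. The correction
stage (`crop_to_body()`, `water_fill()`, `correct_pair()`) does two
things:

1. Crops every image to the body outline of the sCT, which by
   construction has the smallest outline. The outline is extracted by
   thresholding at −300 HU — midway between the air (−500 HU) and
   soft-tissue (−200 HU) cut-offs used in the fill rule — keeping the
   largest 6-connected component and filling enclosed holes, so internal
   gas counts as body. Exclusion is tracked in a validity mask rather
   than by overwriting voxels, so downstream binning can skip cropped
   voxels unambiguously.
2. Assigns water (0 HU, the definition of the HU scale) to every
   reference voxel strictly below −500 HU whose sCT counterpart is
   strictly above −200 HU. The rule is deliberately one-directional:
   the sCT is the object under test and is never modified. For the
   CT–CBCT pairs that feed the population calibration, however, the fill
   is applied symmetrically (each image filled where the other shows
   soft tissue): there neither image is under test, and a transient
   pocket in either would otherwise pollute the calibration bins.

The correction is idempotent, never touches reference voxels at or
above the air threshold, and on noise-free phantoms fills exactly the
generator's transient-pocket voxels.

## Calibration curves

Three curve types (`calibration_curve`) convert HU to relative electron
density (RED) or mass density (DES):

* **TPS** — the treatment planning system's piecewise-linear lookup
  through explicit control points, used for CT and sCT. The shipped
  default control points are the phantom generator's tissue classes,
  which define the ground-truth HU/density relation of the phantom
  world.
* **phantom** — one point per insert of a scanned calibration cylinder:
  (mean HU over the insert ROI, known density).
* **population** — the package's central calibration idea: paired,
  corrected CT–CBCT voxels from a reference cohort are grouped into
  half-open 100 HU bins of CBCT value (anchored at −1024 HU); each bin
  with at least 100 pairs contributes the point (mean CBCT HU, mean CT
  density). The bin abscissa is the mean CBCT HU rather than the bin
  centre — robust when bin occupancy is skewed. Building the curve from
  the cohort *excluding* the patient under evaluation (leave-one-out) is
  the caller's responsibility; `run_cohort_qa()` does it, and each curve
  records the case ids it was built from.

Evaluation is piecewise-linear between points; above the top point the
last segment is extrapolated linearly (the top of a clinical curve is an
extrapolation anyway), below the bottom point the lowest density is
used, and negative extrapolations clamp to zero. Binning pairs by CBCT
HU (the quantity being calibrated) rather than CT HU is an
interpretation choice; it makes the curve a function of the value it
will be applied to.

On phantoms with the default scatter distortion (shift +30 HU,
compression 0.75, cupping 40 HU, noise 25 HU), the population curve
recovers true densities to an RMS of well under 0.01 RED per retained
bin, while the insert-phantom curve — built on an undistorted cylinder —
misses by an order of magnitude more. That contrast is the reason the
population curve exists.

## The MeAE statistic

Paired sCT–reference values are averaged in bins of 10 HU or 0.01
RED/DES (anchored at −1024 HU and 0 respectively), binned by the sCT
value so that the sCT–CT and sCT–CBCT tables share one axis; bins with
fewer than 100 pairs are dropped. Per retained bin
\(AE_i = |\overline{sCT}_i - \overline{ref}_i|\), and with the \(AE_i\)
sorted ascending,

\[
\mathrm{MeAE} = \tfrac12\left(AE_{\lfloor (n+1)/2\rfloor} +
  AE_{\lceil (n+1)/2\rceil}\right).
\]

Every retained intensity bin contributes exactly one value, so bone —
a small voxel fraction but dosimetrically critical — counts as much as
water-equivalent tissue. The voxel-weighted MAE is reported alongside as
the conventional (and much less discriminative) alternative. The per-bin
absolute-error distributions are tested for normality (Shapiro–Wilk; a
constant list raises an error rather than returning a p-value) and the
sCT–CT and sCT–CBCT distributions are compared with a two-sided unpaired
Wilcoxon rank-sum test per value space (exact for small untied samples,
midranks with normal approximation otherwise; two identical constant
lists report p = 1).

An sCT whose population-calibrated CBCT MeAE in DES exceeds 0.1 is
flagged for manual inspection (`qa_report()$flagged`). One caveat is
inherent to the calibration: where two tissue classes fall inside one
100 HU calibration bin (water at 0 HU and muscle at 60 HU do), the
population curve can only be piecewise-linear between bin means, so even
a perfect sCT retains a small (≤ 0.02) MeAE against the
population-calibrated CBCT. The flag threshold sits far above this
floor.

## Phantom generator

`generate_case()` builds a pelvic-like digital phantom: an elliptical
body with a fat rim, muscle interior, an anterior water "bladder", two
deliberately unequal femoral-head spheres with layered bone shells, a
pelvic-ring torus, and a segmented vertebral column. Eight tissue
classes (air to cortical bone, 300–1200 HU split into four bone levels)
give the HU histogram enough spread that every 100 HU calibration bin in
the bone range is populated at the default 96×96×32 / 2×2×3 mm grid.
Anatomy varies between cases (body and bone dimensions drawn within
roughly ±10%), because a multi-atlas without inter-subject variability
would make any atlas-based comparison degenerate.

The four modalities derive from the labelled anatomy:

* **CT** = class HU means + per-class Gaussian noise;
* **MRI** = strictly monotone (hence invertible) mapping of the class
  labels + independent noise — sufficient for patch matching, with no
  claim of MR contrast realism;
* **sCT** = the noise-free, pocket-free CT degraded by
  `sct_error_params()`: a bone HU bias, a fraction of bone voxels
  mispredicted as muscle, and a Gaussian blur emulating patch-averaged
  predictions. The bone-miss draw uses an isolated RNG substream so that
  changing the error level changes nothing else;
* **CBCT** = the noise-free CT of the CBCT's own anatomy through the
  distortion model \(\mathrm{shift} + c\,(HU - HU_0) + \mathrm{cupping}(r)\)
  (quadratic in-plane radial field) plus noise. Defaults: +30 HU shift,
  compression 0.75, cupping 40 HU, noise 25 HU — strong enough that the
  insert-phantom calibration visibly fails while the population curve
  recovers.

Transient air pockets are placed in the CT or the CBCT but never in the
sCT; common pockets appear everywhere. The CT/CBCT body outlines are
expanded by up to `outline_jitter_mm` relative to the sCT. The `truth`
element carries label maps, per-modality body masks, density maps,
pocket voxel indices and the exact distortion — everything downstream
tests compare against. What the phantom does *not* emulate: real CBCT
reconstruction physics, MR contrast, deformable anatomy. Passing tests
therefore demonstrate the correctness and calibration behaviour of the
pipeline, not clinical performance on patients.

`displaced_phantom_ct()` samples the same analytic anatomy in a rigidly
moved pose with 2× sub-voxel supersampling (partial-volume emulation).
This matters for registration testing: constructing a displaced image by
*resampling* an existing volume imprints an interpolation point-spread
mismatch that genuinely displaces the similarity optimum by a fraction
of a voxel — an artifact of the fixture, not of the matcher.

## sCT synthesis

`synthesize_sct()` is a deliberately simple patch-based multi-atlas
method: for each MRI voxel, the surrounding patch (default 5×5×3,
edge-replicated at borders) is compared with the L2-normalized intensity
distance \(d = \lVert p/\lVert p\rVert - q/\lVert q\rVert\rVert\)
against atlas MRI patches at all offsets within a search radius
(default 4 voxels) of the corresponding location; the k = 5 nearest
patches' centre CT values are blended with weights
\(\exp(-d^2/h^2)\), h = mean of the k distances. All-zero patches fall
back to the unnormalized distance; offsets are visited centre-first so
exact matches win ties, making self-atlas retrieval reproduce the paired
CT bit-exactly. Brute-force search (Rcpp) is intentional at phantom
scale; approximate neighbour structures would only obscure the tests.
Leave-one-out discipline is enforced: passing a `query_id` present in
the atlas is an error.

## Rigid bone-match registration

`rigid_register()` mimics the clinical markerless bone match: 6 degrees
of freedom (AP/LR/CC translations in mm; pitch/roll/yaw in degrees,
intrinsic rotations about the volume centre in the order pitch–roll–yaw,
axes x = LR, y = AP, z = CC). For HU-valued moving images the similarity
is the mean squared difference over moving voxels inside the 100–4000 HU
bone window (at least 500 required), divided by the in-bounds fraction
to penalize drifting off the fixed volume; for MRI no intensity
constraint applies and a 32-bin histogram mutual information is
maximized. Both images are first smoothed identically (2 mm Gaussian):
equalizing the effective point spread suppresses the sub-voxel bias that
resampling asymmetries otherwise induce. Optimization is Nelder–Mead
from a centre-of-mass translation initialization over three
deterministic point-subsampling levels, with a simplex restart at the
finest level. Everything is deterministic given the inputs.

`compute_deltas()` and `delta_significance()` implement the offset
statistics: per case and CBCT fraction, each modality's match parameters
minus the CT reference match (zero for CT by construction), pooled
per-DOF mean ± SD, Shapiro–Wilk normality, and a two-sided one-sample
Wilcoxon signed-rank test against zero (`signed_rank_test()`; exact for
untied non-zero samples, p = 1 for an all-zero sample). The clinical
literature sometimes labels this test a "paired rank-sum" test; testing
differences against zero is the signed-rank test, and that is what is
implemented.

With the default phantom (96 mm longitudinal field of view — short, as
pelvic MRI often is), recovery of displacements up to 10 mm / 5° is
within 0.05 mm / 0.2° at noise σ = 25 HU. Halving the longitudinal
extent visibly inflates the spread of the recovered CC translation and
pitch — the short-FOV coupling between those two degrees of freedom that
motivates recommending longitudinal FOVs above ~100 mm.

## Numerical and interface choices

* Axis order (LR, AP, CC), 0-based voxel indices, world mm; NIfTI
  orientation is honoured on read (permutations/flips normalized,
  oblique rejected), volumes are written RAS-aligned.
* Out-of-extent resampling fills with −1024 HU (air) so outline
  mismatch becomes air and flows into the correction rule; density
  volumes fill with 0.
* HU values are clamped to [−1024, 4000], covering the bone-window upper
  bound; the −1024 floor truncates the air noise distribution, which
  slightly raises air-insert ROI means — a real-scanner effect worth
  remembering when checking ROI statistics.
* Binning is half-open [e, e + w), anchored at −1024 HU / 0 density /
  −1024 HU for the QA, density and calibration binnings respectively.
* Problem sizes in the test-suite and acceptance script: 96×96×32
  (2×2×3 mm) for correction/calibration/QA cohorts (9 cases
  leave-one-out), 64×64×16 (3×3×6 mm) with search radius 3 for
  leave-one-out synthesis, 2000 simulations for the rank-test size
  checks (n = 14 per sample, chosen from the exact null distributions so
  the attainable size of both exact tests is closest to the nominal
  0.05). These sizes keep every stage's statistics stable while the
  whole suite runs in minutes.

## Known limitations

* The phantom's MRI is a label remapping; synthesis results show the
  machinery works, not that it rivals published sCT methods on real MR
  contrast.
* The population curve is only defined where the cohort provides ≥ 100
  pairs per 100 HU bin; sparse HU regions fall back to
  clamp/extrapolation behaviour.
* The action level (0.1 DES) is a proposed screening threshold, not a
  validated clinical decision rule.
* Deformable registration is out of scope; all inputs are assumed (or
  generated) rigidly aligned.
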