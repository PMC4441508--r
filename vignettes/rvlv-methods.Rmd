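---
title: "Automated axial RV/LV diameter-ratio measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated axial RV/LV diameter-ratio measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and why it is automated

On a CT pulmonary angiogram (CTPA), the ratio of the maximal right-ventricular
to maximal left-ventricular axial diameter (RV/LV) is a prognostic marker of
right-heart strain in acute pulmonary embolism: a dilated RV (ratio above
about 1) predicts short-term mortality. A radiologist measures each diameter
as the longest distance from the interventricular septum to the endocardium
on the original axial slices, perpendicular to the septum; the two maxima may
sit on different craniocaudal levels. The measurement is simple but
time-consuming and reader-dependent, so it is frequently omitted from
reports. `rvlvcad` computes it automatically and leaves the radiologist a
two-second accept/reject review of the placed calipers.

The pipeline has five stages, each exposed as ordinary R functions and
orchestrated by `run_case()`:

1. **Ventricle detection** (`detect_slices()`): fixed-size sliding windows on
   every axial slice are scored by one linear classifier per chamber over
   gradient-orientation-histogram features (8 signed orientation bins in a
   2x2 cell grid, L2-normalised) plus window-standardised block intensities.
   Windows are resampled to a fixed grid in millimetres, so the features are
   independent of voxel spacing; the intensity features are standardised
   within the window so a poorly opacified ventricle still presents the same
   bright-pool-against-surroundings pattern. Surviving windows are tightened
   to the bright blood-pool component they contain (Otsu threshold among
   non-lung pixels, region growing from the brightest central pixel).
2. **Anatomical pruning and clustering**: boxes with implausible physical
   size, peripheral position, or sub-blood-pool mean attenuation are removed
   (`filter_by_anatomy_prior()`); the rest are clustered across slices by
   Gaussian mean shift in world coordinates (`mean_shift_cluster()`,
   bandwidth 15 mm) and ranked by `sum(scores) * count^0.5`, rewarding both
   confidence and persistence across slices. The RV and LV clusters are
   chosen jointly under a 25 mm minimum separation between their modes,
   because the two ventricles are distinct structures; without this
   constraint both models occasionally peak on the same pool. One seed per
   member slice is placed at the cluster mode's in-plane position, snapped
   to the brightest voxel within 3 voxels (box centres drift into the atria
   near the valve plane, the mode does not).
3. **Septum estimation** (`estimate_septum()`): the septum is a dark
   myocardial slab (~60 HU) between two bright pools, so across it the
   Gaussian-smoothed image (scale 3 mm, about half a septal thickness) has a
   strongly positive second derivative while the in-slab directions are
   flat. Per voxel the Hessian eigenvalues sorted by magnitude give the
   plate score `max(l1, 0) * exp(-(l2^2 + l3^2) / (2 (c l1)^2))` (c = 0.5)
   with the l1 eigenvector as the plate normal. The plane is read off at
   the score maximum inside the dilated (5 mm) union of per-slice RV-LV
   seed segments. Candidate scores are damped by
   `exp(-|grad I|^2 / (2 * 12^2))` (HU/mm): a true slab centre has near-zero
   first derivative, whereas the flat poles of the chambers - strong edges -
   otherwise mimic plates. A gated maximum below 3 HU/mm^2 raises
   `septum_low_confidence`; that floor is an order of magnitude below the
   ~10 HU/mm^2 a normally enhanced study produces (for pool-septum contrast
   D across a slab of thickness T at scale sigma the centre response is
   `2 D (T/2sigma) phi(T/2sigma) / sigma^2`, about 12 HU/mm^2 at D = 290 HU,
   T = 8 mm, sigma = 3.3 mm effective).
4. **Segmentation** (`segment_chamber()`): a geodesic-active-contour level
   set grows from 6 mm balls around the seeds under
   `phi_t = -(p g r - b)|grad phi| + w_k g kappa |grad phi| + w_a grad g . grad phi`,
   with `g = 1/(1 + (|grad I|/25)^2)` the edge-stopping function, `r` a
   blood-pool intensity-consistency term `clamp(1 - |I - I_seed|/150, -1, 1)`
   (the balloon coasts in pool, stalls at edges, retreats in tissue), and
   `b` a soft one-sided septum barrier engaging 1 mm past the plane on the
   wrong side. The barrier is soft deliberately: the plane is an estimate,
   and a hard wall would amplify its error. Evolution (explicit upwind
   scheme, Rcpp) runs on the full cropped grid with periodic Sussman
   redistancing and the implicit function clamped to a +/-9 mm band; the
   mask is the largest connected component containing a seed.
5. **Calipers and ratio** (`slice_caliper()`, `find_valve_cutoff()`,
   `select_max_and_ratio()`): per slice, the caliper is the longest chord of
   the mask along the in-plane projection of the septum normal, scanned at
   quarter-voxel pitch with linearly interpolated boundaries (sub-voxel
   precision is needed for a 0.05 ratio tolerance at ~1.5 mm pixels).
   Because the segmentation runs through the open atrioventricular valve
   into the atrium, atrial slices must be excluded before taking the
   maximum.

## Finding the valve

What curve to analyse for the valve is the least constrained design choice
in the pipeline, and we document our construction explicitly. Per slice we
sample the radial contour profile (maximal mask radius per angle about the
seed; for non-star-shaped slices this takes the outermost boundary) and fit
a 10th-order polynomial over the angle by least squares. Two signals then
mark slices as atrial, walking cranially from the maximal-caliper slice:

* a *concave notch* in the fitted profile - the waist where a slice cuts
  both ventricle and atrium - significant when its depth exceeds 25% of the
  mean radius and 2 mm, and considered only on slices whose caliper is at
  least half the maximum (millimetre-sized polar caps wiggle the fit);
* a *trend re-increase*: ventricular cross-sections taper towards the valve,
  so a caliper rebound beyond 15% of the running minimum and 5 mm marks the
  atrium, with the valve placed at the running minimum.

Isolated calipers departing from the running median of their neighbours by
more than a factor 1.5 are excluded as outliers. When no valve evidence
exists the full range is retained. The absolute floors (5 mm, 2 mm) exist
because purely fractional rules misfire on the tiny cross-sections near the
chamber poles. The valve detector is an isolated interface
(`find_valve_cutoff()`) so alternative constructions can be evaluated
against the same inputs.

## The detector and its training data

The published system this package re-implements used a proprietary 2D object
detector trained on a labelled CTPA corpus that is not distributable. The
architecture is preserved - scored 2D boxes per axial slice, one model per
chamber - but the models shipped here are trained on phantom-derived
fixtures (`detector_training_fixtures()`): mid-ventricular slices with true
chamber boxes as positives; displaced windows, infra-apical heart-free
slices, and the opposite chamber's windows as negatives. Cross-chamber
negatives are what let a linear model tell RV from LV: the chambers differ
mainly in their spatial context (which side the septum and the other pool
lie on), which the signed orientation histograms capture for in-plane
rotations up to the 45 degrees the suite covers. The detector is a pluggable
interface (`save_detector()`/`load_detector()`, `detector_path` in
`pipeline_config()`), so a model trained on real labelled data can be
swapped in without touching any other stage.

## The phantom: what it emulates, and what it does not

`generate_phantom()` rasterises an analytically known cardiac geometry: two
ellipsoidal blood pools (RV 350 HU, LV 320 HU by default) in the frame of
the septum plane, separated by a myocardial septum that fills the gap
between the two endocardial surfaces (thickness = `chamber_separation`,
8 mm, at the equator); a mediastinal soft-tissue envelope (40 HU) inside
lung (-800 HU); optional atrial half-ellipsoids attached cranially with the
same pool attenuation as their ventricle, so the valve presents no edge -
the specific challenge the valve-exclusion stage exists for; a 1-voxel
Gaussian point-spread blur; and seeded additive Gaussian noise. Default
chamber semi-axes (24/22/32 and 22/21/32 mm) give maximal axial diameters
of 48 and 44 mm and a true ratio of 1.09, matching the means reported for
acute-PE cohorts (RV 47.9 mm, LV 44.6 mm, ratio 1.10). The ground truth -
septum plane, chamber masks, maximal axial diameters from the closed-form
ellipse chord `2 a sqrt(1 - (dz/c)^2)` maximised over the actual slice
positions - comes from the noiseless geometry.

The frozen evaluation suite (`acceptance_phantom_specs()`) spans true ratios
0.7-1.8 (the clinically relevant range from normal to severe RV dilation),
septum angles 0/15/30/45 degrees, and noise 0/10/20 HU (half the suite
noiseless), with fixed per-phantom seeds; 110 x 110 x 52 voxels at
1.5 x 1.5 x 2.5 mm. That grid is coarser than a clinical reconstruction
(0.7 x 0.7 x 1.0 mm); a single property test checks mask fidelity at
0.7 mm in-plane spacing, and the sub-voxel caliper makes the ratio
insensitive to the difference. Two degraded fixtures reproduce the dominant
clinical failure modes: an RV pool at 100 HU (poor contrast timing), which
must trip the `low_rv_contrast` flag (RV mean attenuation strictly below
150 HU); and a septum raised to pool attenuation (no slab contrast), which
must trip `septum_low_confidence`. The latter fixture carries no atria,
because the interatrial septum is itself a genuine plate between bright
pools and would otherwise be found instead.

What the phantom does *not* emulate - and hence what passing tests do not
show about clinical data: cardiac motion artifacts, contrast-bolus timing
gradients within a pool, trabeculae and papillary muscles (low-contrast
endocardial texture), non-ellipsoidal chamber shapes, and neighbouring
mediastinal structures of pool-like attenuation (aorta, pulmonary trunk).
The phantom-trained detector in particular should be expected to need
retraining on labelled clinical slices before any use on real studies.

## Parameter-fixing protocol and numerical choices

Level-set and stage parameters were fixed once using the first ten phantoms
of the frozen suite and then used unchanged for every run and test,
mirroring the parameter-fixing protocol of the clinical evaluation this
package emulates. The notable numerical choices:

* **Determinism everywhere.** Phantom noise is generated under a local RNG
  seed (the caller's RNG stream is untouched); detector training is seeded;
  every later stage is deterministic arithmetic. Two runs of a case are
  identical at the report level (timings aside).
* **Level set**: explicit Euler step 0.35 x min(spacing) (CFL-limited),
  curvature capped at 1/min(spacing) for stability, redistancing every 20
  iterations, convergence declared when fewer than 5 x 10^-4 of voxels
  change sign per 10 iterations (the front's benign interface flicker sits
  below this; the mask is stable long before). With `max_iterations = 0`
  the mask is exactly the rasterised seed balls, which the tests exploit.
* **Ties**: cluster-rank ties go to the more cranial cluster; seed-snapping
  ties go to the candidate nearest the window centre; both are documented
  and tested.
* **Degenerate inputs**: a purely craniocaudal septum normal makes the
  caliper direction undefined and errors; seeds on the wrong side of the
  septum plane (majority rule) name the chamber in the error; an empty
  mask, an empty search region, sub-10-pixel contour slices all error
  early with specific messages. Stage failures inside `run_case()` degrade
  to typed flags - a report is always produced, because the clinical
  workflow is review-based.
* **DICOM**: scope is deliberately minimal - uncompressed explicit-VR
  little-endian single-frame CT series, slices ordered by the position tag
  (never file names), inter-slice gaps validated to 10%, rescale applied.
  Pixels are stored as signed 16-bit integers, so HU round to integers on
  a DICOM round trip; NIfTI and MetaImage round trips are bit-identical.

## Problem sizes used in the shipped validation

The shipped tests and the acceptance script run the full pipeline over the
40-phantom suite (about 4 s per case end to end: detection ~1.5 s, septum
~1 s, two segmentations ~1.5 s, calipers ~0.5 s), plus the two failure
fixtures and the analytic/brute-force oracles on small grids (0.1-0.5 mm).
These sizes were chosen so the whole validation reproduces on a laptop in a
few minutes while keeping every geometric tolerance meaningful at the
suite's voxel spacing.

## Known limitations

* The detector is phantom-trained; on clinical data it is a placeholder for
  a model trained on labelled slices (the interface accepts one).
* The septum is modelled as a plane, as in the system this re-implements;
  a strongly curved septum (e.g. paradoxical septal motion) violates the
  model and will show up as a low plate score or misplaced calipers.
* The valve detector assumes the atrium re-widens or necks within the
  segmented mask; an atrium clipped entirely out of the field of view
  degrades gracefully to the full-range default.
* Axial diameters are not true short-axis diameters; this is by design -
  the measurement is defined on original axial slices so a reviewer can
  check it without reformatting.
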