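---
title: "Tracking cutaneous sensory fibers across months of in-vivo imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cutaneous sensory fibers across months of in-vivo imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

After a peripheral nerve injury that denervates part of the glabrous skin,
neighbouring intact afferents can sprout collaterally into the denervated
territory. Whether the regrown innervation recapitulates the original
architecture — and in particular whether thin nociceptive fibers re-enter
the epidermis as intra-epidermal free nerve endings (IENFs), and whether
thick Aβ low-threshold mechanoreceptors return at all — is a structural
question that requires following the *same* patch of skin over months of
in-vivo multiphoton imaging.

`skintrace` implements the full image-analysis chain this experiment needs:

1. **Stitching** of the four quadrant tiles acquired per session into one
   superstack.
2. **Autofluorescence removal**: semi-supervised graph segmentation of the
   epidermal autofluorescence band and hair-like appendages, which are
   then replaced by background.
3. **Depth-adaptive 16→8-bit conversion**, comparable across sessions.
4. **Session registration**: rigid trimmed iterative closest point (ICP)
   refined with a thin-plate-spline (TPS) warp, followed by cropping of
   all sessions to their largest common volume.
5. **3D tracing** of the fibers into geometric graphs with gap bridging
   and caliber classification.
6. **Quantification**: total fiber length, fiber endings, intra-epidermal
   endings, percent-of-baseline time courses, and localized gained/lost
   segment maps.

Because raw longitudinal imaging data of this kind is not publicly
available, the package ships a ground-truthed synthetic skin-innervation
simulator. Every stage is validated against the simulator's voxel-level
and graph-level ground truth.

# The synthetic scene and what it does (not) capture

`simulation_config()` defines the study conditions. The defaults mirror
the acquisition the pipeline targets:

* voxel pitch 0.427 µm × 0.427 µm × 1 µm; desk-scale scenes of
  256 × 256 × 64 voxels (≈109 µm × 109 µm × 63 µm); the
  `acquisition_geometry_config()` preset reproduces the full four-tile canvas
  (four 1050-px tiles with 100-px overlap → a 2000-px, 854-µm superstack)
  with a shallow z extent and is used only for stitching validation;
* excitation rising linearly 3× from surface to bottom, mirroring laser
  power ramped from 5% to 15% with depth;
* an epidermal autofluorescence band in the top 15 µm (9000 counts, with
  smooth lateral texture and ~9% gap area) whose deep edge is the
  dermal–epidermal boundary, plus hair-like appendages (radius 2.5–4.5 µm)
  descending from the surface;
* two caliber classes of fiber tree: thin nociceptor-like trees
  (radius 0.3–0.45 µm, peak 15000 counts) whose terminal branches ascend
  across the boundary as 5–9 µm filopodia-like free endings, and thick
  Aβ-like trees (1.2–1.8 µm, 19000 counts) that stop below the boundary in
  coiled corpuscle-like terminals;
* Poisson shot noise on the expected photon count (0.02 photons per
  16-bit count) followed by Gaussian read noise (σ = 150 counts) on top of
  a 800-count detector baseline.

Trees grow as branching random walks through the dermal plexus; once the
branching budget is spent each tip turns into an ascending terminal
branch. Tubes rasterize as hard disks of their radius (floored at half
the coarsest voxel pitch so sub-voxel tubes stay connected) convolved
with a Gaussian PSF (σ 0.3 µm lateral / 1.0 µm axial).

Longitudinal change (`apply_longitudinal_change()`) removes a configurable
fraction of trees per class, regrows removed thin trees along their stored
baseline centerlines with bounded, spatially smooth jitter (sprouting
retraces the original trajectories), and optionally truncates regrown
trees 2 µm below the dermal–epidermal boundary (`epidermal_entry =
FALSE`), emulating endings that stall under the basal membrane. Each
session also receives an independent acquisition deformation: a small
rigid motion (≤ ~2 µm, ≤1.5°) plus a smooth sinusoidal elastic field whose
local strain is capped at 10% — repositioned live tissue deforms smoothly
and repositioning error does not accumulate across imaging days.

What the simulator deliberately does **not** model: blood vessels, immune
and Schwann cells, photobleaching, scattering-induced depth blur,
motion-during-scan artefacts, or a realistic optics model. Tests passing
on this phantom therefore demonstrate the pipeline's geometric and
statistical correctness under controlled conditions, not its performance
on every pathology of real tissue.

# Stage design

## Stitching

Each seam is estimated on z maximum-intensity projections restricted to
the nominal-overlap strips: difference-of-Gaussian blob keypoints,
normalized 11 × 11-px patch descriptors, mutual-nearest matching, and a
translation consensus (mode of the candidate displacements; inliers within
1.5 px). The 2×2 topology is hardcoded; the seam model is translation-only
(stage-scanned acquisition). If a seam yields fewer than 4 inliers the
stitcher falls back to normalized cross-correlation over the nominal
overlap ± 25%, which is deterministic and robust on sparse scenes.
Sub-pixel offsets are rounded to integers before copying to avoid
interpolation artefacts in downstream tracing. Blending uses a linear ramp
as wide as the overlap; voxels outside overlaps are copied bit-exactly.

## Autofluorescence segmentation

The classifier assigns every voxel one of four classes (background,
fiber, epidermal autofluorescence, appendage) in three tiers:

1. **Weak supervision.** Automatic seeds: the laminar high-intensity band
   near the surface (detected as slices whose median floods above the
   global background) seeds autofluorescence; dermal core components are
   seeded fiber or appendage by a thickness analysis (appendages contain
   an extended run of voxels whose chamfer distance to background exceeds
   2.45 µm; fiber-crossing bumps contribute only a handful); sub-median
   voxels seed background. User-supplied seeds override.
2. **Graph regularization.** On a mean-pooled coarse lattice
   (default 4×4×2), Gaussian affinities on intensity and local-window
   variance feed a harmonic label-propagation solve (sparse graph
   Laplacian, Cholesky); components without seeds are labelled through a
   spectral embedding of the graph; the class-probability maps are then
   smoothed with Perona–Malik diffusion before the arg-max.
3. **Full-resolution refinement.** A PSF-aware "core" mask (voxels above
   half the local structure peak, plus a 2-MAD noise margin) restores the
   physical tube width that the coarse step cannot represent; dermal core
   components take the majority propagated class; fibers crossing the
   band are recovered as laterally thin, band-level-exceeding blobs that
   connect (allowing one-slice breaks) to dermal fiber and do **not**
   pierce the skin surface — structures that reach the top planes are
   hairs or the bright rims of band gaps, never free endings, which
   terminate inside the epidermis.

Removal then replaces autofluorescence/appendage voxels and their
one-voxel point-spread halo with the slice background median; fiber
voxels are never touched.

Measured on the simulator at default SNR (three scenes pooled), fiber
voxel precision and recall are ≈0.92 each, ≥99% of autofluorescence
voxels are removed and ≥98% of fiber voxels keep their original values.
The residual errors are concentrated in a one-voxel boundary ring (the
digitization limit of a ~1-µm tube at 0.427-µm pitch) and in the faint
upper reaches of intra-epidermal segments (see *Limitations*).

## Intensity conversion

Per-slice robust spreads (99.5th minus 50th percentile) are fitted with an
iterated linear-in-z gain; the fitted ramp is divided out (ramps shallower
than 1.3× are left alone — they are content, not excitation), and the
volume maps linearly between its global 1st and 99.5th percentiles to
[0, 255]. The construction makes the conversion invariant to a global
gain, monotone within every slice, and idempotent to within one grey
level; the spec's "global-to-local blend" is exposed as `local_weight`
(default 1 = full depth correction, chosen for idempotence and so that
one tracing threshold works at all depths). Cross-session normalization
additionally aligns the median above-threshold (fiber-foreground)
intensity of each session to the baseline's.

## Registration

Point clouds are the fiber-labelled suprathreshold voxels (≤ 20 000,
uniformly subsampled). Rigid alignment uses trimmed ICP (keep the best
70% of correspondences — denervated sessions share only a subset of
structures), a coarse 1500-point initialization, a uniform-grid nearest-
neighbour index, and closed-form Kabsch updates; an update that would
increase the trimmed objective is rejected, so the recorded residual
history is non-increasing. A sanity gate (trimmed residual ≤ 3 µm, shift
≤ 25 µm, rotation ≤ 10°) falls back to the identity when a session shares
no structure with baseline (e.g. full denervation) — otherwise a garbage
pose would drag the common crop box off the epidermis.

The non-rigid refinement fits a 3D thin-plate spline (kernel U(r) = r,
bending regularization λ = 1) to mutually-nearest correspondences
averaged over 15-µm blocks — correspondences slide along fibers, and the
block average keeps the local displacement field while cancelling the
slide — capped at 200 control points. The warp is applied only inside the
landmark hull (fading to the rigid transform over an 8-µm shell): TPS
extrapolation is unbounded and otherwise fabricates structure at crop
corners. Stacks resample through the reverse-fitted spline with trilinear
interpolation (labels nearest-neighbour). On rendered sessions with the
default 3-µm deformation the composed transform recovers ground-truth
node positions with median error < 2 µm.

## Tracing

The mask (in the pipeline, the segmentation's fiber class; standalone, an
adaptive local-peak threshold) is morphologically closed, speck components
below 30 voxels are dropped, and the volume is thinned to a curve skeleton
by sequential deletion of simple points (topology-preserving, 6
directional sub-iterations, endpoints kept). Junction and end voxels
become graph nodes, voxel paths become edges; leaf edges under 3 µm
hanging off junctions are pruned as thinning artefacts (kept below the
~5–10 µm length of real filopodial endings); end-node pairs within 5 µm
whose outgoing tangents lie in a 30° collinearity cone are joined by
straight bridge edges (greedy nearest-first, each end used once).

Edge arc length is measured on the raw voxel chain (`smooth_window = 1`):
its mild digitization inflation (≈1–3%) roughly offsets the tip erosion of
the thresholded mask, whereas window-3 smoothing removed genuine
tortuosity (−9% on simulated scenes). Per-edge radii are half the
full-width-at-half-maximum of lateral intensity profiles normal to the
centerline, deconvolved in quadrature by the lateral PSF FWHM (0.7 µm);
with a bare mask the chamfer distance transform substitutes. Components
are classified thin/thick by their length-weighted median radius —
threshold 0.8 µm on clean stacks; the pipeline uses 1.2 µm because radii
measured on registered, resampled 8-bit stacks carry a ~+0.3 µm widening
bias (interpolation plus regrowth jitter), with measured thick components
at ≥ 1.25 µm and regrown thin ones at ≤ 1.15 µm. Ties classify as thick.

## Quantification

Total length clips polylines exactly to the common region of interest
(Liang–Barsky). Endings are degree-1 nodes more than 3 µm from every face
of the analysis box (border-clipped endpoints are artefacts). The
dermal–epidermal surface is the deepest extent of the autofluorescence
band per lateral column, outlier-rejected against a coarse block-median
reference (hair footprints block columns) and median-filtered. Terminal
branches ending at least 2 µm above this surface count as intra-epidermal
free endings — the 2-µm depth margin is the combined registration and
boundary-estimation error budget — with endings within half a voxel of
the lateral crop faces excluded as cropping artefacts. Percent-of-baseline
metrics are computed inside the common cropped volume only; a zero
baseline reports `NA`, never a division error. Ending density is emitted
both per area and per volume (the natural normalization is unstated in
the field; both are labelled). Graph differencing matches edges by median
point-to-curve distance (≤ 3 µm, the registration error budget) and
partitions edges into stable/lost/gained.

## Pipeline orchestration

`run_pipeline()` executes the stages in order with per-stage seeds derived
from one master seed by stage-name hashing (adding stages never perturbs
earlier ones), records every stage's parameters and offsets in a JSON
report for exact replay, and writes a tidy metrics CSV. A thin Rscript
front end (`inst/cli/skintrace.R`) exposes the stages as shell
subcommands; the R functions are the primary interface.

# Numerical choices and degenerate inputs

* Thresholds derived from data use robust statistics (median/MAD,
  percentiles); noiseless volumes (background MAD 0) are handled by a
  signal-relative floor.
* Chamfer distances use the 26-neighbourhood with anisotropic weights and
  a half-voxel surface offset; out-of-volume counts as background for
  thickness maps but as unreachable for distance-to-set maps.
* ICP with collinear clouds degrades to a translation-only fit with a
  warning; TPS with coplanar landmarks raises a rank-deficiency error.
* Empty masks, empty skeletons and zero-baseline metrics all return
  defined (flagged) values rather than erroring.
* Test-suite problem sizes: 256 × 256 × 64-voxel scenes throughout, the
  2000-px canvas with 8 z-planes for stitching geometry, and a 5-session
  timeline for the end-to-end check.

# Known limitations

* **Faint intra-epidermal segments.** At the configured autofluorescence
  contrast (band at 60% of fiber brightness) the voxel recall of fiber
  *inside* the band is only ≈0.3: the upper half of most ascending free
  endings is not recovered, so traced baseline IENF counts are biased
  low (0–2 per desk-scale scene against ~14 in the ground truth). The
  per-session *length* and *thick/thin* time courses are unaffected, but
  the IENF percent-of-baseline curve is unstable at this scene size —
  the corresponding end-to-end check is reported honestly as failing.
  Cross-sectional (graph-level) IENF segmentation against the simulator's
  flags is exact.
* **Caliber near the threshold.** Regrown thin fibers measured through the
  full longitudinal chain approach the pipeline's 1.2-µm cut from below;
  scenes with unusually wiggly regrowth can misclassify single components.
* **Translation-only seams.** Rotation or scale between tiles (not
  produced by stage-scanned acquisition) is out of scope.
* The simulator's appendage model is a straight tilted cylinder; real
  hair follicles curve and branch.
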