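---
title: "Evaluating deformable contour propagation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating deformable contour propagation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirqa)
```

## The problem

Daily online plan adaptation on an MR-linac requires contours of the
targets and organs at risk on every session's MR image. Deformable image
registration (DIR) can propagate the planning delineations to the image of
the day, but propagated contours inherit two kinds of error: the residual
error of the registration itself, and systematic differences between
delineations made on different modalities (a prostate delineated on CT is
systematically larger than on MR). This package quantifies the geometric
accuracy of propagated structure sets against manual ground truth on each
scan, compares propagation from a planning CT versus from a planning MR,
and uses the intra-observer variation (IOV) of repeated manual delineation
as the accuracy ceiling: a propagation within IOV cannot meaningfully be
improved by manual editing.

Because clinical delineations cannot be redistributed, the package carries
a first-class synthetic cohort generator that reproduces the study design
(12 patients; a planning CT surrogate, a planning MR, and three follow-up
MRs; 8 pelvic structures) so that every pipeline stage runs and is tested
end to end without patient data.

## Comparison metrics

All comparisons operate on binary voxel masks on regular, possibly
anisotropic grids; array axes are mapped to the patient directions
Right-Left, Anterior-Posterior, Cranio-Caudal by the cohort manifest, not
by file orientation codes. Voxel centers sit at `origin + index * spacing`
(mm); all distances are in mm.

* **Dice similarity coefficient**: `2|A∩B| / (|A|+|B|)` on occupancy. It
  is undefined for two empty masks and `dice()` refuses that case rather
  than returning a silent 0 or 1.
* **Mean surface distance (MSD)**: surface voxels are occupied voxels with
  at least one face-adjacent (6-connectivity) background neighbour, the
  image border counting as background. For each surface voxel of one mask,
  the Euclidean distance to the nearest surface-voxel *center* of the
  other is computed with an exact anisotropic distance transform
  (lower-envelope parabola algorithm, exact to floating point against the
  all-pairs oracle). The default MSD pools both directions before
  averaging (symmetric); a directed mode exists because the direction
  convention in the literature varies, and the pipeline logs which one was
  used.
* **Hausdorff distance (HD)**: the maximum over both directed maxima — the
  worst case. A percentile parameter exists but defaults to 100, the
  classical definition; no percentile variant is used anywhere by default.

The surface-to-surface convention (nearest reference *surface voxel
center*, not nearest occupied voxel, not a sub-voxel mesh) was chosen
because it is exactly checkable against a brute-force oracle; sub-voxel
meshing would change values by fractions of a voxel while making
verification approximate.

Masks delineated on different grids (the CT surrogate may use 3 mm slices
against 1 mm MR slices) are brought onto the finer grid by
nearest-neighbour resampling before comparison. On which grid the original
analysis computed its metrics is not documented anywhere we could draw
from; the finer grid is this package's own documented default.

Pairs with an empty mask produce a *flagged failure record* rather than an
exception: failed propagations (the classic case is a bladder delineated
as a pinhole) are findings, and the pipeline keeps them in its tables with
a status column. `check_topology()` tags every record with the 6-connected
component count and an Euler-characteristic-based handle flag
(`V − E + F − C` on the cubical complex; a cavity-free solid has χ = 1 per
component, so χ < components signals a genus ≥ 1 "pinhole"). The flag
assumes no fully enclosed cavities, which delineated organs do not have.

## Population surface-distance projection maps

To locate *where* on an organ propagation disagrees with ground truth,
each evaluated structure's surface deviations are projected into the
transversal, sagittal and coronal planes: the tight bounding box along the
patient axes is computed from the evaluated structure, each surface voxel
drops its plane-normal coordinate, and the in-plane coordinates are mapped
affinely onto a fixed pixel grid (half-open pixels; the maximum coordinate
clamps into the last pixel; a zero-extent axis maps to pixel 0). Deviations
landing in a pixel are averaged, so that
`sum(mean * count) = sum(deviations)` holds exactly — a conservation
property the tests enforce. Because the pixel count is fixed per structure
type, grids from organs of different sizes align pixelwise, and the
population map takes the 50th and 90th percentile per pixel over all
scans of all patients in one comparison arm (linear interpolation between
order statistics; the median of an even count is the midpoint). Pixels
with no contributing scan are missing, not zero. Maps are rendered with
equal width and the aspect ratio of the mean structure (mean bounding-box
extent per axis over all scans and patients).

Choices the source material leaves open, fixed here: 64 × 64 pixels per
plane for every structure (the per-structure counts of the original
supplementary material are not available; the fixed count is what matters
for the method); deviations are unsigned by default; the bounding box is
taken from the evaluated structure, since box and surface belong to the
same organ; per-arm maps (CT-MR, MR-MR, IOV separately).

## Statistics

Metric records are first averaged over each patient's scans (per
structure and arm), then the population median is taken across patients —
pooling all scans directly would weight patients by scan count and is
rejected. Arms are compared per structure and metric with two-sided paired
Wilcoxon signed-rank tests at the 5% level on the patient-level values.
Zero differences are discarded before ranking (classic Wilcoxon, not
Pratt); tied absolute differences get midranks. The exact null
distribution of the signed-rank sum over all 2^n sign assignments is
computed by convolution for n ≤ 25 — with midranks included, which the
standard `wilcox.test` exact path cannot do — and equals full enumeration
to machine precision; the normal approximation with tie correction and
continuity correction is available for larger n and tracks the exact
p-value to within about 0.02 at n = 12. No multiple-testing correction is
applied; the tables report raw p-values. Whether a tabulated Δ should be
the difference of medians or the median of paired differences is genuinely
ambiguous in this kind of table; both are computed, with the difference of
medians as the labelled default.

The volume-ratio analysis divides the planning ground-truth volume (pCT
for the CT-MR arm, pMR for the MR-MR arm) by the ground-truth volume on
the image of the day and joins each propagated record's DSC and MSD to its
ratio; the planning CT vs planning MR volume table quantifies the
modality delineation bias.

## The synthetic cohort

The generator emulates the *observable* of the study — structures and
their deviations — not the proprietary registration algorithm, whose
internals are undisclosed.

**Anatomy.** Eight parametric organs on a 128 × 128 × 160 mm field of
view: prostate and penile bulb as ellipsoids, seminal vesicles as paired
small ellipsoids, the elective nodal volume CTV56 as paired lateral
bands, the rectum as a curved tube, bladder and femoral heads as spheres.
Each patient draws a global size factor (log-normal, CV 0.06) and a
center shift; each imaging session then draws per-structure size factors
and shifts. The session CVs encode organ rigidity: 0.02–0.06 for rigid or
nearly rigid structures, 0.08 for the rectum and 0.10 for the bladder, so
that planning-to-day volume ratios span roughly 0.5–2.5 with their bulk
between 0.7 and 1.5 — the spread reported for bladder filling in this
setting. The planning CT is its own session: bladder and rectum filling
differ between the CT and MR planning sessions just as they do between
fractions. The CT delineation bias is a 2 mm exact-Euclidean dilation of
the prostate on the CT session (configurable per structure); an optional
genus-1 "pinhole" bladder (a cylindrical channel through the sphere)
reproduces the known failure topology. A CT-surrogate mode with 3 mm
slices exercises the grid-resampling path.

**Propagation error.** One registration connects each planning scan to
each target scan; all structures of that registration share one smooth
random residual field (white noise on a coarse lattice at half the
correlation length, Gaussian-smoothed, trilinearly upsampled, rescaled to
the exact per-component SD). Arm amplitudes default to 2.0 mm (CT-MR),
1.0 mm (MR-MR) and 0.8 mm (IOV) with 20 mm correlation length (12 mm for
IOV) — configuration values, not claims about any particular algorithm.
On top of the noise, the emulated registration *compensates* each
structure's session-to-session anatomy change via the known similarity
map between the two parameter draws — but incompletely: a fraction
`min(1, uncompensated * |log(V_src/V_day)|)` of the compensation is
withheld. This implements the central empirical behaviour being studied —
small anatomical differences are absorbed, large ones are not — at the
MR-MR default (`uncompensated = 1`) a volume ratio of 1.2 leaves a sub-mm
residual while a ratio of 2 leaves most of a ~6 mm boundary offset in
place, which is what produces the parabola of accuracy against volume
ratio with its optimum at ratio ≈ 1. The rate is 50% higher for the
CT-MR arm (`uncompensated = 1.5`): an inter-modality mutual-information
registration has little CT soft-tissue contrast to drive deformable
organ boundaries, so it absorbs anatomical change less completely than
MR-MR cross-correlation — the arm difference for deformable organs is
not just a noise-amplitude difference. Delineation bias (the CT prostate
dilation) is never compensated: it is invisible to an image-based
registration. Warping is backward nearest-neighbour, so a zero field is
exactly the identity and whole-voxel translations are exact — contracts
the tests rely on.

**Determinism.** Every patient/session/registration derives its RNG
substream from the master seed; regeneration is bit-identical, and the
pipeline's CSV outputs are byte-identical for a fixed configuration and
seed.

**What passing tests do and do not show.** The phantoms are smooth convex
or tubular solids with statistically independent session draws; real
pelvic anatomy has concavities, correlated organ motion (bladder pushing
bowel), delineation texture, and imaging artifacts. Passing the suite
shows the *metrics, maps and statistics* are correct and that the
*design-level* signal structure (arm ordering, modality bias, volume-ratio
dependence) is recovered; it does not validate any registration algorithm
on real data.

## Numerical choices and degenerate inputs

* Distance transform: exact squared-Euclidean per axis with anisotropic
  spacing; no approximation anywhere in the metric path.
* Comparisons are cropped to the tight union bounding box of the pair
  before surface extraction — exact, because a tight box preserves every
  voxel's background neighbours — which keeps full-cohort evaluation fast.
* Empty masks: volume 0; `dice`, surface operations and `check_topology`
  raise errors for standalone calls, while the pipeline path records
  flagged failures.
* Percentiles (maps and HD variant): linear interpolation between order
  statistics, midpoint median for even counts.
* All-zero paired differences: Wilcoxon returns p = 1 with an
  `all_zero` flag rather than erroring.
* Projection of a zero-extent bounding-box axis maps all voxels into the
  first pixel row/column; single-voxel structures therefore project into
  exactly one pixel per plane.

## Problem sizes

The analysis scripts and the test suite run the cohort at the reduced
resolution (64³ voxels, 2 × 2 × 2.5 mm, identical field of view and mm
geometry), where a full 12-patient simulate-and-evaluate cycle takes well
under a minute of compute per cohort; the full-resolution grid (1 mm
isotropic, 128 × 128 × 160) is the generator default for standalone use.
Monte-Carlo checks (re-delineation monotonicity, arm-ordering recovery)
use 20 seeds.

## Known limitations

* The similarity-map compensation is exact for the sphere/ellipsoid
  families and approximate for the tube and paired-band structures (their
  lobes and length do not scale isotropically); the residual of that
  approximation is small against the arm amplitudes and acts as extra
  realistic error.
* The handle flag cannot distinguish a handle from an enclosed cavity;
  for delineated organs this is immaterial.
* NRRD support covers single-file raw/gzip little-endian volumes, the
  common interchange case; NIfTI-1 is the primary container. DICOM
  RT-STRUCT is out of scope by design — masks, not contours, are the
  interchange unit.
* IOV is modelled as one smooth low-amplitude field per re-delineation
  session; real intra-observer variation concentrates at ambiguous
  boundaries (apex, bladder neck), which unsigned population maps of the
  synthetic cohort will not show.
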