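---
title: "Automated tissue Doppler deformation imaging: models and methods"
author: "tdistrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tissue Doppler deformation imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdistrain)
```

## The problem

Colour tissue Doppler imaging (TDI) measures myocardial velocity along the
ultrasound beam at high frame rates. From per-view velocity fields and a
manually traced mid-wall contour, this package computes, fully
automatically, the quantities used for ischemia assessment in
echocardiography: segmental and global longitudinal strain, peak systolic
strain rate, and the post-systolic index (PSI), with noise flagging and a
noisy-area estimate. Because TDI is one-dimensional (along-beam) and noisy,
every stage of the pipeline embodies a modelling decision; this vignette
documents them, together with the synthetic phantom used to validate the
whole chain.

## Pipeline model

**Cycle selection.** The second of the available consecutive cardiac
cycles is analysed (first as a fallback for single-cycle recordings); the
cycle is delimited by R-wave markers, and all frame windows are half-open
`[start, end)`.

**Wall tracking.** The traced mid-wall contour (base of wall 1 through the
apex to base of wall 2, one trace per apical view) is advanced frame to
frame by explicit Euler along the local beam direction: each point moves by
`v * dt` along the ray from the probe through its current position, with
the velocity re-sampled bilinearly in (beam angle, depth) at the updated
position. Points traced outside the sector snap to the nearest edge beam
(ties toward the lower beam index) and points leaving the sampled depth
range are clamped and flagged. This is the simplest scheme consistent with
per-position velocity data; it deliberately performs no angle correction,
so the well-known beam-direction dependence of TDI (underestimation of
motion that is oblique to the beam) is reproduced rather than hidden.

**3D mesh.** Under the standard assumption of a 60-degree rotation between
the three apical views, the six tracked walls sit at circumferential angles
0/60/120/180/240/300 degrees (A4C wall 1 defines 0 degrees and images the
inferoseptum; APLAX wall 1 the anteroseptum at 60; A2C wall 1 the anterior
wall at 120; opposite walls at +180). Each wall is resampled to a common
longitudinal parameter -- arc-length fraction from the apex, `L` levels at
cell centers -- and, per level, the six points are interpolated around the
circumference by the unique C2 periodic cubic spline (radius and depth as
functions of angle), evaluated at `C` uniform angles. The spline reproduces
its knots, so source-plane nodes equal the tracked 2D points embedded in
3D; everything between the planes is interpolation, and artifacts in one
view propagate into the interpolated sector, as they do in the real
system.

**Timing.** Aortic valve closure (AVC) is the frame of the smallest
reconstructed cavity volume (disk summation: shoelace cross-section areas
integrated over the levels' mean depths by the trapezoidal rule), ties to
the earliest frame, with a warning flag when the minimum falls on a cycle
edge. Mid-diastole -- the end of the post-systolic search window -- is
defined as the midpoint of diastole, `avc + (cycleEnd - avc)/2`; only
"until mid-diastole" is conventionally specified, so the midpoint is a
documented design choice. An explicit AVC override is honoured when
provided.

**Segments.** The AHA 16-segment model (basal and mid thirds in six
60-degree sectors, apical third in four 90-degree sectors, no apical cap)
is applied on the (level, angle) lattice. The apex-most quarter of the
apical third's longitudinal extent is discarded from all segment
statistics, reflecting the unreliability of TDI in the apical cap.

**Deformation.** Per segment, the imaged wall(s) are evaluated at the
segment's longitudinal end points (fixed material points of the reference
trace, linearly interpolated between trace points in the reference
arc-length coordinate). The along-wall velocity of an end point is its
tracked frame-to-frame displacement projected onto the local wall tangent;
the natural strain rate is `(vFar - vNear) / L` with `L` the current
inter-point arc distance; Lagrangian strain is
`exp(integral of SR) - 1` by trapezoidal quadrature, anchored at zero at
the cycle start. Where a 90-degree apical sector contains two imaged walls
their strain-rate traces are averaged. Frames where the beam is more than
75 degrees from the wall tangent at an end point are flagged low quality,
not corrected. No drift compensation is applied: the phantom's prescribed
curves return to zero by construction, so any drift is measurable rather
than hidden. Strain traces are smoothed by a 5-frame centered moving
average (current frame plus two back and two forward; clipped at the trace
boundaries); strain-rate traces are smoothed with the same kernel by
default, controllable via `PipelineConfig@smoothSR`, since the original
system's behaviour for strain rate is not documented.

**Metrics and windows.** Peak systolic strain is the minimum of smoothed
strain over systole `[cycleStart, avc)`. Peak systolic strain rate is
searched only in `[8%, 50%)` of the systolic length, excluding the
pre-ejection spike. The post-systolic peak is searched in
`[avc + 90 ms, midDiastole)`, excluding the post-ejection spike; an empty
window is recorded as missing. PSI is
`100 * (peakCycle - endSystolic) / peakCycle` with peak-cycle strain the
most negative smoothed value over the whole cycle and end-systolic strain
read at the nearest frame at or before AVC; a flat trace gets PSI 0 with a
flag, and PSI above 100% is flagged suspect. Noise cut-offs are strict:
strain below -25% or above +5% is flagged, boundary values pass. By
default the flag examines the whole smoothed trace (cycle minimum against
the lower cut-off, cycle maximum against the upper), because a fully
reverberated segment's trace is inverted to pure apparent stretch and its
most negative value is unremarkable; restricting the check to the
peak-cycle value remains available (`noiseFlagSource = "peak"`). The noise
area fraction weights flags by subsegment area over the non-discarded
mesh; flags are evaluated per segment and inherited by the segment's
subsegments (the original subsegment granularity is unknown; the function
itself accepts any flags-and-areas decomposition). Segments are never
auto-rejected by default -- all segments enter the aggregates regardless of
quality, matching the automated system's behaviour -- but
`rejectNoisy = TRUE` implements the rejection variant.

**Aggregation and evaluation.** Territory means are unweighted over the
contributing segments of LAD = {1,2,7,8,13,14}, CX = {5,6,11,12,16},
RCA = {3,4,9,10,15}; global values average all 16. Occlusion
discrimination uses the rank-based (Mann-Whitney) AUC -- ties counted one
half, orientation fixed by the clinical direction (less negative strain,
higher PSI = more abnormal) and deliberately not folded to be at least
0.5 -- with a seeded percentile bootstrap (2000 resamples) for the 95%
interval, and Welch's unequal-variance two-sided t-test for group
comparison. A linear mixed model over segments is out of scope here; the
evaluation layer implements only the two instruments above.

## The synthetic phantom

The phantom exists so that every stage is testable without clinical data.
It emulates the *statistical and kinematic structure the pipeline assumes*,
not ultrasound physics: there is no B-mode synthesis, no speckle, no wave
propagation.

**Geometry and motion.** The left ventricle is a half-ellipsoid of
revolution (defaults: long axis 90 mm, base radius 25 mm -- a normal adult
ventricle), probe at the apex with a 10 mm standoff, views rotated
0/60/120 degrees. Material wall points slide along the meridians of the
static surface so that each segment's longitudinal Lagrangian strain
follows its prescribed curve; the apex is fixed and the base descends
toward it in systole, which is also what makes the reconstructed cavity
volume smallest at true AVC. The prescribed curve is a chain of
raised-cosine lobes through landmark extrema: zero at both cycle ends, the
systolic peak (default -18%, at the end of systole) and, for "ischemic"
segments, a post-systolic extremum `peak - pssAmplitude` at
`AVC + pssTimeMs` (default 150 ms, chosen to sit inside the post-systolic
search window with lobes wide enough that 5-frame smoothing at 100 Hz
biases the landmarks by well under a strain point). Any smooth family
anchored at the landmarks would do; raised cosines make every landmark an
exact extremum with a closed-form derivative.

**Velocity fields.** Wall velocities are projected onto the beam
directions (motion toward the probe positive) and painted onto the
beam-by-depth grid with the velocity of the nearest wall tissue: for each
beam, samples within the wall-thickness band (perpendicular distance up to
`wallHalfwidthMm`, default 8 mm, along-beam extent capped at 35 mm)
receive the velocity of the wall point nearest them, found by sliding
along the locally straight wall by the along-beam offset times the cosine
of the beam-wall angle. The wall material is continued 60 mm past the base
(an "annulus" continuation advected with the basal segment) so the field
does not end abruptly at the wall's end even at peak contraction. Noise is
additive white Gaussian velocity noise (default SD 0.5 cm/s, a mild
clinical level), drawn from the single seeded stream independently of the
SD so that the noise component scales exactly. Reverberations are
modelled as multiplicative attenuation toward zero velocity (stationary
clutter) inside a beam-by-depth band; a full-attenuation band over a
wall's basal end freezes that material point while its neighbours keep
moving, which inverts the measured strain-rate curve -- the qualitative
failure mode seen clinically inside reverberations.

**What passing tests do and do not show.** Recovery of prescribed strain
within about one strain point on the noiseless phantom shows the geometry,
tracking, interpolation and window logic are self-consistent, including
the intrinsic cosine-squared underestimation of oblique motion (the
phantom's beam projection plus the tangent projection in analysis).
It does not show robustness to out-of-plane motion, translational rocking,
clutter with realistic spectra, trace misplacement, or arrhythmia -- none
of which the phantom generates. The artifact model is a stand-in, not a
claim about the true distribution of clinical noise.

## Numerical choices and problem sizes

Mesh resolution defaults to 30 levels by 36 angles (angles a multiple of
six so source planes fall on lattice nodes); cell areas are measured at
the reference frame. The phantom defaults to 3 cycles at 100 Hz with 48
beams and 120 depth samples over 5-115 mm; the validation cohort uses 40
studies (30 normal, 10 with one ischemic territory: peak -8%, PSS
amplitude 8%) generated at 2 cycles, 40 beams and 100 depth samples --
sizes chosen so the full validation runs on a laptop in minutes while
leaving the per-study recovery tolerances unchanged. Euler tracking at
100 Hz contributes negligible integration error relative to the projection
bias because the velocity lobes vanish at the integration end points.
Degenerate inputs are errors, not silent repairs: non-finite strain rates,
segments shorter than 1 mm, self-intersecting mesh cross-sections (area
non-positive, reported with the level), bands outside the grid, and
containers with missing paths (first failing path named).

## Known limitations

The tracked contour is a single mid-wall line; radial and circumferential
deformation are out of scope, as is speckle tracking. Strain accuracy
degrades with the beam-wall angle exactly as in the real modality -- basal
segments of a wide ventricle read systematically low -- and the package
reports, by design, what the one-dimensional measurement sees. The
evaluation layer treats studies as independent; per-segment correlation
within patients is not modelled.
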