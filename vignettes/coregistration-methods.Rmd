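---
title: "Video-based probe co-registration: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based probe co-registration: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capreg)
```

## The registration model

`capreg` localises fNIRS/EEG channel positions on the scalp from a colored
point cloud reconstructed by structure-from-motion, using nine
solid-color fiducial stickers: three on the head (Nz at the nasion, AL/AR
at the preauricular points) and six on the cap (approximately Cz, Pz, Iz,
Fpz, T7, T8 of the 10-20 system — here `Cz`, `Pz`, `Iz`, `FRONT`, `LEFT`,
`RIGHT`).

Two modelling assumptions carry the whole method:

1. **The cap is quasi-rigid.** It does not stretch locally; differences in
   head size and placement are captured by a global rigid rotation plus
   scaling along the anterior–posterior and left–right axes. Under this
   family, five cap points (with the head points) already determine the
   registration; six are used for redundancy because the posterior
   stickers are hard to film on infants seated on a parent's lap.
2. **Probes are affine in the fiducials.** Each model probe is
   pre-registered as a sum-to-one weighted combination of the nine model
   fiducials, \(p_j = \sum_{i=1}^{9} w_{ij} f_i\), and the *same weights*
   are re-evaluated on the newly found fiducials of a session. Because
   every weight row sums to one, this interpolation commutes with any
   affine map: rigid motion, anisotropic scaling, and shear of the
   fiducial set move the interpolated channels exactly with it. That is
   what makes the rotate+scale placement model and the interpolation
   mutually consistent.

The per-probe weight system has four equations (three coordinates plus
the sum-to-one constraint) in nine unknowns. We take the minimum-norm
solution, \(w = A^\top (A A^\top)^{-1} b\): it is unique, symmetric (a
probe at the fiducial centroid gets the uniform row \(1/9\)), and
preserves the affine-equivariance guarantee. An affinely degenerate
fiducial configuration (all nine coplanar) makes \(A A^\top\) singular and
is rejected as an error.

## Stage by stage

### Frame masking

Frames are white-balanced by the gray-world rule (each channel's mean is
scaled to the global gray mean) — the simplest correction that stabilises
hue. Sticker pixels are those whose hue lies within `hue_tol` of the
user-chosen sticker hue, with distance measured around the hue circle;
pixels with zero saturation or value have no hue and never match. Every
8-connected cluster of at least five such pixels is one detection, circled
by its exact minimum enclosing circle (Welzl's algorithm) inflated by 20%.
The kept region of a frame is the union of cap mask, face polygon and
sticker circles; a frame strictly more than 98% blackened is rejected
(exactly 98% is kept).

The published pipeline states the hue tolerance as "± 0.15%". Read
literally as 0.15 percent of the hue circle (±0.54°) it would reject
ordinary camera noise, so this package reads it as ±0.15 *of* the hue
circle (±54°) and exposes it as `hue_tol` (default 0.15, fraction of the
circle). The 20% circle margin is applied to the continuous
minimum-enclosing radius, before any pixelation. The cap-segmentation CNN
and the face-landmark detector of the original system are out of scope:
both are pluggable contracts, with a two-hue-band fallback for the cap
and direct landmark input for the face.

### Fiducial recovery

In the cloud, sticker-colored vertices are clustered by single linkage
with a 10 mm merge radius (`link_radius_mm`); clusters with fewer than
five vertices (`min_cluster_size`) are discarded as reconstruction
speckle. Neither constant is stated in the source method; 10 mm matches
the default 10 mm sticker diameter (two stickers closer than that could
not be distinct anyway), and both are configurable.

Labeling is hypothesize-and-score: an ordered triple of model labels is
assigned to a triple of observed centroids, a closed-form three-point
similarity transform (rotation + uniform scale + translation, the
Umeyama/Horn solution) maps the model onto the observation, and the
hypothesis is scored by the summed distances of the *remaining* model
fiducials to the remaining centroids under an optimal one-to-one
assignment (exact, never double-matching — computed by branch-and-bound
over at most six points). With at most nine centroids all
\(\binom{n}{3} \times 9 \cdot 8 \cdot 7\) hypotheses are enumerated
(the similarity family is the minimal one matching the rotate+scale
placement assumption; a triple cannot determine more anyway). With more
centroids, triples are sampled deterministically from the seed.
Degenerate (collinear) triples are skipped; if every hypothesis is
degenerate an error is raised. Exact cost ties resolve to the
lexicographically first label triple, making the result order-invariant
and reproducible. The scoring loop is compiled (Rcpp/RcppArmadillo)
because the test suite exercises hundreds of full enumerations.

### Head transform and projection

The four head fiducials (Nz, AL, AR, Cz) fix the map into reference (MNI)
space. `Cz` is genuinely double-role: it is a cap sticker, but the method
assumes a well-seated cap puts it near the true vertex and uses it as the
fourth head point — with only Nz/AL/AR the vertical direction would be
poorly constrained. The fitted family is
\(y = S\,R\,x + t\) with \(S = \mathrm{diag}(s_{LR}, s_{AP}, 1)\) applied
along the *reference* axes — the subject cloud comes out of SfM in an
arbitrary orientation, so "anterior–posterior" is only well defined after
rotation. The vertical scale is fixed at 1 by default (only AP and LR
scaling are part of the model); `free_vertical = TRUE` releases it.

The fit is Gauss–Newton on (rotation, scales, translation), initialised
from the closed-form similarity fit, with the rotation update applied
multiplicatively through the exponential map and re-orthonormalised each
step. On noiseless data drawn from the same family it recovers the
planted parameters to machine precision (the acceptance suite checks
1e-6); convergence stops when the update falls below 1e-13 or after 200
iterations.

Channels are then \(\sum_i w_{ij} f_i^{MNI}\). When fiducials are missing
(at least five of nine required), the weight system is re-solved on the
available subset of *model* fiducials, so a subject identical to the
model still reproduces the model probes exactly.

### Session statistics

Validation statistics are geometric and therefore invariant under any
common rigid transform: per-channel Euclidean distances (summarised as
mean ± SD over subjects of per-subject channel means), between-session
shift vectors, the spatial angle between the two methods' shifts
(undefined and excluded, but counted, when a shift has zero length), a
one-sample Kolmogorov–Smirnov statistic against uniformity on [0°, 180°]
with the asymptotic p-value, paired t tests, and ordinary least squares
of shift sizes with the slope's F test on (1, n−2) degrees of freedom.
The original validation used linear mixed-effects models with subject
random effects; this package deliberately substitutes pooled OLS — its
acceptance properties are parameter-recovery ones (slope → 1 as noise →
0), not re-inference on the human dataset — and records the substitution
in the regression output's `note` field.

## The synthetic world

`make_model_head()` is the stand-in for the reference capture (a cap
photographed on a plastic head): an ellipsoid with semi-axes 80 × 95 × 90
mm (an adult head), fiducials at canonical directions shipped in
`extdata/fiducial_directions.csv`, and ten probes on the surface between
fiducial pairs. The axis convention everywhere is x = left-right,
y = anterior-posterior, z = up, origin at the head center, millimetres.

`simulate_subject()` applies the placement model to the whole marked
constellation — rotation (subject pose) composed with AP/LR scaling about
the head center (head-size accommodation) — and emits each fiducial as a
cluster of sticker-colored vertices under isotropic Gaussian noise.
Emitting the transform this way keeps the generator inside the family the
registration assumes, which is what makes the zero-noise round trip
*exact*: the head-transform family is the exact inverse of the generator
family. Defaults are the stated conditions of the validation experiments:
0.5 mm vertex noise (the scale of SfM reconstruction error), 200 points
per sticker, rotations up to ±30° and scales in [0.9, 1.1] for the
end-to-end acceptance runs, ±60° and noise up to 2 mm for the labeling
stress test.

What the generator does **not** emulate — and what a green test therefore
does not establish — includes: real SfM failure modes (drift, partial
reconstruction, outlier vertices far from any sticker), cap cloth
deformation beyond the global rotate+scale family, lighting-dependent hue
shifts in the cloud colors, motion blur, and occlusion by hair or hands.
The sticker diameter (nowhere stated in the source method) defaults to
10 mm. The rendered frames are flat-shaded pinhole projections with
convex-hull silhouettes; visibility uses the outward-normal rule, exact
for a convex head.

The shipped `extdata/reference_mni_fiducials.csv` holds approximate
standard 10-20 scalp positions for Nz/AL/AR/Cz in MNI millimetres; it is
an editable input, never hardcoded. Synthetic round-trip tests instead
use the model head's own fiducials as the reference so that ground truth
is well defined in the reference frame.

## Numerical choices and degenerate inputs

* Weight rows must sum to 1 within 1e-9 and reproduce the model probes
  within 1e-6 mm; violations are errors, not warnings.
* Labeling requires at least five centroids; the head-transform fit
  requires all four head labels; projection requires five of nine
  fiducials. Each failure is a typed condition (`insufficient_points`,
  `missing_fiducial`, `insufficient_fiducials`, ...) so the CLI can exit
  with a machine-parsable code.
* Hue is undefined for achromatic pixels/vertices; they can never match a
  sticker or cap hue.
* All generators are seeded and restore the caller's RNG state; the same
  seed reproduces bitwise-identical scenes, clouds and frames.
* The Perlin pattern is multi-octave 2-D lattice gradient noise (4
  octaves, persistence 0.5), min-max normalised and thresholded; any
  feature-rich two-color pattern serves the purpose, so the original
  pattern script is not reproduced.

## Known limitations

* No cortical projection or anatomical (lobe-level) labeling of channels:
  outputs are MNI scalp coordinates; atlas-based steps are downstream.
* SfM itself is out of scope; the package consumes a colored PLY cloud
  and documents that handoff (frames in, cloud out, correspondences
  limited to a two-second window in the external stage).
* The quasi-rigid cap assumption excludes elastic EEG-style caps.
* Mixed-effects inference over subjects is intentionally replaced by
  pooled OLS (see above); the reported F statistics are not comparable to
  mixed-model ones when subject variance is large.
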