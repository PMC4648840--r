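---
title: "Measuring full-field tendon strain with stereo digital image correlation"
author: "tendondic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring full-field tendon strain with stereo digital image correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Tendon and ligament tissue is anisotropic, non-linear and spatially
inhomogeneous, so a single strain gauge — or any point sensor — cannot
characterize its deformation. Digital image correlation (DIC) replaces point
sensors with an optical full-field measurement: the specimen surface carries
a random high-contrast speckle texture, small square image patches
("facets", classically 5–20 px) are treated as measurement points, and each
facet is located in every subsequent image with subpixel accuracy. With two
calibrated cameras the facet positions triangulate to 3D surface
coordinates, so rigid-body and out-of-plane motion — a major error source
for single-camera DIC — drops out of the strain estimate.

`tendondic` implements this chain for the uniaxial tendon tensile test:

1. a **synthetic rig** that renders seeded stereo speckle-image sequences of
   a loaded tendon specimen with exact ground truth,
2. **facet tracking** (integer ZNCC search + inverse-compositional
   Gauss–Newton subpixel refinement),
3. **stereo calibration and triangulation** (DLT least squares),
4. **surface strain tensors** from local least-squares displacement
   gradients in per-facet tangent planes, and
5. the **analysis layer**: virtual extensometers, grip-slip quantification,
   accuracy (scatter) assessment, stress–strain modulus fitting, the
   loading/unloading hysteresis, and the cumulative strain distribution on
   a 1 × 1 mm grid.

Because no real image data ship with the package, the synthetic rig is a
first-class, tested component: it defines the study conditions under which
every quantitative claim of the package is validated.

## The synthetic rig

### Scene and loading protocol

The specimen is a rectangular tendon surface (default 20 × 35 mm) clamped
between a bone-block clamp below and a tissue clamp above. Both clamp
plates are rendered as rigid, separately speckled bodies (white paint with
black dots — the inverse of the specimen's white-on-dark texture), so they
can serve as a grip-to-grip "virtual LVDT". The screen behind the specimen
is white.

The default loading protocol starts at a 48.9 N preload, loads in 10 N
steps while below 100 N, then in 25 N steps to a 628.3 N maximum, holds
there (representing the two-minute constant-force dwell), and unloads in
50 N steps back to the preload. Three images are captured per camera at
each load position; repeated frames at one position differ **only** in
sensor noise, which is what makes the static accuracy analysis meaningful.
The wording "the first ten steps per 10 N until 100 N" does not reconcile
exactly with a 48.9 N preload, so the increments are what the package
fixes: +10 N while the next step stays at or below 100 N, +25 N afterwards;
all increments are configurable.

### Constitutive model and ground truth

The homogeneous response is linear: `eps_yy = sigma / E` with
`sigma = F / A` (defaults `A` = 55 mm², `E` = 500 MPa — mid-range for
human Achilles tendon, where per-specimen moduli of roughly 300–800 MPa
are typical). Three observed features of
real tendon tests are layered on top, each with an exact analytic (and
therefore differentiable) form:

* **Transverse widening.** Specimens are slightly convex out of plane; under
  tension they straighten and widen. The generator models a convex bow
  (default 1 mm deep) that flattens in proportion to the load fraction and a
  positive transverse coupling `eps_xx = 1.5 eps_yy`, so the transverse
  strain exceeds the longitudinal one, as observed.
* **Strain inhomogeneity.** A smooth seeded perturbation field (Gaussian-
  filtered white noise on a coarse grid, bicubically upsampled; correlation
  length 2 mm) modulates the displacement field. Two constraints keep the
  field physically sensible: the longitudinal perturbation is centred per
  cross-section, because force balance in a uniaxial test pins the
  width-averaged strain to the nominal value; and its amplitude follows an
  envelope that is strongest adjacent to the clamps and decays to a floor
  (0.15 of the clamp-edge amplitude) mid-substance — real tests show
  elevated, irregular strains near the grips and their best accuracy in the
  specimen centre. With the default amplitude 0.3 the local longitudinal
  strain varies by roughly ±30% near the clamps; the mean over the central
  4 mm disc stays within a few percent of nominal (measured 1.000 ± 0.027
  over 20 field seeds), which is what makes central-gauge modulus recovery
  well-posed.
* **Grip slip and hysteresis.** Slip is modelled as rigid translation of
  the tendon ends relative to their clamp plates: during loading the
  cumulative slip is `s/(1-s)` times the specimen elongation (total slip
  fraction `s` split between the bone-block and tissue clamps, the former
  slipping more), so slip is exactly `s` of the commanded grip travel at
  every loading frame; slip is **not** recovered on unloading. The
  permanent set (default 0.3 mm) accrues during the constant-force hold at
  maximum load, so the loading branch of the stress–strain curve stays
  purely elastic while the loading/unloading difference at matched forces
  shows the full hysteresis. At every frame the identity
  *grip travel = specimen elongation + cumulative slip* holds exactly.

The ground truth (`ground_truth_maps()`, and the per-frame columns of
`simulate_experiment()`) is analytic: the strain maps are the exact spatial
derivatives of the displacement maps (the inhomogeneity term is
differentiated through its bicubic interpolant), verified against central
finite differences to 1e-6 and better.

### Speckle, optics and rendering

The speckle is a Poisson number of hard-edged dots (mean radius 2 px,
density 0.03 /px², i.e. ≈40% coverage — the range airbrush patterns are
tuned to; at the 0.01 /px² of sparse patterns a 21 px facet averages only
~4 dots and low-texture facets occasionally mis-register by a pixel while
still passing the quality gate) rasterized onto the dark background, then
blurred with a 1 px Gaussian. Patterns whose expected coverage exceeds 90%
are rejected as uncorrelatable. Sensor noise (default SD 1% of the dynamic
range) is added per rendered frame, never to the texture itself.

Cameras are ideal pinholes (no lens distortion — a documented limitation
for real-data use): two cameras 500 mm from the grip plane, 140 mm apart,
toed in on the mid-gauge point, with the focal length chosen so one pixel
spans 0.05 mm at the grip plane. A 20 mm tendon therefore spans ~400 px,
preserving the facet-to-feature scale of the physical rig (2486 × 1985 px
sensor) at half resolution. Frames are rendered by inverse mapping: for
every sensor pixel the pre-image on the deformed surface is found by a
short fixed-point iteration on the ray–surface intersection (the
micrometre-scale inhomogeneity term is applied as a single post-hoc
correction — its gradient is ~1e-2, so the induced error is below 0.1 µm),
and the reference texture is sampled there with bicubic (Keys, a = −0.5)
interpolation. Rendering is deterministic given the scene seed.

## Facet tracking

Temporal correlation is **reference-based**: every frame is correlated
against the (preload) reference image, so there is no frame-to-frame drift
accumulation; facet *i* in frame *k* is initialized from its converged
result in frame *k−1*, with an exhaustive integer ZNCC search (radius
10 px, ties broken toward the smaller offset) used for the first frame and
after any failure. Subpixel refinement minimizes the ZNSSD criterion with a
first-order (affine) facet shape function by inverse-compositional
Gauss–Newton — the Hessian is built once from the reference facet — with
bicubic image interpolation; convergence is declared when the displacement
update norm falls below 1e-4 px (at most 50 iterations), and the
equivalent ZNCC of the final match is reported. Facets are valid when
converged with ZNCC ≥ 0.8. Facet size defaults to 21 px — just above the
classical 5–20 px range, favouring stability at the default speckle scale —
with a 5 px grid step; all of these are configurable.

Measured on noise-free synthetic speckle, integer translations are
recovered exactly and subpixel translations to better than 0.02 px,
checked against an independent sinc-interpolated (upsampled ×100)
cross-correlation oracle.

## Stereo reconstruction

Calibration is a direct linear transform (DLT) least-squares fit of each
camera's 3 × 4 projection matrix from a synthetic planar dot target
presented at several positions and depths (a planar-only cloud is rejected
as degenerate), with the reprojection RMS reported. Triangulation solves
the homogeneous linear system by SVD; noise-free projections invert to
1e-6 mm, and near-parallel ray pairs are flagged low-confidence.

Stereo matching correlates each left-camera reference facet into the right
image with the same machinery and quality semantics as temporal matching.
For deformed frames the left reference facet is matched directly into the
right-camera frame, initialized by composing the reference disparity with
the temporal displacement; because the match is re-optimized, genuine
disparity changes (out-of-plane motion, e.g. the flattening bow) are
measured rather than assumed away. A rigid 1 mm out-of-plane translation of
a synthetic plane is recovered as (0, 0, 1.000) mm with a field SD below
0.01 mm — the out-of-plane artifact that plagues single-camera DIC is gone.

## Strain computation

Displacement gradients are estimated per facet by a weighted least-squares
fit of a linear function over a window of neighbouring facets (default
5 × 5 facets with Gaussian distance weighting, σ = half-window; at least 6
valid neighbours, else the facet is invalid — not an error). The fit is
exact for affine displacement fields (tested to 1e-10), which fixes the
estimator's bias structure: on a quadratic field the reported gradient is
exactly the WLS slope on the stencil.

For 3D surfaces, each facet first gets a local tangent plane (weighted LS
over the same window); the in-plane basis takes the projection of the
global load axis as its first direction, so `eyy` is the longitudinal
strain by construction, and `exx` the transverse one. Neighbour positions
and 3D displacements are expressed in that basis and fed to the same
gradient estimator. Both engineering strain (`exx = du/dx`,
`eyy = dv/dy`, `exy = (du/dy + dv/dx)/2`; the default, since reported
tendon strains stay below ~8%) and Green–Lagrange strain
(`E = (F'F − I)/2`, exactly rotation-invariant) are available; strains are
dimensionless internally and reported in % at I/O boundaries. Positive
`exx` means widening.

## The analysis layer

* **Virtual extensometers.** DIC-1 is the distance between the mean tracked
  positions of strips on the two clamp plates; DIC-2 the distance between
  on-specimen facet bands adjacent to the clamps. Regions stand 0.3 mm off
  the clamp edges so no correlation window can straddle the plate/tendon
  boundary (where slip opens a gap), and each region mean uses a fixed
  reference position plus the mean displacement of currently-valid facets,
  making it immune to valid-set churn. Band centres therefore sit 0.95 mm
  inside the clamps; DIC-2 consequently misses the outermost 2 × 0.95 mm of
  gauge, which biases the recovered slip fraction upward by ~2 points at
  the default geometry — the price of keeping windows off the moving
  boundary.
* **Slip.** The DIC-1 minus DIC-2 elongation difference, its fraction of
  total DIC-1 elongation at maximum load, a per-grip split (plate-minus-
  adjacent-band motion per side), and the strain overestimation factor
  (grip-to-grip strain over on-specimen strain).
* **Scatter.** Between repeated static frames the true strain is zero, so
  the strain output is pure measurement scatter; reported both as the
  max-minus-min over the whole field and as mean/SD over the central
  4.0 mm disc, because near the boundaries correlation is genuinely less
  accurate.
* **Modulus.** Stress (force over the configured cross-section) against
  central-disc `eyy` per loading step; the linear region is the contiguous
  window (≥ 8 points) maximizing r², ties broken toward the longer window
  and then higher stress — a rule chosen here, since only marks on a curve
  exist to emulate; it is configurable.
* **Cumulative strain distribution.** The analysed area is tiled with
  1 × 1 mm squares; each square takes the strain of the nearest valid facet
  within half a square diagonal (else it is excluded and counted), and
  `A(x)` is the fraction of sampled squares with strain ≤ x, evaluated on a
  fixed 0–10% grid in 0.1% steps (covering the 5% assumed damage
  threshold). The sampling rule (nearest valid facet) is a package choice;
  the ECDF itself is checked against brute-force counting.
* **Hysteresis.** Unloading-phase displacements minus the nearest-force
  loading-phase displacements, for DIC-2 (true tissue hysteresis) and DIC-1
  (which additionally contains the unrecovered slip).

## Validation under the reference conditions

The acceptance suite simulates the full default protocol (123 frames × 2
cameras at 560 × 993 px — a desk-scale sensor crop that keeps the 0.05
mm/px magnification and facet-to-speckle scale; ~8 minutes on one CPU) on a
specimen with `E` = 514.68 MPa and a scheduled 53% slip fraction, then runs
the complete measurement chain with default settings. Under these
conditions the package reproduces: R² ≥ 0.99 (measured ≥ 0.9999) between
the DIC-1 extensometer and the rig's reference displacement; overall static
scatter ≤ 0.3% strain and central scatter SD ≤ 0.03% strain; the slip
fraction within 3 points of schedule with an overestimation factor ≈ 2;
the generating modulus within 5% (measured within ~1%); and `A(2%)` of a
constructed field with a calibrated 80% sub-2% area fraction within 3
points. `scripts/acceptance.R` recomputes exactly these numbers from
scratch for any seed.

## What the synthetic tests do and do not show

The generator emulates the geometry, optics, loading schedule, slip,
hysteresis, inhomogeneity and sensor noise of a real rig, with exact ground
truth — that is what lets tracking accuracy, scatter and parameter recovery
be measured at all. It does **not** emulate: lens distortion, specular
reflections or moisture glare, drying or viscoelastic creep, fluid droplet
formation, non-rectangular specimen silhouettes, or texture decorrelation
at large strains. Passing the suite therefore demonstrates the correctness
of the measurement chain, not the hardware robustness of a physical setup;
real-data use would at minimum require a distortion model in the
calibration stage.

## Numerical choices

* Bicubic (Keys, a = −0.5) interpolation everywhere an image is sampled off
  the pixel grid; image edges are clamp-padded.
* IC-GN convergence at 1e-4 px update norm, 50-iteration cap, divergence
  declared if the update exceeds the search window.
* Patches whose intensity variance is below 1e-20·n are treated as
  textureless (ZNCC undefined → NA / no-match), which also catches uniform
  patches whose floating-point variance is a rounding residue.
* Integer-search ties break toward the smaller displacement magnitude,
  then row-major order; `fit_modulus` r² ties (within 1e-9) break toward
  the longer window, then higher stress.
* The 3 × 3 normal equations of the gradient/plane fits are solved in
  closed form (cofactors), vectorized across facets; windows with a
  singular system are invalid, not errors.
* Physical units are mm, N, MPa and % strain; image intensities live in
  [0, 1] regardless of file bit depth, converted only at I/O boundaries.
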