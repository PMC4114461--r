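---
title: "Position and orientation tracking for Freezing-of-Gait monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position and orientation tracking for Freezing-of-Gait monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Freezing of Gait (FoG) in Parkinson disease is strongly context-dependent:
episodes cluster at doorways, turns, destinations and other spatial triggers.
A monitoring system that wants to exploit this needs the patient's 2D pose —
floor position $(x, y)$ and heading $\theta$ — continuously and indoors.
`fogtrack` implements such a pose pipeline: overhead depth cameras track the
position of an upright person on the floor plane, and a waist-worn
smartphone-class MARG sensor (gyroscope, accelerometer, magnetometer at
100 Hz) supplies the heading, fused with the vision stream by one of two
methods. Because no recordings of the original laboratory study are
available, the package also contains a seeded synthetic generator that
emulates the full accuracy-assessment protocol, so that every stage is
testable end to end.

## Coordinate frames and conventions

All angles are degrees, measured **counterclockwise when the floor is viewed
from above**, in $[0, 360)$.

* **World frame**: $z$ up; the $x$-axis is aligned with (magnetic) North in
  the inertial filters' world.
* **Tracking frame** (per camera): origin on the floor directly below the
  camera, $y$-axis the in-plane projection of the optical axis, $x$-axis
  completing a right-handed basis. Headings are measured against this
  $x$-axis.
* **Device frame**: worn at the left hip, $x$ up, $y$ along the wearer's
  forward (dorsoventral) axis, $z$ to the left. Gravity therefore lies along
  the negative $x$-axis of the device.
* $\alpha$ is the compass heading of the projected device $y$-axis, $\psi$
  the rig angle between the camera forward axis and North — both in the same
  counterclockwise sense as $\theta$. With the correction
  $\theta = \alpha - \psi + 90^\circ$ this is the unique self-consistent
  choice: the $+90^\circ$ step implicitly places the camera $y$-axis at
  $+90^\circ$ from the $x$-axis, which fixes the counterclockwise sense for
  every other angle.

## Position: plan-view particle-filter tracking

Background subtraction uses only the depth image: a pixel is foreground if it
is valid and more than $\tau = 0.10$ m closer than the per-pixel background
reference, which is refreshed (median of 5 frames, at most every 120 s) only
when no tracks are active. Foreground pixels are back-projected to 3D,
expressed in the tracking frame, and binned on a floor grid (cell
0.05 m) into plan-view maps: per-cell **maximum height** and **occupancy**
(each pixel weighted by its physical footprint $z^2 / (f_x f_y)$ in cell
units, making occupancy range-independent). Points below a **height cut-off**
of 1.0 m are discarded, which makes the tracker blind to furniture-level
scene changes by construction.

Because a depth camera sees only the camera-facing surface of the body, the
back-projected cloud sits about half a torso depth closer to the camera than
the body axis; points are therefore shifted 0.10 m radially away from the
camera base before binning. Without this correction the position estimate
carries a systematic toward-camera bias of roughly the same magnitude.

Each person is tracked by an independent particle filter ($N = 300$) over
$(x, y, v_x, v_y)$ with a first-order linear dynamic model (per-step noise
0.03 m / 0.25 m/s) and an observation likelihood formed as a Gaussian-kernel
(bandwidth 0.08 m) smoothed mixture of normalized occupancy (weight 0.625)
and a height-plausibility score (weight 0.375, Gaussian around 1.65 m with
sd 0.4 m); the colour term of the original three-map mixture is dropped
because the synthetic scenes carry no colour. Weights are renormalized each
frame and systematically resampled when the effective sample size drops
below $N/2$. New persons are seeded from connected components of occupied
cells with summed occupancy $\ge 50$ and maximum height $\ge 1.3$ m, outside
a 0.5 m exclusion radius of existing tracks; tracks are confirmed after
3 supported corrections and dropped after 5 consecutive unsupported frames.
A dense-grid Bayes filter with the same observation model serves as the
independent oracle in the tests; the two agree within 1.5 cells.

## Orientation filters: GROE and AOE

Both filters carry a unit quaternion (device to world) advanced by gyroscope
integration plus one normalized gradient-descent step toward the reference
directions — gravity alone (**GROE**; yaw is a gauge freedom) or gravity plus
the Earth's magnetic field (**AOE**; absolute). Gains follow the values
recommended in the gradient-descent AHRS literature: $\beta = 0.1$ (GROE) and
$\beta = 0.041$ (AOE); the filters are initialized from a closed-form
attitude (minimal tilt rotation, or the gravity/field TRIAD solution), which
replaces a slow large-angle convergence transient. Magnetometer vectors are
normalized before use; hard/soft-iron calibration is out of scope.

## Heading Method 1: AOE plus static rig angles

With the device in its expected mounting, the projection of the device
$y$-axis onto the floor gives the compass heading $\alpha$, and
$\theta = \alpha - \psi + 90^\circ$ maps it into the tracking frame. The
method needs a calibrated $\psi$ and the assumed mounting; a mount rotated by
$\gamma$ shows up directly as a $-\gamma$ bias in the heading error, which is
exactly the signature used in the evaluation.

## Heading Method 2: GROE plus a vision reference

GROE leaves the heading gauge undetermined and the mounting unknown; both are
absorbed by one **correction angle** $\delta_c$. The vision side proposes a
**static heading**: a 21×21-cell height template centred on the tracked
person (normalized by its maximum; 441 values plus the normalization
constant and the nonzero-cell count give 443 attributes) is classified by a
443–25–8 feed-forward network (symmetric-sigmoid units, classic
back-propagation on mean squared error with ±1 one-hot targets) into eight
45°-heading classes; the winning activation, mapped to $[0,1]$, is a quality
score. The static heading is accepted only after 3 consecutive frames of the
same class with quality above 0.8, and is **confirmed** as the external
reference $\theta_s$ when it agrees with the **dynamic heading** (the
least-squares velocity direction of the track over 0.5 s, gated at
0.3 m/s) within ±15° for 3 consecutive frames. On a confirmation frame
$\delta_c = \theta_i - \theta_s$, where $\theta_i$ is the heading of the
projected device $y$-axis in the GROE gauge; afterwards
$\theta = \theta_i - \delta_c$. $\delta_c$ is frame-independent (both terms
shift equally under a change of tracking frame), so a single correction
spans camera hand-offs, and it is recomputed at every new confirmation
(latest wins), absorbing slow gyro-bias drift of the GROE yaw. Before the
first confirmation the heading is withheld rather than extrapolated, so
stops visited earlier appear as missing values — the replication reproduces
a missing-stop rate of the same order as the original study's 11/288.

The classifier's characteristic error mode is confusion between opposite
classes ($k$ vs $k+4$): the trunk cross-section is symmetric, and only the
ventral head offset breaks the tie. Wrong references registered this way,
and references confirmed on walk legs that pass the ±15° gate at up to
~20° from a class centre, are the dominant sources of Method2 error — the
same behaviour the original evaluation reports.

## The synthetic generator

The generator emulates the accuracy study, not arbitrary scenes:

* **Rig**: two virtual depth cameras (640×480, 57° horizontal field of view,
  2.25 m height, 25° downward pitch, depth valid 0.4–6 m) covering an
  8×5 m area in non-overlapping halves, as in the original two-camera setup.
* **Protocol**: 12 participants; per mount condition two walks (left-start
  and right-start) that together visit the 12 numbered reference poses on
  the 0.5 m marker grid (three physical markers are revisited under a second
  number); 3 s stops; walking at 1.0 m/s with on-the-spot turns at 120°/s.
  Participants stop near, not on, the marker (positional jitter sd 0.05 m,
  heading jitter sd 3°), as real participants did; the truth table records
  the actual pose, so tracker error is separated from placement error —
  something the original study explicitly could not do.
* **Bodies**: trunk with elliptical cross-section (shoulder width ~0.45 m,
  chest depth ~0.26 m), narrower leg section and a head sphere offset
  0.04 m ventrally; heights drawn from Normal(1.742, 0.088) m. The ventral
  head offset is what makes front and back learnable at all for the
  classifier — real bodies provide this asymmetry naturally.
* **Depth noise**: $\sigma(z) = 0.0019\,z^2$ m, the standard quadratic
  structured-light noise law.
* **IMU**: device orientation composed of the body heading, the mount
  rotation (0° for Position1; uniform 50–60° clockwise for Position2, fixed
  per participant) and a small random mounting tilt (sd 2°); accelerometer =
  gravity + trajectory acceleration + a step-frequency bounce while walking
  (1.5 m/s² vertical at 1.9 Hz) + noise (sd 0.05 m/s²); gyroscope = true
  rate + noise (sd 0.005 rad/s) + constant per-axis bias (sd 0.002 rad/s);
  magnetometer = Earth field direction (inclination 67°) + noise (sd 0.01).
  Torso sway during gait and the hip's offset from the turning axis are not
  modelled; both would perturb the filters mildly but identically for both
  methods.

What passing tests on this generator do show: the geometry, the filters, the
classifier and the fusion logic are implemented consistently and reach the
published accuracy bounds under the stated conditions. What they do not
show: robustness to articulated and stooped postures, loose clothing,
magnetic disturbances, occlusions or multiple people — none of which the
generator emulates (the original study flags several of these as future
work).

## Numerical choices and degenerate inputs

* Angles wrap to $[0,360)$; signed differences to $(-180, 180]$ with the
  antipodal case mapped to $+180$.
* Quaternions are renormalized after every filter step (norm drift
  $\le 10^{-9}$); the axis projection errors out when the device $y$-axis is
  within 5° of vertical.
* The floor-plane fit uses 200 consensus rounds with a 0.02 m inlier
  tolerance and a 0.5 minimum inlier fraction, refined by a least-squares
  (smallest principal direction) fit on the inliers; collinear samples are
  skipped and an unreachable consensus is an error.
* Classifier ties break toward the lowest class index; an all-zero template
  classifies with quality 0. Features are standardized inside the model
  (the raw attribute scales differ by two orders of magnitude).
* Stop windows are 1 s centred in each stop interval; position windows are
  accepted under the 0.04 m per-coordinate standard-deviation rule. The
  rule's units are interpreted as metres and applied to position only;
  heading windows use a 15° circular-sd gate instead. Per-point "average
  angles" are circular means.
* The replication runs the tracker at 15 Hz (half the nominal 30 Hz sensor
  rate), which keeps a full 48-walk replication within minutes while leaving
  all temporal rules (3-frame runs, 0.5 s velocity windows, 1 s stop
  windows) well sampled.

## Design choices that were genuinely open

* **Walk scripts**: the original marker layouts are given only as schematic
  figures; the generator treats the published per-point reference
  coordinates as canonical and splits the 12 points into two 6-stop walks
  (this is the only reading consistent with the published count of
  12 points × 12 participants × 2 conditions = 288 stops).
* **Sign conventions**: the source text never fixes the sense of $\theta$,
  $\alpha$ or $\psi$; the package uses counterclockwise-from-above
  throughout, the unique choice consistent with the $+90^\circ$ correction
  (see above).
* **$\delta_c$ updates**: recomputed at every confirmation rather than once;
  a single early bad reference would otherwise poison a whole walk, and
  re-confirmation is what bounds GROE yaw drift between references.
* **Classifier training corpus**: four synthetic trainer bodies standing on
  a 0.5 m grid over the camera's usable coverage at all eight classes, with
  ±10° heading jitter and two noise realizations (~4700 templates,
  comparable to the original ~6000). Training over the full coverage is
  essential: a classifier trained on a narrow central grid degrades exactly
  on the walk segments near the coverage edges.

## Known limitations

Single-person scenes only (multi-person association and re-identification
are out of scope, as in the original evaluation); upright posture assumed;
no magnetometer calibration; the dynamic-heading gate (0.3 m/s over 0.5 s)
and the detection thresholds are engineering defaults the original work does
not specify. Method2 depends on walk legs roughly aligned with a 45° class
centre to confirm references; trajectories that avoid such legs delay or
lose heading output, which mirrors the original system's reported failure
cases.
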