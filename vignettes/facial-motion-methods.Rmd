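---
title: "Methods: 3-D dynamic quantitative analysis of facial motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3-D dynamic quantitative analysis of facial motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemotion3d)
```

# The measurement problem

Grading facial-nerve function from visual inspection is subjective and
poorly repeatable. A marker-based optical motion-capture system makes the
assessment quantitative: small retro-reflective markers are placed on 21
anatomically defined facial points, six synchronized cameras observe them
at 100 frames per second, and the system reconstructs each marker's 3-D
trajectory while the subject performs ten standardized expressions. From
the trajectories it derives static measures (inter-landmark distances,
angles, direction components) and dynamic measures (maximal deviation,
speed, acceleration, moving direction) in an anatomically meaningful
coordinate system. This package implements that pipeline end to end,
together with a synthetic capture generator that stands in for the
hardware, so that every algorithmic stage can be validated against known
ground truth.

# The synthetic capture rig

The simulator emulates the physical system's study conditions:

* **Cameras.** Six ideal pinhole cameras (no lens distortion) on a
  1360 × 1024 sensor, arranged as two perpendicular rows of three — a
  symmetric "L" — each 800 mm from the volume centre and aimed at it.
  The focal length defaults to 2000 px, i.e. roughly a 10 mm prime lens
  at a 5 µm pixel pitch; at the working distance this gives ≈0.4 mm per
  pixel of lateral resolution, which puts reconstruction errors at the
  default noise level in the few-tenths-of-a-millimetre regime the rig
  is designed for while keeping the whole calibration volume inside all
  six frusta. Distance-dependent lens effects are deliberately not
  modelled, so hardware-specific results (the reported 60–90 cm
  distance sweep and its 80 cm optimum) are out of scope here.
* **Noise.** Additive i.i.d. Gaussian pixel noise, default
  σ = 0.5 px per observation coordinate. Everything downstream is
  seeded; identical configuration + seed reproduces a dataset
  bit-for-bit.
* **Phantoms.** The calibration wand (T-rod) carries three collinear
  markers at 100/150 mm spacings (the reported geometry states
  collinearity but not spacings; these are configurable defaults). The
  accuracy phantoms are the 176.84 mm two-marker linear rod and the
  three-marker right-angle L-rod. Phantom body frames sit at the marker
  centroid so a randomly posed phantom stays centred in the swept
  volume.
* **Face.** A rest-pose template with the 21 landmarks plus 3 helmet
  markers, mirror-symmetric across the midline. No coordinates are
  reported, so the template (in `inst/extdata/face_template_synthetic.csv`)
  is an invented but anatomically plausible adult face; it is marked
  synthetic and user-replaceable. The three helmet markers form a wide
  triangle (90 mm base, ≈45 mm height): the helmet frame's orientation
  noise scales inversely with the reference triangle's extent and is
  amplified by the ~150 mm lever arm to the lower face, so a deliberately
  well-spread triangle is essential for sub-half-millimetre head-motion
  compensation (see Reference frames).
* **Expressions.** Each of the ten standardized expressions is a
  per-landmark peak displacement field with a raised-cosine
  onset (0.5 s) – hold (1 s) – offset (0.5 s) profile. The reported
  protocol specifies only verbal cueing, so both the temporal profile
  and the displacement amplitudes (3–15 mm depending on the movement)
  are simulator choices, not measured values. Head motion is smooth
  seeded sinusoidal rigid motion (a few degrees / up to ~12 mm by
  default); helmet markers undergo head motion only, facial landmarks
  undergo head motion composed with the expression field.

What the simulator does *not* emulate: lens distortion, motion blur
(rapid wand motion is representable only as observation dropout), skin
sliding and soft-tissue dynamics, marker-blob detection (observations
are already point coordinates), and between-repetition variability of a
subject's expressions. Tests passing on synthetic data therefore
demonstrate the correctness of the computational chain under the stated
noise model, not the field performance of any camera hardware.

# Calibration

Each camera's 3 × 4 projection matrix is estimated by the normalized
direct linear transform from (known 3-D wand position, observed 2-D
point) correspondences, with Hartley-style conditioning of both point
sets before solving the homogeneous system. The commercial system
self-calibrates from the wand alone; full self-calibration is outside
this package's scope, and the wand's true positions come from the
simulator manifest (or any surveyed target), preserving the visible
contract: wand sweep in, projections plus an error gate out.

The *calibration systemic error* is never defined by the reported
system, so the package declares a stand-in: the RMS, over sweep frames,
of the difference between reconstructed and known wand inter-marker
distances (all three pairs). All frames are used up to 5000, beyond
which a seeded subsample of 5000 is taken. The protocol's gate — fewer
than 0.3 mm, with at least 3000 frames per camera — is enforced as a
pass flag plus a frame-budget warning; short sweeps warn rather than
fail so degraded sessions remain inspectable. At the default rig and
σ = 0.5 px, a 3000-frame sweep lands at ≈0.19 mm and passes.

# Reconstruction and tracking

Triangulation is homogeneous linear least squares (DLT) over all
observing cameras; two views suffice mathematically, and the protocol's
"at least three cameras" rule is enforced as a quality flag rather than
a failure so that degraded frames stay analyzable. Iterative
reprojection refinement proved unnecessary at this noise scale — the
test suite shows the linear solution agrees with a Gauss–Newton
reprojection-minimizing oracle to 10⁻⁹ mm on noiseless data.

Marker labelling uses a declared stand-in for the system's undescribed
"reference database": the first frame is matched to a labeled template
by mutual nearest neighbours (ambiguities are hard errors listing the
offending markers), and subsequent frames by gated nearest-neighbour
tracking with a maximum inter-frame displacement of v_max / f
(default 500 mm/s at 100 Hz = 5 mm/frame), assigned greedily in order
of increasing distance with one-to-one uniqueness. With markers spaced
far above the gate — true for this landmark set — the greedy assignment
coincides with the exhaustive minimum-total-distance matching, which
the tests verify on small clouds. Gaps of at most 10 frames (0.1 s) are
filled by cubic spline interpolation; longer or edge gaps are left
flagged, never extrapolated.

# Reference frames

**Helmet frame.** The three rigid helmet markers determine an origin and
a plane; the frame is: origin at the marker centroid (the reported
description says only that the markers determine "an origin"; centroid
is the declared choice, configurable), third axis the unit plane normal
(sign fixed toward the face at session start, then tracked by
continuity), first axis the direction from origin to marker 1
orthogonalized against the normal, second axis completing a
right-handed triad. Re-expressing landmark positions per frame in this
frame removes rigid head motion exactly, which is what makes free head
movement during capture acceptable.

**Anatomical frame.** Computed once from the rest pose in helmet
coordinates and held fixed thereafter — the helmet, not the face,
provides dynamic stability, because no facial point is truly static.
The horizontal plane passes through the two tragus points and the nasal
reference point; the sagittal plane is perpendicular to it through the
nasal point; the coronal plane passes through the left tragus
perpendicular to both. Axes follow the reporting conventions: Y is the
horizontal-plane normal (up "+", oriented by the brow-versus-lower-lip
direction), X the sagittal normal (left "+", from right to left
tragus), Z = X × Y (forward "+", toward the cameras). The origin is the
intersection of the three planes. Two reported phrasings — "root of
the columella nasi" (landmark I) and "nasal center point" — are
ambiguous about which point anchors the planes; the package uses I
(midline, and in the spirit of the horizontal-plane description),
configurable to K.

# Kinematics

Velocity and acceleration come from central differences at the capture
frequency, after optional Savitzky–Golay smoothing (window 11 samples =
0.11 s, polynomial order 3). Savitzky–Golay was chosen over a moving
average because it preserves peak amplitudes, which are the reported
quantities; both window and order are configurable and logged. The
filter is exact for polynomial trajectories up to the fitting order and
attenuates a 2 Hz expression-scale sinusoid by well under 1%.

Per expression and landmark the summary reports the maximum deviation
from the rest position (mean over a rest window preceding the cue), the
maximum speed and acceleration magnitude, and the moving direction as
the unit displacement vector at maximum deviation. The 20-row static
measure set (distances G-H, g-h, I-G, I-g, H-h, E-H, E-h, II-III;
vertex angles ∠CED, ∠ced, ∠EHh, ∠ehH with the middle letter as vertex;
X and Z direction components for the four nasolabial segments) is
computed on rest landmarks in anatomical coordinates. "Direction" for
the static rows is never defined in the reported table; the package
declares it as the X/Z components of the unit vector from the first to
the second landmark. Expression windows come from the cue schedule in
the configuration; there is no automatic segmentation.

# Accuracy protocol

A rod session (static ≈5 s, dynamic ≈60 s) is simulated, reconstructed,
and measured per frame (end-to-end distance, or the angle at the
L-rod's corner marker); at least 10 frames are sampled uniformly
without replacement, and the sampled values are tested against the
manufactured reference with a two-sided one-sample t-test. "Average
error" is reported both signed and absolute, since the reported wording
is ambiguous between the two. The reported accuracy magnitudes
(0.19 mm, 0.29°) depend on unmodelled optics and are not asserted
anywhere; the simulated chain is required only to show the structural
properties — exactness at zero noise, and error monotone in noise.
The reference worked test statistic (t = 1.51 with p = 0.165) implies
df = 9, consistent with a 10-frame sample; the accompanying tabulated
mean ± SD pair is not internally consistent with that t and is not
asserted.

# Reliability

Test-retest agreement uses the one-way random-effects single-measures
intraclass correlation ICC(1,1) = (MSB − MSW)/(MSB + (k−1)MSW). The
reported analysis never states its ICC form; ICC(1,1) was selected
because it reproduces every tabulated 95% confidence interval of the
20-row static reliability table from the tabulated point estimates at
n = 19 subjects and k = 2 sessions, to the table's tabulated precision.
Confidence bounds use the F pivot: F = (1 + (k−1)ICC)/(1 − ICC),
lower = F / F₀.₉₇₅(n−1, n(k−1)), upper = F · F₀.₉₇₅(n(k−1), n−1), each
mapped back through ICC = (F* − 1)/(F* + k − 1). Missing sessions are
excluded pairwise per parameter with a logged count, never imputed;
zero-variance tables are flagged undefined.

Two cohort generators support parameter-recovery testing: a pure
variance-components cohort (subject truth ~ N(µ, σ_b²), sessions add
N(0, σ_w²)), whose estimated ICC must recover σ_b²/(σ_b²+σ_w²), and a
face-level cohort that perturbs the template per subject
(σ_between = 3 mm) and per session (σ_within = 0.3 mm) before running
the static measure set. Synthetic direction components come out nearly
as reliable as distances — unlike real subjects, the simulator repeats
an expression identically, so the between-repetition inconsistency that
degrades direction reliability in practice is absent by construction.
The reported dynamic-ICC extremes (0.999 / 0.11) came from volunteer
data that is not tabulated and are not reproducible; the tabulated average
distance ICC of 0.973 does not equal the mean of the table's eight
distance rows, so its averaging set is unknown and it is likewise not
asserted.

# Numerical choices and problem sizes

* Collinearity tolerance for plane/frame construction: triangle area
  below 10⁻⁶ mm² is degenerate.
* DLT solves use the eigenvector of the 12 × 12 (or 4 × 4) normal
  matrix after Hartley conditioning; projections are normalized to unit
  Frobenius norm.
* The helmet-plane normal's sign is a hint-plus-continuity rule, which
  keeps the frame stable through arbitrary head rotation.
* The test suite and the demo subcommand run the same pipeline at
  reduced sizes (400–3000 wand frames, sessions of a few seconds,
  cohorts of 8–19 subjects); these sizes are stated here as the
  package's own validation choices and keep the whole suite in the
  tens of seconds on one CPU.

# Known limitations

Point-landmark only (no surface meshes); no lens distortion or bundle
adjustment; no blob detection; no clinical grading score — the package
measures motion, it does not grade palsy; and synthetic reliability
overstates the repeatability of direction measures for the reason given
above.
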