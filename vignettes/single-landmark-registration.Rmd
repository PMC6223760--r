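---
title: "Single-landmark image-to-patient registration: model, simulator and numerical choices"
author: "slreg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-landmark image-to-patient registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slreg)
```

## The registration problem

Image-guided laparoscopic surgery overlays preoperative image data (MR or
CT volumes, segmented models) on the live view of tracked instruments. The
prerequisite is *image-to-patient registration*: a rigid transform
$T = (R, t)$ mapping image-frame coordinates into the tracking reference
frame attached to the operating table, $p' = R\,p + t$. Once $T$ is known,
a tracked 2-D laparoscopic ultrasound (LUS) probe can display its slice in
the registered scene, and conversely a point clicked on the US image can
be placed in the image volume.

`slreg` implements two registration routes and everything needed to
simulate and evaluate them.

### Fiducial-landmark registration (FLRM)

The classical method: $n \ge 3$ corresponding fiducials
$\{(x_i, y_i)\}$ are matched in the least-squares sense,
$$\min_{R \in SO(3),\,t} \sum_i \lVert R x_i + t - y_i \rVert^2 .$$
`flrm_register()` solves this in closed form: subtract centroids, take the
SVD $U D V^\top$ of the cross-covariance $\sum_i \tilde x_i \tilde
y_i^\top$, set $R = V U^\top$ (flipping the sign of the last singular
direction when $\det < 0$, so the solution is a rotation and never a
reflection), and $t = \bar y - R \bar x$. The fiducial registration error
(FRE) is the RMS residual over the fitting pairs. The solution is
cross-checked in the test suite against a brute-force numerical minimizer
over the rotation parameters.

### Single-landmark registration (SLRM)

FLRM needs several accessible fiducials — often unavailable or slow to
sample intraoperatively. The single-landmark method replaces them with an
orientation prior plus one landmark:

1. **Initialization.** A tracked tool is laid along the patient's
   longitudinal (cranio-caudal) axis, parallel to the coronal plane. Its
   measured orientation *is* the rotation of the registration, mapped
   through a fixed tool-axis convention (below). One anatomical landmark,
   marked in the image and touched with the tracked pointer, fixes the
   translation: $t = p_{patient} - R\,p_{image}$. The landmark therefore
   maps exactly, by construction.
2. **Re-registration.** Any new landmark sampled later — typically a
   lesion centre clicked on the tracked US image — updates only the
   translation by the same formula, keeping $R$ fixed (bitwise, in this
   implementation). Only the latest point is honoured; there is no
   history blending, matching the "match the newest point" behaviour the
   method is defined by.

Because rotation errors pivot the volume about the registered point, the
error at a target a distance $d$ away (perpendicular to the error axis) is
the chord length
$$\mathrm{TRE}(d) = 2\,d\,\sin(\theta/2),$$
for an orientation error $\theta$: exact at the registered point, growing
linearly-ish with distance ($\approx d\,\theta$ for small $\theta$). At
$d = 60$ mm, $\theta \approx 11.9^\circ$ gives $\approx 12.4$ mm. This
error law is asserted exactly (to $10^{-9}$ mm) in the test suite.

### Patient orientation (supine/prone)

The pointer must face upward in both patient positions so its optical
markers stay visible. For a prone patient the acquired orientation is
therefore pre-composed with a 180° rotation about the longitudinal axis,
$R \leftarrow R\,R_x(\pi)$. Whether the flip is applied to the tool pose
or the image volume is an equivalent choice of convention; this package
applies it to the acquired orientation.

## Coordinate conventions

These are documented choices; any fixed convention works because image and
patient frames use the same one.

* **Patient frame axes**: column 1 = longitudinal (cranial→caudal),
  column 2 = left–right (completing right-handedness), column 3 =
  anterior "up".
* **Tool axes**: the pointer's local $+x$ lies along the patient
  longitudinal axis, its local $+z$ anterior. `rotation_from_axes()`
  rebuilds the frame from those two measured directions by Gram–Schmidt
  (column 3 is the component of "up" orthogonal to the longitudinal axis)
  and refuses inputs within $10^{-6}$ rad of (anti)parallel.
* **Quaternions**: component order $(w, x, y, z)$, the convention of
  tracker pose files; rotations are stored as matrices internally and
  quaternions appear only at I/O boundaries.
* **US pixels**: 0-based, $u$ = column (lateral), $v$ = row (axial
  depth), points at pixel centres, image plane $z = 0$; fractional
  coordinates are allowed (zoomed clicks). The probe calibration
  transform absorbs any vendor-specific plane convention.

### Orientation averaging

The user may sample the tool orientation several times;
`slrm_initialize()` averages the samples by default (or keeps the last
one, `sample_mode = "last"`). `mean_rotation()` uses the chordal
(sign-aligned, normalized component-wise) quaternion mean. This is
accurate for tightly clustered samples — the only regime repeated
acquisitions produce — and is *not* suitable for widely spread rotations,
a documented limitation (the eigenvector method would be needed there).

## Pivot calibration

A pointed tool's tip offset $p_{tip}$ (tool frame) and the fixed pivot
point $p_{pivot}$ (reference frame) satisfy $R_i p_{tip} + t_i =
p_{pivot}$ for every pose $i$ acquired while pivoting the tool about its
stationary tip. `pivot_calibrate()` stacks these into a $3n \times 6$
linear least-squares system $[R_i\;{-I}]\,(p_{tip}, p_{pivot})^\top =
-t_i$, solved by QR. The formulation is exact in the noiseless case and
returns both unknowns plus the RMS residual. Pose sets whose rotations are
(nearly) identical make the system rank-deficient and are rejected
(smallest singular value $\le 10^{-8}$). No sample-validity filtering is
applied — vendor tools filter "valid samples" by undisclosed criteria that
cannot be reproduced.

## The tracked-ultrasound chain

`click_to_reference()` composes three maps:
pixel $\to$ image-plane mm (spacings), image plane $\to$ probe sensor
(the probe spatial calibration — an *input* to this package, estimated by
external wire-phantom procedures), probe sensor $\to$ reference frame
(the tracked probe pose at click time). The simulator provides the pose
synchronously with the click; real systems may interpolate between
tracking frames, which is out of scope here. Only linear-array geometry is
supported (no scan conversion).

## The virtual phantom and the displacement experiment

The simulator stands in for a soft-tissue abdominal ultrasound phantom in
a rigid, fiducial-carrying case. Anatomy is reduced to labelled points —
sufficient for every quantity the evaluation computes, and deliberately
not an image simulator:

* a reference landmark (the anatomical point where the round and
  falciform ligaments meet is the clinically convenient choice),
* a lesion exactly 60 mm away,
* five case fiducials, four near the top face and one on the bottom
  (non-coplanar by construction, with a small seeded jitter),
* a `ground_truth` image-to-reference transform encoding the current
  placement on the table (identity for a fresh phantom).

`run_experiment()` executes the protocol: for each method × axis
({frontal, longitudinal} = reference x, y; the table grid's axes are
otherwise unlabeled) × displacement ({10, 50, 100} mm) × repetition
(10), the phantom is displaced, registered (SLRM: orientation + reference
landmark, then a translation-only re-registration at a fresh sample of the
same landmark; FLRM: refit of all five fiducials), and the lesion is
localized via a simulated click on the tracked US image whose plane passes
through it (the probe is modeled as rigidly attached to the case, so its
pose follows the ground truth plus tracking noise). The TRE of the trial
is the distance between the registered image-frame lesion and the
US-localized lesion. The default grid yields 60 TRE samples per method.

### Noise model

Measurements are perturbed by zero-mean Gaussians:

| parameter | default | unit | applied to |
|---|---|---|---|
| `sigma_tool_pos` | 0.3 | mm/axis | pointer-sampled points, probe origin |
| `sigma_tool_angle` | 1 | degree | pointer and probe orientations |
| `sigma_click` | 0.5 | mm/in-plane axis | the US click |

The position default is on the order of the sub-millimetre calibration
errors optical set-ups report (pointer ≈ 0.4 mm, probe ≈ 0.2 mm); the
orientation and click defaults are plausible round figures for hand-held
sampling. They are choices, fully configurable, and fixed once: the
simulator does not claim to reproduce any particular physical phantom's
absolute TRE values (which fold in operator skill, marker visibility and
anatomy), only the method's structural properties — zero-noise exactness,
displacement invariance, the chord law, and the growth of SLRM error with
distance from the registered point.

Additionally a *deterministic* pointer-orientation bias
(`angle_bias_deg`, about `angle_bias_axis`) can be injected. This exists
to study fixed orientation errors analytically: a bias $\theta$ about an
axis perpendicular to the landmark→lesion direction (the automatic choice
when no axis is given) must reproduce the chord law exactly, and does. The
stochastic `sigma_tool_angle` averages over random axes and cannot express
that experiment.

### Randomness

One master seed drives everything. Each trial derives its own substream
seed from (master seed, trial index), so trial results are independent of
execution order and any subset of the grid reproduces exactly. All derived
seeds stay below $2^{31}$.

## Evaluation

`summarize_groups()` reports, per (method, axis, displacement) group:
n, mean, sample standard deviation ($n-1$), min, max, and *repeatability*
defined as the standard deviation of the mean, $sd/\sqrt n$ — computed
from unrounded sds (tables whose sd column is rounded to one decimal will
not exactly regenerate a repeatability column rounded to two; no attempt
is made to match such rounding). `format_tre_table()` applies the
conventional table precision: one decimal for mean/sd/min/max, two for
repeatability.

`one_way_anova()` is the classical equal-variance between/within
decomposition ($F = MSB/MSW$, df $(k-1, N-k)$) and `welch_test()` the
unequal-variance two-sample test with Welch–Satterthwaite fractional df;
both delegate to the standard implementations in `stats` and return a
uniform result container, and both are verified against hand-formula
oracles in the tests. Levene's test, Tukey/Scheffé post-hoc comparisons
and pooled t-tests are intentionally not implemented — they add no novelty
and are one `car::leveneTest()` or `TukeyHSD()` call away for users who
need them.

The displacement-invariance check compares the six SLRM group means using
the pooled within-group standard error ($\sqrt{MSW \cdot 2/n}$): the
design is balanced and the variances homogeneous, so pooling is the
correct estimator and is far more stable than per-group SEs at $n = 10$.

## Numerical choices

* Rotation validity: $\lVert R^\top R - I\rVert_\infty$ tolerance
  $10^{-9}$; drift beyond $10^{-12}$ is repaired by SVD projection onto
  the nearest rotation; matrices beyond $10^{-6}$, or with $\det < 0$,
  are rejected as invalid rather than silently repaired.
* FLRM degeneracy: image-side fiducials are declared collinear when the
  ratio of the second-smallest to largest singular value of the centered
  point matrix is $\le 10^{-6}$ — far below any physical fiducial spread,
  so only genuinely degenerate configurations are rejected.
* The reflection-correction branch of the SVD fit is exercised by a
  frozen test fixture (near-coplanar points under heavy noise).
* Pivot rank check: absolute smallest singular value $> 10^{-8}$ on the
  stacked system.
* Ties/degenerate statistics: zero within-group variance raises an error
  (`F` undefined) rather than returning `NaN`.

### Problem sizes

The test suite and the reproduction script use: the full 120-trial
protocol (and a 2-repetition grid where every trial is provably
identical, as in the chord-law checks); 100 random 5-fiducial instances
(noiseless and at 0.5 mm noise) for the oracle comparison; 600 poses at
0.1 mm noise for pivot calibration; $2\times10^4$–$10^4$ draws for the
noise-calibration laws; 1000 resamples for the Welch null calibration.
These sizes give comfortable statistical resolution for every asserted
property while keeping a full run fast on a single CPU.

## Known limitations

* Rigid transforms only: respiratory motion, pneumoperitoneum and liver
  mobilization deform the anatomy by amounts no rigid method models;
  re-registration at the lesion mitigates this only locally. Deformable
  and vessel-based registration are out of scope.
* The chordal rotation mean degrades for widely spread orientation
  samples.
* The simulator does not model B-mode image content, human reaction
  times, marker-occlusion dropouts, or vendor sample-validity filtering.
* Accuracy claims from the simulator are structural, not absolute: the
  noise magnitudes behind any physical phantom study are not identifiable
  from published summary tables.
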