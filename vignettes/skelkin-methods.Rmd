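---
title: "Methods: the skeletal-model layer, its losses, and the direct-vs-multi-step harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the skeletal-model layer, its losses, and the direct-vs-multi-step harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

skelkin works with a tree-structured skeletal model: rigid body segments
connected by joints with up to three ordered rotational degrees of freedom,
and markers rigidly attached to segments at fixed body-frame offsets. All
internal units are metres and radians; millimetres and degrees appear only
at file boundaries (TRC/MOT) and in reports, which is how results in this
field are conventionally printed.

A subject is described by per-body, per-axis scale factors
$\hat\beta$ relative to the default model (all ones). Scaling acts on every
translation and marker offset elementwise,

$$\hat T = T \odot (\hat\beta \oslash \beta), \qquad
  \hat d = \vec d \odot (\hat\beta \oslash \beta),$$

with the parent body's ratio applied to the parent-side joint offset and the
child body's ratio to the child-side offset. The model format itself does
not force this pairing; we chose it because each offset is expressed in the
frame of, and grows with, its own body (the knee moves away from the hip
when the femur lengthens). It is covered by the parameter-recovery tests, so
the convention is enforced, not merely documented.

A joint's motion rotation composes its ordered axis-angle factors with each
later axis pre-rotated by the accumulated earlier rotations,

$$R_1 = G(A_1,\theta_1),\quad R_2 = G(R_1 A_2,\theta_2),\quad
  R_3 = G(R_2 R_1 A_3,\theta_3),\quad R_{motion} = R_3 R_2 R_1,$$

where $G$ is the Rodrigues axis-angle map. The parent-from-child transform
of a joint is the three-factor product

$$R_{parent\leftarrow child} =
  R_{parent\leftarrow joint}\; R_{motion}\; R_{child\leftarrow joint}^{-1},$$

with the constant joint-frame factors built from Euler orientations (fixed
convention: intrinsic, body-fixed X-then-Y-then-Z; the upstream modelling
tradition does not pin one down, so it is documented here and identical
everywhere, including the independent test oracles) and the scaled
translations above. Forward kinematics traverses the tree from the pelvis
root breadth-first, so each parent's world transform exists before its
children are visited; a batched sequence evaluator returns identical
results frame by frame.

The ground-from-pelvis rotation is special: its three coordinates are
unbounded, and a regression onto three unbounded angles is discontinuous in
the parameters, so the direct path predicts an unconstrained 3x3 matrix and
projects it onto SO(3) by the SVD polar factor. The root transform carries
no translation; all positions are root-relative. "Joint position" means the
world origin of a joint's child body, a definition the model format makes
unambiguous.

Angles outside a coordinate's declared range raise a recorded warning
rather than an error: the pelvis coordinates are legitimately unbounded, and
an optimiser may transiently step outside a range.

## Differentiability

Every operation above is a composition of smooth primitives. The package
ships analytic Jacobians of all marker coordinates with respect to both the
angles and the scale factors, implemented in compiled code alongside the
forward pass. The angle derivative of each motion rotation uses the exact
product rule through the pre-rotated axes (the derivative of $G$ with
respect to its axis direction is taken term by term); scale derivatives are
linear. The test suite checks both Jacobians against central finite
differences at random configurations, which is the contract any
reimplementation must meet.

## Losses

Training of the direct path is supervised by

$$L = \lambda_1 L_{joint} + \lambda_2 L_{marker} + \lambda_3 L_{body}
      + \lambda_4 L_{angle},$$

with root-relative L1 position terms (both point sets have their root
position subtracted first, cancelling any global translation) and plain L1
terms on scales and angles. The default weights are
$\lambda = (1.0,\, 2.0,\, 0.1,\, 0.06)$. The marker and joint terms are the
point of the skeletal-model layer: they propagate the cumulative effect of
small proximal angle errors on distal positions back into the angle
estimates.

## Metrics

* **MPBLPE** (mm): mean Euclidean distance over bony landmarks after
  aligning prediction and truth at the root, pooled over frames and
  landmarks (for balanced data the frame-then-landmark and pooled means
  coincide, so the pooled mean is used).
* **Angle errors** (deg): MAE, the SD of signed errors, and RMSE, per
  coordinate and pooled, over valid entries only. SD uses the population
  convention (divide by $n$); the convention is stated because the two
  choices differ at small $n$.
* **Body-scale errors**: RMSE over all scale entries (unitless), plus a
  millimetre MAE obtained by converting the scale error along each body's
  longest default dimension through its reference length.
* **Mean velocity** (deg/s): mean absolute first difference over the
  sampling interval with $n = \#frames - 1$ pairs. The naive reading of the
  defining sum would index one past the final frame; with $n$ pairs the
  statistic is exact (equal to $|slope|$) for affine signals, which the
  tests assert.
* **Correlation categories**: $|\rho| \le 0.35$ weak, $\le 0.67$ moderate,
  $\le 0.90$ strong, above that excellent; boundaries inclusive on the
  lower category.
* **Distribution summaries**: median and IQR (type-7 linear-interpolation
  quantiles, the R default, stated because quantile rules differ) plus mean
  and sample SD.

## Scaling and inverse kinematics

The multi-step baseline first scales the model from marker-pair distances
observed during a neutral calibration hold: for each configured pair mapped
to a body axis, the scale is the mean observed distance over calibration
frames divided by the default-model distance at the neutral pose.
Unconfigured axes inherit the body's mean configured scale; bodies with no
pair keep scale one. The bundled fixture places one marker at each body
origin and one at the end of each axis extent, so every axis is observable
from a same-body pair and noise-free recovery is exact.

Per-frame inverse kinematics minimises the weighted sum of squared
marker distances by damped Gauss-Newton (Levenberg-Marquardt) steps using
the analytic Jacobian, with: a free root translation absorbing the global
offset; missing markers excluded; joint ranges enforced by projection after
each step (the pelvis unbounded); at most 100 iterations and a step
tolerance of 1e-8. A stalled search with a near-zero gradient counts as
converged (a local minimum); otherwise the best iterate is returned and
flagged. Each frame is initialised from the previous frame's solution, the
first from the neutral pose.

The rejection rule reads "segments fitting worse than 2 cm" as a
per-segment marker RMS *distance* above 20 mm (centimetres are a length),
and flags the coordinates of every joint adjacent to such a segment as
invalid for that frame. The flag count is monotone as the threshold
tightens, which the acceptance tests exercise. The rule serves ground-truth
generation; the comparison harness reports the flags but scores all frames,
because under the 30-50 mm systematic bias the rule would otherwise reject
everything and leave no frames to compare.

Low-pass smoothing is a zero-phase fourth-order Butterworth filter applied
forward and backward, with odd-reflection end padding and mean removal so
that constants pass through exactly.

## The synthetic generator

The generator stands in for motion-capture recordings:

* **Motions**: each coordinate follows a bank of sinusoids (default two
  harmonics, frequencies 0.1-0.8 Hz, total amplitude 40% of the
  coordinate's half-range) around its range midpoint, after a 1 s
  neutral-pose calibration hold and a half-second smooth ramp. A coordinate
  with zero amplitude holds the neutral pose. Sampling is 30 Hz, well above
  twice the highest excitation frequency.
* **Corruption** emulates the error structure of image-based keypoint
  estimators: a constant per-marker systematic bias with direction uniform
  on the sphere and norm uniform in 30-50 mm (the magnitude reported for
  pose-estimation keypoints against optical capture), i.i.d. Gaussian
  jitter of 5 mm per axis, and contiguous occlusion windows (default
  expected rate 2%, 10-frame gaps).
* **Subjects**: per-body, per-axis scale factors drawn uniformly from
  0.9-1.1 per sequence.

All randomness flows from explicit integer seeds; identical specs produce
bit-identical artifacts.

What the generator does **not** emulate: soft-tissue artefact, correlated
(heteroscedastic, view-dependent) keypoint noise, marker swaps, real human
motor variability, or any image formation. Passing tests therefore show
that the algorithms are correct and that the direct-vs-multi-step ordering
holds under this error model -- not that any particular accuracy level
transfers to real video data.

## The comparison harness

Both estimation paths consume byte-identical corrupted test observations.

The **multi-step path** is scale-from-markers on the calibration window,
optional 6 Hz marker smoothing, then sequence IK -- the classical pipeline,
which can only react to its corrupted input.

The **direct path** is a deliberately small stand-in for a learned
regressor: per-frame observed marker clouds (gap-filled, centred,
standardised; an odd window of frames is configurable, default one) are
expanded in radial-basis features anchored at landmark frames sampled from
the training set (default 1200, bandwidth half the median pairwise squared
distance), and a linear head maps features to all non-root angles, all
scale factors, and the nine root-rotation entries. The head is warm-started
by a ridge fit (penalty 0.01) to the kinematic labels and then refined by
subgradient Adam (default 150 steps, batch 48, rate 1e-5) on the composite
loss, in which the joint- and marker-position terms are evaluated through
the forward-kinematics layer with its analytic Jacobians; the SO(3)
projection uses a straight-through gradient. Because training labels are
the generator's true kinematics while inputs carry the bias distribution,
the regressor learns to compensate systematic error that the multi-step
path must swallow -- the mechanism the comparison is designed to isolate.
Deep image backbones and sequence networks are out of scope; the window
parameter and output smoothing are their desk-scale analogues. The full
kinematic labels (including the root rotation) enter the warm start, and
the refinement then couples them through the pose terms; a separate
rotation-matrix loss term is deliberately absent, matching the four-term
loss above.

Default problem sizes are 24 training and 6 test sequences of 8 s at 30 Hz
(one synthetic subject each). These sizes were fixed once, as a desk-scale
design point where the multi-step baseline is well-conditioned (240 IK
frames per sequence) and the regressor has ~5800 training frames; the
qualitative comparison is stable across seeds at this size. The clean-data
sanity check uses 60 single-subject sequences and 2000 basis functions,
where the regressor reaches sub-degree MAE.

Reported metrics are computed on the motion window (after calibration and
ramp) over the non-root coordinates, since the direct path represents the
root as a matrix rather than angles.

## Numerical choices and degenerate inputs

* Rotation validity tolerances: 1e-8 on orthonormality and determinant;
  axis unit-norm tolerance 1e-9 (axes are never silently normalised).
* Empty inputs pass through: zero-frame trajectories yield zero-frame
  results without error.
* A frame with fewer than two fully observed markers cannot be posed; the
  IK marks all its coordinates invalid and moves on.
* Predicted scale factors are clamped to [0.2, 3] before entering forward
  kinematics during training, so early optimiser steps cannot produce
  degenerate geometry.
* TRC files may be in mm or m; anything else is an error, not a guess.
  MOT files are degrees on disk, radians in memory; the root rotation
  travels in nine auxiliary row-major columns because the format has no
  matrix convention.

## Known limitations

* The fixture's markers sit exactly on body axes; real marker sets are
  irregular, and axis observability would then depend on the pair
  configuration.
* The spine is lumped into three segments by default (nine are supported);
  per-vertebra motion is not modelled.
* The direct regressor is a shallow approximator: it demonstrates the
  training-through-the-layer mechanism and the error-compensation effect,
  but its absolute accuracy is not representative of a deep network.
* IK is a local optimiser; with extreme corruption it can settle in a wrong
  basin. Warm starts along the sequence mitigate, and the rejection rule
  flags, but neither eliminates this.
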