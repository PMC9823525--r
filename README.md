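# skelkin

Marker-based 3D human kinematics at desk scale: a scaling-aware,
differentiable forward-kinematics layer over a tree-structured skeletal
model, the losses and metrics used to score joint-angle estimators,
marker-distance model scaling plus damped least-squares inverse kinematics
with a residual rejection rule, TRC/MOT file handling, a synthetic
motion/marker generator, and a harness that contrasts **direct kinematic
regression** (trained through the forward-kinematics layer) with the
classical **multi-step** scale-then-inverse-kinematics pipeline.

## Who this is for

Researchers in biomechanics and markerless motion capture who want the
modelling stage of a kinematics pipeline — the part between observed point
clouds and reported joint angles — as small, tested, scriptable components,
plus a self-contained testbed for the question *does estimating kinematics
directly beat estimating pose first and fitting afterwards?* when the
observations carry the systematic errors typical of image-based keypoint
detectors (30–50 mm bias, millimetre jitter, occlusion gaps).

## The core computation

A skeletal model has bodies, joints (≤ 3 ordered rotational DOFs, axes
`A_i`), and markers at body-frame offsets `d`. A subject is a set of
per-body, per-axis scale factors `β̂` relative to the default model:

```
T̂ = T ⊙ (β̂ ⊘ β),   d̂ = d ⊙ (β̂ ⊘ β)
R1 = G(A1, θ1),  R2 = G(R1 A2, θ2),  R3 = G(R2 R1 A3, θ3)
R_parent←child = R_parent←joint · R_motion · R_child←joint⁻¹
```

Forward kinematics composes these transforms breadth-first from the pelvis
root (root-relative, with the unbounded root rotation handled as a matrix,
projected onto SO(3) when it comes from a regressor). Analytic Jacobians
with respect to angles *and* scales ship with the forward pass; they drive
both the Levenberg–Marquardt inverse kinematics and subgradient training of
the direct regressor under the composite loss

```
L = λ1·L_joint + λ2·L_marker + λ3·L_body + λ4·L_angle,
λ = (1.0, 2.0, 0.1, 0.06)
```

where the position terms are root-relative L1. Evaluation metrics include
MPBLPE (mean per-bony-landmark position error, mm), MAE/SD/RMSE of angles
(deg), body-scale RMSE and mm-converted MAE, mean velocity (deg/s), and
Pearson correlations with the weak/moderate/strong/excellent categories at
0.35 / 0.67 / 0.90.

## Worked example

```r
library(skelkin)

model <- make_default_model()          # 17 bodies, 39 coordinates, 68 markers
motion <- simulate_motion(model, trajectory_spec(duration = 8, seed = 1))
fk <- fk_sequence(model, angles = motion$angles, roots = motion$root_rotation)

# corrupt the clean markers the way a keypoint detector would
clean <- marker_trajectory(dimnames(fk$marker_positions)[[2]],
                           motion$timestamps,
                           aperm(fk$marker_positions, c(3, 2, 1)))
observed <- corrupt_markers(clean, noise_spec(seed = 2))

# classical pipeline: scale from the calibration hold, then IK
ms <- run_multistep(observed, model, experiment_config())
angle_errors(ms$motion$angles, motion$angles)$mae    # degrees

# full comparison on freshly generated train/test data
report <- compare_pipelines(experiment_config(seed = 11))
print(report)
```

The comparison prints (this exact run):

```
Direct vs multi-step comparison (synthetic)
  direct:      MAE_angle   4.77 deg  SD   6.36  MPBLPE   31.0 mm   MAE_body  13.2 mm
  multi-step:  MAE_angle  10.07 deg  SD  12.80  MPBLPE   47.9 mm   MAE_body  29.3 mm
  relative MAE_angle change: +52.6% (positive = direct better)
```

Read: under identical corrupted observations the direct regressor — whose
training labels are clean kinematics, so it can *learn to compensate* the
systematic marker bias — roughly halves the joint-angle MAE of the
multi-step pipeline, which must treat the biased markers as truth. The
absolute numbers are properties of the synthetic error model; the ordering
is the point.

A command-line front end wrapping these functions (model validation, FK,
scaling, IK, simulation, comparison) is in `inst/cli/skelkin.R`.

## Layout

| Path | Contents |
| --- | --- |
| `R/model.R`, `R/model_io.R` | model schema, validation, YAML/TRC/MOT I/O |
| `R/kinematics.R`, `src/fk.cpp` | FK, batched FK, analytic Jacobians |
| `R/losses.R`, `R/metrics.R` | composite loss, evaluation metrics |
| `R/scaling_ik.R` | marker-pair scaling, LM inverse kinematics, smoothing |
| `R/synthetic.R` | humanoid fixture, motion simulator, marker corruption |
| `R/experiment.R` | direct regressor, multi-step baseline, comparison |
| `vignettes/skelkin-methods.Rmd` | the full methods description |
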