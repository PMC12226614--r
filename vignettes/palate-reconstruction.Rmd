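---
title: "Reconstructing cleft palate surfaces from single images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cleft palate surfaces from single images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cleftrecon` reconstructs the 3D surface of a cleft palate from a single
photograph by (1) predicting dense 2D landmarks - one per sub-sampled
template vertex - with a convolutional regressor that also reports its
uncertainty, and (2) fitting a PCA statistical shape model to those
landmarks by alternating pose and shape optimization. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions behind each stage.

## The camera and pose model

Points on the palate, in millimetres, are mapped into the image by a
pinhole camera with intrinsic matrix `K` (focal lengths `fx, fy`,
principal point `cx, cy`) after a similarity transform: a single global
scale `s`, a rotation `R` and a translation `T`. We treat `s` as a
global pre-transform applied to world points before `[R|T]` and perform
the per-point homogeneous division by camera depth separately, because
the fitting stage optimizes scale as one pose parameter alongside the
rotation angles and the translation vector.

Because a smartphone capture has no calibration, `K` is approximated:
principal point at the image center and `fx = fy = (width/2)/tan(fov/2)`
with a default horizontal field of view of 53 degrees, typical of a
smartphone main camera (`approximate_intrinsics()`). With an
approximate, fixed `K`, the global scale and the object depth are nearly
confounded: enlarging the object and moving it away changes the image
only through perspective foreshortening. We accept this documented
ambiguity; the reliable outputs of pose estimation are reprojections,
not raw pose parameters, and all tests of pose recovery are phrased as
reprojection contracts.

Image coordinates are 0-based with the origin at the top-left pixel
center, `u` rightward and `v` downward; the convention matters whenever
landmarks and pixels are exchanged (rendering, augmentation, resizing).

Pose estimation from at least four 2D-3D correspondences
(`estimate_pose()`) is damped nonlinear least squares
(Levenberg-Marquardt via `minpack.lm`) over a minimal parameterization:
an axis-angle rotation vector (no gimbal lock near the identity), the
translation, and the log of the scale (positivity for free). A soft
barrier keeps all points at positive depth during the search. When no
warm start is given, LM is run from a small set of canonical initial
rotations (identity, half-turns and quarter-turns about the image axes)
and the best solution is kept: a palate photographed via a dental
mirror is seen roughly "upside down", and a single identity-rotation
start frequently converges to a mirror-ambiguous local minimum.

## The statistical shape model

All meshes live on one fixed template grid (default 100 x 100 = 10,000
vertices), so vertex `i` is the same anatomical location on every mesh.
`shape_model()` first applies generalized Procrustes alignment -
iterative Kabsch superimposition onto the evolving mean, rigid-only by
default - then computes the principal components of the stacked
3V-dimensional vertex vectors by thin SVD (per-mode variance
`singular_value^2 / (n - 1)`). Whether the original work normalized
scale during alignment is unstated; we expose `scale_align` and default
to rigid-only, since palate size is itself clinically meaningful
variation that the model should capture. The number of retained modes
is the smallest count whose cumulative variance fraction reaches the
threshold, default 99.9%. Multiple meshes of one patient (different
ages) are treated as independent samples.

`simulate()` draws mode weights as independent zero-mean Gaussians with
the model variances; this is the "in-distribution" sampler used by the
experiments, and it inherits the usual PCA assumption that the shape
population is well described by a multivariate Gaussian in the mode
basis.

## Flip-flop fitting

`fit_flipflop()` minimizes the weighted squared reprojection error of
the model's landmark-subset vertices, optionally plus a Tikhonov prior
`lambda * sum(w_i^2 / variance_i)`, by alternating:

* **pose step** - LM over rotation, translation and scale against the
  currently reconstructed shape;
* **shape step** - damped Gauss-Newton over the eigenmode weights,
  solved *jointly with the scale*: at fixed rotation and translation
  the camera-frame landmark `s*R*(mean + B w) + T` is linear in
  `(alpha, nu) = (s, s*w)`, so each inner iteration solves one
  weighted least-squares system in `(alpha, nu)` with the full
  projective quotient-rule Jacobian, through a truncated-SVD
  pseudo-inverse because the scale/depth ambiguity can make the normal
  matrix numerically rank-deficient.

Re-solving the scale inside the shape step is a deliberate overlap of
the two blocks: the leading PCA mode of a palate family is largely a
size mode, and a strict weights-only step zigzags against the pose
step's scale for thousands of iterations. Every sub-step is safeguarded
by a step-halving line search on the true (non-linearized) cost, so the
joint cost is non-increasing by construction - a property the test
suite asserts on every fit.

Termination: the fit stops when both sub-steps' relative parameter
updates fall below their tolerances (default `1e-6`) in the same outer
iteration, when the joint cost stalls (relative improvement below
`1e-10` over two consecutive iterations - remaining parameter motion is
then reparameterization along the scale/depth-flat direction), or at
`max_outer_iters` (default 200). Because the alternation can settle in
a genuine joint stationary point with a non-trivial residual, up to
`n_restarts` (default 2) retries are made from seeded 3-degree
rotation perturbations of the best pose when the residual RMSE exceeds
`restart_rmse` (default `1e-3` px); the lowest-cost solution wins.
Residual local minima persist for a small fraction of geometries - the
recovery-rate test tolerates up to 5% of seeded trials failing the
0.1 px reprojection contract.

The optional prior (default `lambda = 1e-3`) guards against
out-of-distribution extrapolation when landmarks are noisy; the
unregularized path (`lambda = 0`) is available. Weighting by predicted
landmark variance (`use_sigma_weighting`) is off by default: the
regressor predicts confidences, but nothing requires them to enter the
fit, so the default keeps the two stages decoupled.

## The synthetic palate generator

The generator stands in for textured intraoral scans of real patients.
It emulates, on a fixed grid, the features the fitting pipeline
actually depends on: a smooth dome (neonatal maxilla, defaults 34 x 38
x 11 mm), two alveolar ridge bulges (height 2-4 mm) whose crests define
the plate-contact region, a unilateral cleft modelled as a lateral
separation of the anterior segments (0-12 mm) with a groove at a
signed lateral offset, a smooth seeded per-identity perturbation
(RMS 0.4 mm), and a mottled mucosa-like per-vertex color. Identity
families are drawn from declared uniform ranges
(`sample_palate_params()`).

What it does **not** emulate: real scan noise and holes, specular wet
tissue, non-rigid template registration error, lips/tongue occluders,
and real texture statistics. Consequences: tests passing on synthetic
families show the *method* is correct and precise under its own
assumptions (exact correspondence, Lambertian appearance); they do not
quantify the domain gap to real photographs, which the dataset-size
experiment addresses only qualitatively at toy scale.

Rendering is a z-buffered software rasterizer with flat per-face
Lambertian shading (`|cos|` of normal versus light), textured-noise
background, and optional linear motion blur - deterministic given its
seed, which is what makes every landmark file exactly reproducible.
Landmarks are the exact projections of the landmark-subset vertices;
occluded landmarks are kept (the training target is the vertex
position, visible or not) and flagged by a z-buffer visibility bit, so
training may mask them (`mask_occluded`), though the default keeps
them. Camera randomization: +/-20 degrees per axis around the
canonical mirror view, +/-15% distance, defaults declared here rather
than inferred from any source.

## Landmark sub-sampling

`subsample_landmarks()` reduces the 10,000 template vertices to 1,000
landmarks by seeded weighted farthest-point sampling, with
contact-region vertices carrying a 4x selection density - the ridges
matter most for the plate, so they are sampled more densely. FPS keeps
the subset well spread at any weight; with weight 1 it reduces to plain
farthest-point sampling.

## The uncertainty-aware landmark regressor

No deep-learning framework is assumed: the regressor is implemented in
the package as a small strided-convolution encoder (3x3 kernels,
stride 2, ReLU; default channels 16-32-64 on 64 px inputs) with a
fully connected head producing, per landmark, a 2D mean in coordinates
normalized to `[-1, 1]` and one shared variance through a softplus map
(per-landmark rather than per-coordinate - the isotropic choice halves
the variance head and is the simpler model absent evidence for
anisotropy). Training minimizes the mean Gaussian negative
log-likelihood per coordinate,

```
L = 1/2 [ log max(sigma^2, eps) + (y - mu)^2 / max(sigma^2, eps) ]
```

with `eps` the machine epsilon, exactly as the loss is defined; the
floor keeps a collapsed variance finite, and for a fixed error the loss
is minimized at `sigma^2 = (y - mu)^2`, which is what makes the
predicted variance interpretable as a calibrated squared error.
Optimization is Adam (default `lr = 1e-3`, batch 16) with seeded
shuffling and augmentation (rotation +/-10 degrees by default during
training, color shift, pixel noise; flips off unless a left/right
symmetry map is supplied, since flipping permutes anatomical left and
right). "Train until convergence" is operationalized as early stopping
on validation NLL with patience 10. Gradients are exact (the test
suite checks them against finite differences); convolution is im2col
matrix multiplication, adequate at the package's CPU toy scale
(64 px, 50-1,000 landmarks).

## Dense video annotation

For real videos, sparse manual 2D-3D correspondences on one frame are
propagated to every frame by a pluggable tracker; the baseline is
frame-to-frame normalized cross-correlation of 21 x 21 grayscale
patches with search radius 20 px, correlation threshold 0.6 and
quadratic sub-pixel refinement. A landmark that cannot be matched is
flagged lost, never fabricated. Published long-term pixel trackers can
be plugged in through the same call contract; the baseline is adequate
for slow, well-textured motion and will drift on feature-poor tissue.

Each frame with at least four surviving tracks gets a pose
(`estimate_pose()`, warm-started from the previous frame) and a dense
annotation by projecting **all** template vertices. Frames are then
quality-filtered on three criteria: the number of projected points
inside the image (default at least 90%), the sparse reprojection RMSE
(default at most 3 px), and the pose jump, measured as the Frobenius
norm of the difference between the frame's 3x4 projection matrix and
that of the last *accepted* frame, normalized by the focal length
(default at most 0.1). Comparing against the last accepted frame makes
a single teleported pose reject only itself. The thresholds are
declared defaults; survivor counts are monotone in each of them.
Non-rigid template-to-scan registration is out of scope: the pipeline
consumes a pre-registered template, and synthetic data is in
correspondence by construction.

## Scaling experiments and extrapolation

`model_size_experiment()` builds models on growing seeded subsets of a
mesh family (99.9% truncation at every size) and evaluates mean
reconstruction error on held-out meshes - 20% of the family, 5 seeded
replicates, median reported. Whether the original protocol evaluated on
held-out or training meshes is unstated; held-out is the default and a
flag restores the training-mesh variant. `dataset_size_experiment()`
is the learning-curve analogue for the landmark regressor: one
training run per identity count (default 1, 2, 4, 8 at 48 px with 12
renders per identity, 3 seeds), evaluated on renders of held-out
identities, with an optional surface-error curve obtained by fitting
the shape model to the predicted landmarks (after rigid alignment,
since predicted-landmark fits are defined up to the pose ambiguity).

`fit_exponential()` fits `y = a exp(-b n) + c` with `a, b > 0` by
multi-start LM (`minpack.lm::nlsLM`, decay-rate starts spanning 0.2-30
per data span); the asymptote `c` is the convergence point - the error
expected with unlimited data. A flat curve returns its constant as `c`
directly; a decay rate pinned at its bound flags model misfit. With
`a > 0` the asymptote bounds the fitted curve from below.

## Numerical choices and degenerate inputs

* Rotations are stored orthonormalized; inputs off by more than `1e-4`
  from orthonormality, or with determinant -1, are rejected rather than
  silently repaired.
* The log-scale pose parameter is clamped to `[-30, 30]` so
  finite-difference probes cannot overflow.
* Pose steps whose internal barrier-augmented objective disagrees with
  the true cost are rejected, preserving monotonicity.
* Zero-variance modes simulate to exactly zero weights; a two-mesh
  model retains exactly one mode with 100% variance; `variance
  threshold = 1` retains the full centered rank `n - 1`.
* Ties in nearest-vertex landmark transfer go to the lower vertex
  index; duplicate assignments move to the next-nearest free vertex.

## Problem sizes

The package targets CPU desk scale throughout, and the documented
experiments use these sizes: 50-identity families on the full
10,000-vertex template for concept verification (10 seeded fits);
20 x 20 to 24 x 24 grids for unit-scale work; the ceiling experiment
trains on 100 renders of one identity at 64 px with 50 landmarks; the
dataset-size curves use 1-8 identities, 12 renders each at 48 px,
3 seeds. Full-resolution training and real clinical data are outside
the package's scope; the real-data error levels reported in the
literature depend on unavailable patient scans and are not reproduced
here.

## Known limitations

* The flip-flop alternation can terminate in a joint stationary point
  with a residual of a few hundredths of a pixel for a small fraction
  of geometries; restarts mitigate but do not eliminate this.
* The scale/depth ambiguity means recovered pose scale is not
  individually meaningful; compare reconstructions after alignment.
* The NCC tracker drifts on feature-poor regions and is not a
  substitute for a learned long-term tracker on real footage.
* The renderer is not photorealistic; domain-gap conclusions from
  synthetic data are qualitative.
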