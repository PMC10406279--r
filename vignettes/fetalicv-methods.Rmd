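---
title: "Atlas-based fetal ICV measurement: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based fetal ICV measurement: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Fetal intracranial volume (ICV) — brain tissue plus cerebrospinal fluid
beneath the cranium — is usually traced manually on 3D ultrasound, which is
slow and rater-dependent. `fetalicv` implements an automatic alternative:
an average brain model (atlas) carrying a reference ICV mask is registered
to each subject scan through a staged sequence of intensity-based
registrations; the subject's ICV mask is obtained by propagating the model
mask through the inverse of the final transformation; and the ICV is

$$\mathrm{ICV} = N_{\mathrm{mask}} \times v_{\mathrm{voxel}},$$

the voxel count of the propagated mask times the volume of one subject
voxel, reported in cm³. Every measurement is made twice, by two
independently parameterized pipeline variants, and accepted only when the
two agree (consensus quality control).

# Preprocessing

Ultrasound exports pad everything outside the sweep field of view with
zeros, and acoustic shadows behind the skull are near-zero as well. Because
intensity-based registration is attracted to sharp edges, every voxel that
is exactly zero is replaced by the average grayscale before registration.
The average is taken over the *nonzero* voxels: the zeros being replaced
are padding, and including them in the mean would drag the fill value
toward black and partially recreate the boundary the step is meant to
remove. The replacement is idempotent.

Fetal scans occur in two mirror-image head orientations ("Left"/"Right").
Orientation is assigned manually per scan in the run configuration —
automatic detection is out of scope — and `canonicalize_orientation()`
mirrors the first (left-right) voxel axis about the grid center. Models are
built per size class *and* per orientation, and the pipeline refuses
cross-orientation pairing rather than silently mirroring.

# Registration engine

Each stage (`register()`) optimizes one transform family — translation,
rigid, similarity (rigid + global scaling), full affine, or cubic B-spline
free-form deformation — under either

* `ssd`: mean squared intensity difference, or
* `ncc`: Pearson correlation of intensities (negated for minimization),

over a *smoothing-only* image pyramid: each level blurs both images with a
Gaussian (sigmas in voxels, e.g. `c(4, 2, 1, 0)`) but never down-samples,
so the grid is identical at every level.

The optimizer is a decaying-gain gradient descent of the package's own
design:

* gain schedule $a_k = a_0\,\big(\frac{A+1}{A+k+1}\big)^{0.602}$ with
  $A = 50$;
* `standard_gd`: $a_0$ is set so the first step moves `sp_a` mm;
  `adaptive_gd`: $a_0$ is auto-calibrated from the initial gradient so the
  first step moves about one voxel (half a voxel for B-spline stages);
* a decaying trust-region clamp limits every update's max component to the
  first-step length times the gain, which prevents the oscillation that
  raw gradient steps produce on speckled images;
* on persistent non-improvement the gain is backtracked (times 0.7 every
  second failed iteration), so stages that start near their optimum can
  still refine below the nominal step size;
* the B-spline family adds heavy-ball momentum (0.9): its objective is
  high-dimensional and locally quadratic, and momentum speeds the slow
  distributed modes (a uniform dilation, say) by an order of magnitude;
* linear-family gradients are central finite differences on *scaled*
  parameters (rotations, log-scale and matrix entries are multiplied by the
  image half-extent so every parameter moves points by about 1 mm per
  unit); B-spline gradients use the analytic chain rule through the cubic
  basis, accumulated in compiled code.

The metric and gradient are evaluated on a seeded random voxel subsample
drawn once per pyramid level (`max_samples`, default 8192; reduced-size
runs use 6000). A fixed per-level sample keeps finite differences
consistent and the whole run bit-reproducible given the seed. A level that
completes its iteration budget without any improvement flags the result
`converged = FALSE`; the best-so-far transform is always returned, so the
final metric is never worse than at the initial transform.

# The two pipelines and the transform chain

Both pipeline variants walk a fixed stage plan, re-registering the
(running) warped subject to a stage target and prepending each stage's
transform to a chain that maps model-grid points to subject space. After
every stage the subject is re-resampled *from the original data* through
the whole chain — one interpolation regardless of chain length. The first
stage's target is the model template itself (the model acts as both target
and one of the averaged images); from the second stage on, the target is
rebuilt as the voxelwise mean of the template and the current warped
subject. No intensity normalization is applied before averaging (a config
toggle exists).

* `minc_style`: four "affine" stages (full 12-parameter affine
  optimization, which subsumes translation and rotation) followed by three
  B-spline stages; SSD metric, standard-gain descent; an optional pre-blur
  on the affine stages is the first fallback preset.
* `elastix_style`: a translation stage, a rigid stage, then four B-spline
  stages; NCC on the linear stages, adaptive-gain descent. When the rigid
  stage's result fails the overlap-similarity check (floor 0.7) the stage
  is escalated to the similarity family — the global-scaling escape hatch
  for subjects whose head size differs substantially from the model.

The deliberate differences in metric, optimizer and stage plan are what
gives the consensus check its power: failures should not be perfectly
correlated between variants.

ICV measurement inverts the chain: linear members in closed form, B-spline
members numerically as a dense displacement field via damped fixed-point
iteration ($v \leftarrow v - \tfrac12\,(v + d(y+v))$, cap 100 iterations,
round-trip residual checked against a tolerance of 5% of the field
spacing; non-convergence is an error that reports the worst residual). The
model mask is then resampled onto the *subject* grid — linear
interpolation thresholded at 0.5, which gives smoother propagated
boundaries than nearest-neighbour — and counted. Counting on the subject
grid makes "voxel count times voxel volume" unambiguous; the model-grid
alternative would use a different voxel size.

# Groupwise model construction

`build_model()` builds the average template: every scan is first registered
(affine) to a designated seed scan and averaged; three more affine rounds
register every scan to the previous average; four B-spline rounds then
sharpen the template, and the output is the arithmetic mean after the
fourth round. The reference ICV mask is attached by label fusion
(`attach_icv_mask()`): each cohort mask is propagated onto the model grid
through its scan's chain, the propagated masks are majority-voted at 0.5,
and the fused mask is smoothed with a 3×3×3 median filter applied three
times — the same smoothing the method prescribes for model masks.

# Consensus quality control

For each subject both variants run independently; the final ICV is their
mean. The QC consists of:

* **SD gate** — the two-value *sample* SD, $|a-b|/\sqrt2$, compared with
  either a fixed threshold in cm³ (the study used 10 cm³ at 20 weeks and
  20 cm³ at 30 weeks) or a fraction of the mean ICV (default 0.10; the
  recommended band is 7.5–12%). The sample convention is the conservative
  (larger) of the two possible two-value SDs; thresholds are configurable
  so the population convention can be emulated.
* **Similarity floor** — the overlap similarity
  $\sum ab / (\sum a^2 \sum b^2)^{1/2}$ between the registered subject and
  the last-stage average of the elastix-style variant must be at least
  0.7. The floor is inclusive: exactly 0.7 passes.

On failure the offending variant (the elastix-style one when its
similarity is under the floor, otherwise both) is re-run with fallback
presets, at most twice: preset 1 enables pre-blur (minc-style) or switches
to standard-gain descent with doubled step (elastix-style); preset 2
forces the similarity stage (elastix-style). A subject still failing is
*excluded* — recorded in the ledger with its reason, never silently
dropped.

# The phantom generator

`make_head_phantom()` renders a seeded synthetic fetal head with exact
ground truth: a bright cranial shell around textured tissue, a midline
falx-like band, up to three asymmetric inclusions (two dark ventricle-like
cavities and a bright choroid-like body), multiplicative log-normal
speckle (sigma 0.25), a zeroed acoustic-shadow wedge, and zero padding
outside a conical sweep. The cranial surface is not a pure ellipsoid: a
fronto-occipital egg taper (12%) plus two unequal petalia-like bulges (15%
right-frontal, 8% left-occipital) make the shape chiral, as real fetal
heads are — without them a mirrored phantom registers back onto the model
almost perfectly and orientation handling would be untestable. The shadow
wedge defaults to 90°, reflecting that transabdominal imaging shadows much
of the hemisphere closer to the probe. The ground-truth mask is the set of
voxel centers inside the inner surface, so true ICV is exact by
construction and any measurement error is attributable to registration.

Two presets set the size class: `"20w"` (semi-axes 26×33×28 mm, 2 mm
voxels on a 48³ grid) and `"30w"` (38×48×41 mm, 3 mm voxels) — labels
bracketing the two gestational-age groups, not claims of anatomical
fidelity. `make_cohort()` draws per-subject isotropic scale (default
range entered per experiment), a small rigid pose jitter (±2 mm, ±4°),
and independent speckle, all from one master seed.

What the phantoms do *not* emulate: sulcation and gyration, the cerebellum
and skull base, rater-dependent probe positioning, attenuation gradients,
and refraction artifacts. Passing phantom tests therefore demonstrates the
correctness of the registration/propagation machinery and the QC logic
under controlled conditions, not clinical accuracy on real scans.

# Validation experiments and problem sizes

The test suite validates the method end-to-end at desk scale (all sizes
chosen as the package's own phantom-study design):

* *Registration recovery*: known translations (±4 voxels), a 5° rotation
  and global scales 0.9–1.1 recovered on 48³ phantoms within 0.5 voxel,
  0.5° and 3%.
* *End-to-end recovery*: a model built from 8 phantoms (20-week class,
  48³), four held-out phantoms with true ICVs spanning roughly ±10% of the
  model; both variants recover ICV within 5% of ground truth, the
  consensus SD stays under the 10% gate and the final similarity exceeds
  0.7. Reduced iteration counts (`profile = "fast"`: pyramid `c(2, 0)`,
  40 iterations, 6000-voxel subsample) are used throughout.
* *Failure injection*: a subject generated in the opposite orientation but
  mislabeled (canonicalization skipped) at the 30-week size class — where
  the study's exclusions occurred — drives the two variants apart and is
  excluded by the SD gate after both retry presets; the matched control
  passes. At the 20-week size the mirrored phantom is measured within
  ~10% by both variants coherently, a known blind spot of any consensus
  gate: it detects decoupled failures, not correlated ones.
* *Model-choice robustness*: two models built from disjoint 6-phantom
  subsets give per-subject ICVs within 5% of each other on a 10-phantom
  cohort, and a two-sample t-test between the two sets is nonsignificant —
  mirroring the study's "Left"/"Right" two-model check.

# Numerical choices and degenerate inputs

* Voxel (i, j, k) (0-based) sits at `origin + spacing * (i, j, k)` in mm;
  all transforms act on world coordinates; resampling is pull-back
  (output voxel x takes the input value at T(x)).
* Out-of-domain samples take the input's nonzero-mean background (masks:
  0); NCC on a constant image is an error, as is similarity of an all-zero
  volume and zero-replacement of an all-zero scan.
* B-spline control grids cover the fixed image with one control point of
  margin per side; the default finest control spacing is 8 voxels.
* Mask warping interpolates linearly and thresholds at 0.5 (ties count as
  foreground); rigid transforms change large ball-mask volumes by < 2%
  (discretization bound).
* The 30-week preset uses 3 mm voxels so the bulged outer surface keeps a
  2-voxel margin on a 48³ grid.
* All randomness (phantoms, subsampling) derives from explicit integer
  seeds through a deterministic 31-bit tag hash; identical inputs and seeds
  give bit-identical results.

# Known limitations

* The two pipeline variants share one registration engine; their failure
  modes are therefore more correlated than two genuinely independent
  packages would be, and the SD gate inherits that blind spot for
  correlated errors.
* The overlap-similarity score of a subject against an average *containing
  that subject* is bounded well above zero by construction; the 0.7 floor
  only catches gross failures, which matches its role as a last-resort
  check.
* Absolute cohort statistics (growth curves, sexual dimorphism,
  intraclass correlations against manual raters) require real scans and
  are out of scope; phantom parameter recovery substitutes for them.
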