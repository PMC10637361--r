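---
title: "Methods: tractography-based target planning for tcMRgFUS thalamotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tractography-based target planning for tcMRgFUS thalamotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfusplan)
```

## The planning problem

Transcranial MR-guided focused ultrasound (tcMRgFUS) thalamotomy for
essential tremor ablates the ventral intermediate nucleus (VIM) of the
thalamus. The VIM is invisible on routine MRI, so planning rests on two
surrogates: a geometric *standard coordinate* derived from the anterior and
posterior commissures (AC, PC), and diffusion-tensor tractography of the
tremor-relevant bundles — the cerebellothalamic (CTT) and pallidothalamic
(PTT) tracts as targets, and the corticospinal tract (CST) and medial
lemniscus (ML) as no-go structures whose injury causes motor and sensory
deficits. `tfusplan` implements that planning chain as composable stages
plus a `plan()` orchestrator, and ships a synthetic phantom generator so
the whole chain is testable without patient data.

## Coordinate conventions

All world coordinates are millimetres. The package frame has +x toward the
patient's *left*, +y anterior, +z superior; voxel indices are 0-based and
voxel centres map through the NIfTI affine. Under this convention the
lateral offset of the standard target is +14 mm for a left-side treatment
and −14 mm for a right-side one, which makes the targeting rule signed and
directly testable.

## AC-PC alignment and the standard coordinate

`acpc_transform()` computes the minimal rotation taking the PC→AC
direction onto +y (so AC and PC share an axial plane and a parasagittal
line) and maps the PC to the origin. Minimal rotation implies zero roll
about the AC-PC axis; when a roll reference volume is available the
residual roll is estimated by rigid registration against it and composed
in, but the default is roll = 0 because the landmark pair alone cannot
constrain it. Landmark *detection* is out of scope — landmarks arrive as
JSON, reflecting that the geometric computation downstream, not the
detector, is the reusable part.

The standard coordinate is then

* anterior to the PC by 25 % of the straight-line AC-PC distance,
* 1 mm superior to the AC-PC plane,
* 14 mm lateral toward the treated side.

```{r}
lm <- landmark_pair(ac = c(0, 24, 0), pc = c(0, 0, 0))
standard_coordinate(lm, side = "left")
```

The 25 % rule uses the chord, not an arc length; sites differ in their
exact variant of this rule, and only this one is implemented — alternates
would be configuration extensions with their own validation.

## Rigid registration with normalized gradient fields

T1-weighted anatomy and diffusion data differ in contrast, so alignment
uses the normalized gradient fields (NGF) distance: per voxel
$1 - \langle \nabla f, \nabla m\rangle^2 / ((\|\nabla f\|^2+\varepsilon^2)
(\|\nabla m\|^2+\varepsilon^2))$, averaged over the evaluation domain. The
edge parameter $\varepsilon$ (default 1 % of the fixed image's 98th
percentile gradient magnitude) decides what counts as an edge rather than
noise; the measure is invariant to affine intensity rescaling.

Four numerical choices matter, all adopted after observing that a naive
implementation has its optimum visibly displaced from the true transform
on analytic phantoms:

1. **Gradients** are fourth-order central differences; second-order
   differences bias gradient *directions*, to which NGF is maximally
   sensitive.
2. **The moving gradient field is interpolated** at the transformed points
   and rotated into the fixed frame (chain rule), rather than
   differentiating a resampled image; at the finest level the sampling is
   tricubic (Catmull-Rom), which removes most of the sub-voxel
   interpolation ripple.
3. **The averaging domain is fixed**: at the finest level only interior
   fixed-grid voxels with non-negligible gradient (default: above 5 % of
   the maximum magnitude) that map well inside the moving grid under the
   warm start are averaged, and samples that leave the moving grid score
   the maximal dissimilarity 1. With a transform-*dependent* overlap, the
   optimizer profits from shuffling uninformative flat voxels in and out
   of view — an effect we measured at several times the true alignment
   signal.
4. **Optimization** is coarse-to-fine (factor-2 Gaussian-antialiased
   pyramid). The coarsest level runs Nelder–Mead from eight deterministic
   Halton-spaced starts spanning ±10° / ±5 mm (a single descent in six
   rigid parameters is unreliable at that range), keeps the best three
   candidates, and each finer level refines all candidates with
   quasi-Newton (BFGS) steps, selecting the final winner by the finest
   objective. Everything is deterministic for fixed inputs.

On smooth band-limited phantoms this recovers random transforms up to
±10° / ±5 mm with worst-case errors around 0.02° and 0.02 mm (the test
suite asserts 0.5° / 0.2 mm over 20 cases). The *deformable* atlas
registration of a full clinical pipeline is out of scope; the atlas label
volume is accepted already in DWI space.

## DWI preprocessing and the tensor fit

The DWI volume is supersampled to an isotropic grid (default 1 mm) with a
separable Lanczos-3 kernel, $L(x)=\operatorname{sinc}(x)
\operatorname{sinc}(x/3)$ for $|x|<3$, weights renormalized to unit sum
per output sample so constant images are reproduced exactly.
Supersampling adds no information; it exists so that plain trilinear
interpolation suffices later during tracking. A Gaussian smooth (default
$\sigma$ = 1 mm, in world units) follows; the pipeline order
supersample → smooth → fit is a configuration choice, and smoothing width
trades noise suppression against partial-volume blurring at bundle edges.

Tensors solve the Stejskal–Tanner model per voxel by log-linear least
squares, $\log(S_k/S_0) = -b_k\, g_k^\top D\, g_k$, with $S_0$ the mean of
the $b=0$ frames. Weighted or iterative schemes would down-weight
low-signal directions but the plain log-linear solution is the direct
inversion of the stated model and is exact on noise-free signals (the
suite checks recovery to 1e-8 relative). Voxels with non-positive signals
are masked out; negative eigenvalues are clamped to zero for derived
metrics (FA, colour maps) while the raw tensor is kept. Motion, eddy and
susceptibility correction are assumed already applied upstream.

## ROI model and adaptive tracking parameters

Each bundle is declared as a seed region, include (waypoint) regions every
accepted streamline must traverse, and exclude regions it must avoid.
`default_bundle_specs()` encodes the four planning bundles with resolved
laterality: the CTT decussates, so its cerebellar includes (dentate
nucleus, superior cerebellar peduncle) lie contralateral to its precentral
seed while red nucleus and thalamus are ipsilateral. The precentral gyrus
seeds both CTT and CST: a large cortical seed makes the non-bijective
tracker fill the bundle, which is why the CTT's iteration cap is 2500
(finding streamlines that thread both the small red nucleus and the
thalamus is rare) while all other bundles cap at 500. Every bundle
requires at least 100 accepted fibers.

Tracking parameters (step 1 mm, FA stop 0.15, bend limit 45°, accepted
length 20–200 mm) are defaults of a per-atlas-label override map: at every
tracking position the covering label is read by nearest-voxel lookup
(labels are never interpolated) and any override for that label replaces
the defaults field-by-field. Published per-region values are not part of
this implementation; the adaptive *mechanism* is, and the map is plain
YAML/JSON configuration. Include-ROI order is not enforced — membership
only — since traversal, not sequence, is the declared semantics.

## Streamline tracking and probability maps

Tracking is deterministic principal-eigenvector integration: trilinear
interpolation of the six tensor components, eigen-decomposition *after*
interpolation, fixed-step Euler steps with the local step size, sign
continuity by dot product with the previous direction, and termination on
low FA, sharp bends, leaving the grid, or the length cap. Fixed-step
Euler keeps the step-length invariant exact (every consecutive point pair
is one local step apart); a midpoint scheme would halve the curvature
error but break that invariant, and at supersampled resolution with step
≤ one voxel the Euler error is already small: on a quarter circle of
radius 20 mm the in-span tracked length is within 5 % of $10\pi$ mm. The
*total* track length additionally includes roughly one voxel of overshoot
past each tube end, where trilinear tensor interpolation keeps FA above
the stop threshold in the tube/background mixing zone — a property of any
FA-terminated tracker on a finite bundle, which is why the curvature
check measures the in-span length.

`track_bundle()` seeds batches (default 100) uniformly over seed-ROI
voxels with uniform sub-voxel jitter, keeps streamlines passing every
include and no exclude, and repeats until ≥ `min_fibers` are accepted or
`max_iterations` batches have run — reproducibly for a fixed seed.
Probability maps count *distinct* streamlines per voxel, divide by the
accepted count, and rescale to max 1; global normalization and the
rescale differ from per-seed-voxel normalization only by that constant.
Thresholds on the scaled maps are 0.2 (CTT/PTT/CST) and 0.5 (ML) for this
pipeline's maps and 0.1 for FSL-style probabilistic maps, all inclusive;
they are heuristic diameter-matching constants, exposed as configuration.

## The phantom generator

`make_phantom()` builds the full input set of a planning run: a tube of
prolate tensors (eigenvalues 1.7/0.3/0.3 × 10⁻³ mm²/s, the textbook white
matter values; FA ≈ 0.80) along a straight or quarter-arc centreline in an
isotropic background (ADC 0.7 × 10⁻³ mm²/s), forward-simulated DWI signals
at b = 1200 s/mm² on 56 Fibonacci-lattice directions plus one b = 0 frame,
S0 = 1000, spherical seed/include/exclude ROIs on and off the corridor, a
two-label atlas splitting the corridor so parameter adaptation is
exercised, axis-aligned AC/PC landmarks 24 mm apart, a T1-like anatomy, a
spherical lesion near the corridor midpoint, and a five-point treatment
log around the standard coordinate with temperatures straddling the 55 °C
therapeutic criterion. Noise is Gaussian at SNR 20 by default — analytic
tractability over Rician realism; noise-free variants are used where a
test needs exact inversion.

What the phantom does *not* emulate: crossing fibers, susceptibility
distortion, Rician bias at low SNR, anatomical geometry, or partial-volume
mixtures beyond the tube boundary. Green tests on phantoms therefore
validate the geometry and the algorithmic contracts, not clinical
accuracy; the clinical numbers of a 40-patient cohort are explicitly out
of reach at desk scale.

## Evaluation statistics

For a patient $j$ with $K$ therapeutic sonication points $p(i,j)$ (those
reaching ≥ 55 °C, inclusive) and standard coordinate $\mathrm{stdCoord}(j)$:

$$\mathrm{dev}(j) = \frac{1}{K}\sum_{i=1}^{K} \lVert p(i,j) -
\mathrm{stdCoord}(j)\rVert, \qquad
\mathrm{xdev}(j) = \frac{1}{K}\sum_{i=1}^{K} \bigl|\,|p_x(i,j)| - 14\,\bigr|$$

with conditional cohort means $\frac{1}{M}\sum_{j\,:\,\mathrm{cond}}(\cdot)$
over the $M$ of $N$ patients satisfying a predicate. The lateral statistic
uses $|p_x|$ so one formula serves both treated sides; whether a signed
convention was intended for single-side cohorts is ambiguous, and the
magnitude reading is the implemented choice. The 14 is the standard
coordinate's defined lateral offset, exposed as a bound constant rather
than a parameter. Bundle-to-point distances are border distances: zero
inside a suprathreshold voxel, else the minimum distance to suprathreshold
voxel centres (a centreline variant is deliberately not guessed into
scope). Dice is the usual $2|A\cap B|/(|A|+|B|)$.

## The `plan()` pipeline

`plan()` chains: landmark load → AC-PC transform and reorientation →
standard coordinate → optional rigid T1→DWI registration → DTI
preparation → per-bundle tracking → probability-map scaling, thresholding
and AC-PC reorientation (derived maps receive the same transform as the
planning image) → evaluation when a treatment log or lesion is present.
All randomness funnels through one seed; reruns are byte-identical, which
the suite asserts by hashing every output. Stage failures carry a stage
tag and abort the run.

## Problem sizes and defaults used by the test suite

The suite runs phantoms at 64³ × 1 mm (tracking, pipeline) and 32³ × 2 mm
(registration), 56 + 1 gradient frames, 100-seed batches, and 20
registration recovery cases; these sizes make every property cheap to
check while leaving the contracts (fiber minimums, iteration caps,
tolerances) at their stated values. The unreachable-include contract uses
a 2-seed batch so that exhausting 2500 iterations stays quick.

## Known limitations

Single-tensor model only (no crossing fibers); deterministic tracking only
(the probabilistic comparison arm of clinical practice is out of scope);
rigid registration only (no deformable atlas propagation); no DICOM
ingestion; landmark and ROI segmentation models are inputs, not products.
The NGF fixed-domain objective assumes the warm start is within a few
voxels of the optimum at the finest level — guaranteed by the multilevel
cascade, but a caller invoking `ngf_distance()` directly gets the plain
overlap average, whose optimum is less sharply placed.
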