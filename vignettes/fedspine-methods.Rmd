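---
title: "Methods: simulating cross-silo federated learning for lumbopelvic landmark localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating cross-silo federated learning for lumbopelvic landmark localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Automatic measurement of the lumbopelvic parameters — sacral slope (SS),
pelvic tilt (PT), pelvic incidence (PI) and lumbar lordosis (LL) — from
lateral spine radiographs is usually posed as anatomical landmark
localization: a network predicts a fixed set of keypoints (vertebral
endplate corners, the sacral upper endplate, the femoral head centers) and
the angles are derived from them geometrically. Training such a model well
requires pooling images from several hospitals, which privacy regulation
makes difficult. Federated learning (FL) sidesteps pooling: each hospital
trains locally and shares only model parameters, which a server aggregates.

`fedspine` implements the full simulation needed to study this trade-off:
a synthetic multi-hospital cohort generator with exact ground truth, the
landmark localizer, three federated strategies (FedAvg, FedOpt, FedProx),
centralized and per-hospital local baselines, and a cross-site evaluation
suite. Real radiographs from the motivating setting cannot be
redistributed, so the synthetic generator is the data source that makes
every downstream stage testable.

## Geometry conventions

All coordinates are continuous, 0-based image pixels with the y axis
pointing down; the patient's facing direction (`anterior_is_plus_x` or
`anterior_is_minus_x`) is recorded explicitly. The 29-landmark schema is
6 vertebrae (T12–L5) × 4 endplate corners, plus the sacral endplate
anterior/posterior/midpoint and the two femoral head centers — the minimal
set from which all four angles are computable.

The angle definitions are the standard clinical (Duval-Beaupère) ones:

* **SS** — unsigned acute angle between the sacral upper endplate and the
  horizontal.
* **PT** — signed angle at the bicoxofemoral point H (midpoint of the
  femoral head centers) between the vertical and the segment to the sacral
  endplate midpoint M; positive when M is posterior to H.
* **PI** — signed angle between the caudal perpendicular to the sacral
  endplate at M and the segment M→H.
* **LL** — signed angle between the superior endplate of L1 (T12
  selectable) and the sacral endplate, positive for lordosis.

With these sign conventions PI = PT + SS is an algebraic identity, provided
the sacral endplate is oriented anatomically: its cranial normal faces
antero-superiorly, i.e. the plate descends toward its anterior margin. The
generator constructs landmarks in exactly this orientation, so the identity
(and every other angle) closes to machine precision — the test suite
verifies closure below 1e-6 degrees over a thousand random constructions.
Degenerate geometry (coincident endplate points, H = M) raises an error
rather than returning NaN, because a silent NaN entering a federated
average would poison every client's next round.

## The synthetic cohort generator

Each hospital is a `center_profile`: a patient share, an angle model, and
an image-appearance model. Angles are drawn as
PI ~ N(pi_mean, pi_sd), PT = PI·f with f ~ N(pt_fraction_mean,
pt_fraction_sd), SS = PI − PT, and LL = ll_slope·PI + ll_intercept + noise,
truncated to clinically valid ranges. This mirrors how the parameters
covary in practice (PI is the anatomical constant; PT and SS partition it;
LL tracks PI). The default four centers have shares 0.45/0.35/0.14/0.06 and
mean PI of 56/52/50/44 degrees, the smallest center emulating a younger,
more heterogeneous cohort with the most distinct image appearance. The
spread in mean PI (12 degrees) makes the non-IID structure real rather than
cosmetic; a test asserts it exceeds 8 degrees.

Landmarks realizing a sampled angle set are built analytically: sacral
endplate (≈35 mm) at slope SS, H at pelvic-thickness distance along the
direction making PT with the vertical, femoral heads symmetric about H, and
vertebral corner quadrilaterals whose endplate inclinations interpolate
linearly from the sacral plate to the L1 superior endplate (which subtends
exactly LL), with per-vertebra heights/widths/disc spaces jittered per
patient. Landmarks are stored in continuous coordinates, never quantized,
so closure is exact. Each patient contributes 3–4 follow-up images whose
angles are perturbed by at most 2 degrees — the follow-up structure is what
makes patient-level splitting meaningful.

The default canvas is 256×256 at 1.5 mm/px: the T12-to-femoral-heads
anatomy spans roughly 300 mm, so the field of view must be ≈380 mm; the
desk-scale studies use 48–64 px images at the same physical field
(spacing scales accordingly). Rendering draws endplate quadrilaterals and
femoral-head circles as anti-aliased strokes over Gaussian background
noise, then applies the center's intensity shift, contrast scale and noise
level; optional bright bars emulate instrumentation occlusion without
moving landmarks. The renderer is deliberately schematic: it reproduces the
*statistical* structure the analysis needs (center-distinct appearance,
geometry-locked ground truth), not radiographic realism — conclusions about
absolute millimetre accuracy on real radiographs do not transfer, while
conclusions about the *relative* behaviour of training arms under
heterogeneity are exactly what it is built to support.

The patient-level split shuffles each center's patients by seed and
apportions 80/10/10 by largest-remainder rounding; all images of a patient
follow the patient. Largest-remainder rounding (ties broken by category
order) is used for both center shares and split fractions — reproducibility
over elegance.

## The localizer

The model is a stacked-hourglass convolutional network: a stem of 3×3
convolutions and 2×2 max pools down to the heatmap resolution
(stride 4 by default, configurable as any power of two), then `n_stacks`
symmetric encoder–decoder modules with additive skip connections, each
emitting one heatmap logit per landmark through a 1×1 head; between stacks,
1×1 remap convolutions feed features and heatmaps back into the trunk
(intermediate supervision). Heatmaps are normalized by a spatial softmax
and decoded by the DSNT head: coordinates are the expectation of the
heatmap over fixed grids with values (2k − (n+1))/n, k = 1…n, making
outputs resolution-independent in (−1, 1).

The training loss is the mean Euclidean distance between predicted and
ground-truth normalized coordinates plus a divergence between the predicted
heatmaps and Gaussian target heatmaps (σ = 1 heatmap pixel) centered at the
ground truth. The divergence is Jensen–Shannon by default — the
regularizer recommended for DSNT training, symmetric and bounded —
with KL selectable by configuration. The whole backward pass is
hand-derived (no autodiff framework is involved) and is verified in the
test suite against central finite differences to a relative error below
1e-4 on a sub-1000-parameter model, and the hot loops (im2col/GEMM
convolution, pooling, upsampling) are compiled via Rcpp/RcppArmadillo.

Clients and the centralized/local pipelines optimize with Adam
(β = 0.9/0.999, ε = 1e-8), the standard choice for this architecture
family; initialization is He-normal, seed-controlled. Heatmap resolution
follows the hourglass convention of stride 4; whether full- or
quarter-resolution heatmaps are used in comparable systems varies, so the
stride is configurable.

Augmentation applies histogram-equalization-style contrast enhancement,
coarse dropout, brightness/contrast jitter, blur, Gaussian noise, and
random rotations within ±10 degrees; rotations transform the landmarks
with the same matrix about the image center, photometric steps never touch
them, and every draw is seed-deterministic. Aspect-preserving resize scales
the long side with bicubic (Catmull–Rom) interpolation, pads the short side
symmetrically with the median border intensity, and records the affine
transform so predictions map back to the original pixel frame — all angle
errors are computed in that original frame to avoid resampling bias.

## Training protocols

The full-scale schedules are the package defaults:

| arm         | local epochs × rounds | total | LR                      | decay                  |
|-------------|----------------------|-------|-------------------------|------------------------|
| centralized | — (200 epochs)       | 200   | 1e-4                    | ×0.1 after 50 epochs   |
| local       | — (200 epochs)       | 200   | 1e-4                    | ×0.1 after 50 epochs   |
| FedAvg      | 10 × 30              | 300   | 1e-4 (client)           | ×0.1 after 15 rounds   |
| FedOpt      | 3 × 100              | 300   | 1e-3 client, 1e-4 server| —                      |
| FedProx     | 10 × 100             | 1000  | 1e-4 client, 1e-5 server| —                      |

Batch size is 8 everywhere; early stopping triggers after 10 consecutive
validation epochs without improvement ("improvement" is strictly-less-than
with tolerance 1e-6); checkpoint selection returns the parameters of the
best validation epoch, not the last. The validation checkpoint metric is
the mean landmark error in mm (the quantity the study ultimately cares
about); validation loss is selectable. Epoch and round indices are 0-based,
so "decay after 50 epochs" means epochs 0–49 run at the base rate.

Two design points deserve a note:

* **FedOpt's server optimizer.** Only "adaptive learning rates and momentum
  decays" is specified in this family of setups; the package implements the
  FedAdam-style update (β = 0.9/0.999, τ = 1e-9) on the pseudo-gradient
  g = global − weighted-average(clients), plus a plain-average mode used to
  prove exact reduction to FedAvg at server LR 1.
* **FedProx's "server learning rate".** Standard FedProx aggregates by
  plain weighted average; the 1e-5 "server LR" in the motivating protocol
  most plausibly acts as a damping factor on the aggregated step. The
  package defaults to plain averaging and exposes `server_damping` for the
  damped interpretation. The proximal coefficient μ is not published for
  this setting; the default is 0.01.

Client updates are reduced in sorted client-id order so results are
machine-reproducible regardless of scheduling; every stochastic stage
derives its seed from one master seed, making whole simulations pure
functions of (data, config, seed). Clients are simulated in-process,
synchronously, all participating every round; the client interface returns
only parameters, sample counts and scalar metrics — a test walks the
returned structure to assert no sample object ever crosses the server
boundary.

## Evaluation

Per-image landmark error is the mean Euclidean distance over the 29 points
in mm; per-vertebra summaries average the four corners of each level.
Angle errors are absolute differences in degrees between angles computed
from predicted and ground-truth landmarks, aggregated per image first and
then averaged. The cross-site matrix evaluates every model on every
center's held-out test set; local models are *internal* on their own center
and *external* elsewhere. Percentage-of-correct-predictions (PCP) curves
report the fraction of predictions within 1–15 degree thresholds, with the
comparison inclusive at the threshold. Evaluation refuses to run when a
test patient appears in the supplied training-patient set.

A useful decoupling check: a global translation of all predicted landmarks
inflates the landmark error but leaves all four angle errors at zero, since
every angle is translation-invariant. The tests assert this explicitly.

## The desk-scale study

The end-to-end study (`run_desk_study()`) runs the three arms at sizes
chosen for a single CPU: 120 patients (≈420 images) over the default four
centers, 48×48 images over the same 384 mm field, a 1-stack 16-channel
model, centralized and local arms for up to 30 epochs with patience 10,
and FedAvg at 5 local epochs × 6 rounds, all at LR 1e-3 (the larger rate
compensates for the short schedules at this scale; the full-scale defaults
above remain unchanged). The robust qualitative outcome mirrors half of the
motivating findings exactly: local models generalize poorly across centers
and FedAvg beats them externally at every seed. The other half —
FedAvg matching centralized accuracy — compresses only partially at this
scale: with six aggregation rounds, clients holding a few dozen images
each, and a mean-PI spread of 12° between centers, weighted parameter
averaging pays a real cross-silo penalty, and the FedAvg-to-centralized
ratio sits above centralized rather than beside it. That the gap is the
federation and not the machinery is pinned down structurally: the test
suite shows a single-client federated round reproduces plain local
training bit-for-bit, so everything separating FedAvg from centralized
enters through client heterogeneity and averaging. Note also the epoch
budgets: at
full scale FedAvg receives 1.5× the centralized epoch budget (300 vs 200),
while the desk study gives both 30 — a deliberately conservative handicap
for FedAvg. The end-to-end test therefore runs three seeds and requires a
majority verdict on each half of the property separately.

## Known limitations

* The renderer is schematic; no claim is made about absolute accuracy on
  real radiographs.
* Per-center angle distributions are plausible defaults, not calibrated to
  any real cohort (those distributions are not public).
* The exact 29-point enumeration, the LL upper endplate (L1 vs T12), the
  FedOpt server optimizer family and FedProx μ are under-specified in the
  motivating setting; the package picks the standard option in each case
  and leaves the alternative configurable.
* Asynchronous participation, client dropout, secure aggregation and
  differential privacy are out of scope.
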