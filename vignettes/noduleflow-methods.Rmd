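---
title: "Methods: multiposition lung-nodule segmentation and spiculation recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiposition lung-nodule segmentation and spiculation recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleflow)
```

## The problem and the pipeline

Lung nodules occupy a tiny fraction of a thoracic CT volume, and their most
important malignancy cue — the spiculation sign, spike-like radial
protrusions of the boundary — is easy to miss when a reader (or a model)
inspects a single slice orientation. `noduleflow` mirrors the radiological
reading workflow as a three-stage pipeline:

1. **Parenchyma segmentation.** Nodules only occur inside the lung
   parenchyma, so the first stage narrows the search space: an
   attention-gated encoder–decoder produces a per-pixel parenchyma
   probability for each axial slice.
2. **Multiposition nodule segmentation.** The volume, masked to the
   parenchyma, is resliced into axial, coronal and sagittal stacks. A
   same-size U-Net with a bidirectional feature pyramid segments each stack;
   the three reassembled 3D masks are fused voxel-wise and connected
   components are screened by circularity and size.
3. **Spiculation-sign recognition.** Each retained candidate is described by
   radiomics and morphological features; univariate screening plus the LASSO
   select discriminative features for two logistic submodels whose
   probabilities are averaged.

Everything below documents the models, their tunable parameters and the
design decisions taken where the architecture left choices open.

## Stage 1: attention-gated parenchyma network

The network (`buildParenchymaNet()`) is an encoder–decoder. Each level
applies two 3×3 convolutions with rectifier activations; scale changes go
through *multiscale parallel sampling blocks* — two stride-2 convolutions
(kernels 3 and 5) summed for descent, two stride-2 transposed convolutions
(kernels 2 and 4) summed for ascent — so the scale change itself is learned
at more than one kernel scale.

**Attention gates.** Every skip connection is gated before concatenation.
For coding features $x$ and the upsampled gating signal $g$:

$$\alpha = \sigma_2\!\big(\varphi^T \sigma_1(W_x^T x + W_g^T g + b_g)\big),
\qquad \text{output} = \alpha \odot x,$$

with $\sigma_1$ the rectifier, $\sigma_2$ the logistic sigmoid, and
$W_x, W_g, \varphi$ 1×1 convolutions. Coefficients $\alpha$ are strictly
inside $(0,1)$, so the gate can only attenuate irrelevant background — the
mechanism that suppresses non-lung tissue near wall-adherent nodules. A
variant of this formula sometimes printed with an extra additive sigmoid
term is not implementable as typed (the term is dimensionally dangling);
the package implements the standard additive gate above, which matches the
two-input description of the module.

**Dense atrous convolution (DAC) bottleneck.** Four cascade branches of
dilated convolutions run in parallel at the coarsest scale and are summed
with the residual input. The branch compositions are fixed as

| branch | composition (kernel, dilation) | receptive field |
|---|---|---|
| 1 | (3,1) | 3 |
| 2 | (3,3), (1,1) | 7 |
| 3 | (3,1), (3,3), (1,1) | 9 |
| 4 | (3,1), (3,3), (3,5), (1,1) | 19 |

using the stride-1 identity $RF = 1 + \sum_i d_i (k_i - 1)$
(`receptiveField()`). This is the unique simple cascade design realizing
the stated fields 3/7/9/19 with dilations drawn from {1,3,5}. The block's
final fusion is a plain residual sum (rectifiers act inside the branches),
so a zero-weight block is exactly the identity — a property the tests use.

**Loss.** Training (`trainSegmenter()`) minimizes the soft Dice loss
$1 - 2\sum p_i g_i / (\sum p_i^2 + \sum g_i^2 + \epsilon)$ with
$\epsilon = 1$; the smoothing makes the loss defined when both maps are
empty and bounds the gradient on tiny structures. Optimization is Adam
(default learning rate $10^{-3}$, batch 8), the conventional choice where
the architecture itself does not prescribe one.

## Stage 2: multiposition nodule network

`buildNoduleNet()` is a five-level U-Net (depth 5 counts resolution levels,
the standard U-Net nomenclature) with three deliberate properties:

- **Same-size contract.** All convolutions use edge padding, and inputs
  whose sides are not divisible by $2^{levels-1}$ are internally
  edge-padded and cropped back, so the output probability map always has
  the input's spatial size (including 200×200, the default slice
  normalization target).
- **Mish activation**, $f(x) = x\tanh(\ln(1+e^x))$, evaluated through a
  numerically stable softplus. It is smooth, non-monotonic, admits a small
  negative information flow (global minimum ≈ −0.3088 near $x ≈ −1.19$) and
  avoids dead rectifier units.
- **Bidirectional feature pyramid.** The encoder's per-level features are
  projected by 1×1 convolutions to a common pyramid width; a top-down pass
  then a bottom-up pass fuse neighbouring scales, each fusion node using
  *fast normalized weights* $w_i = \mathrm{relu}(u_i) / (\sum_j
  \mathrm{relu}(u_j) + \varepsilon)$ with learned $u_i$ — nonnegative
  weights summing to one (up to $\varepsilon$), so fusion is a learned
  convex combination. The pyramid was described without equations in its
  source; top-down + bottom-up path augmentation with normalized fusion is
  the established realization of "two-way cross-scale connections that
  shorten the information path". The decoder then consumes the enhanced
  pyramid levels as skip connections.

**2.5D reasoning.** A sphere looks disc-like in *all three* positions;
a vessel looks disc-like in at most one and strip-like in the others.
Stage 2 exploits this twice:

- mask fusion (`fusePositionMasks()`) defaults to a **majority vote**
  (≥ 2 of 3). The OR rule that the recognition stage uses is deliberately
  *not* used here: segmentation needs the one-position-is-not-enough
  argument, and majority is its voxel-wise form. Union and intersection
  remain selectable.
- candidate screening (`screenCandidates()`) keeps a 26-connected component
  only if its max-area-slice circularity $4\pi A / P^2$ reaches the
  threshold (default 0.6) in at least two positions, and its equivalent
  sphere diameter lies in [4, 12] mm. The lower bound sits below the 6 mm
  study focus on purpose: partial-volume effects shrink a voxelized 6 mm
  sphere, and screening must not discard true nodules.

The perimeter in the circularity score is the polygonal arc length of the
Moore-traced outer contour (straight steps 1, diagonal steps $\sqrt 2$); a
naive boundary-pixel count biases discs above 1. Residual discretization
can still push a small disc marginally above 1, so scores are clamped to
[0, 1]. Probability maps are thresholded at 0.5 before fusion — the neutral
default, configurable — since no threshold is prescribed by the method.
Per-position networks share one architecture but separate weights.

## Stage 3: spiculation-sign recognition

`extractFeatures()` computes a fixed, documented vector of 22 features per
candidate:

- *first-order* (6): mean, variance, skewness, kurtosis, energy (mean
  squared HU) and entropy (25-HU-bin histogram) of the candidate's
  intensities;
- *2D shape* (4 × 3 positions): circularity, elongation (square root of
  the principal-axis variance ratio), perimeter-to-area, and the variance
  of the mean-normalized radial length of the contour, each on the
  max-area slice of that position;
- *3D shape* (4): sphericity $(36\pi V^2)^{1/3}/A$, surface-to-volume
  ratio, equivalent diameter, compactness $36\pi V^2/A^3$.

The surface area $A$ is estimated from exposed voxel faces scaled by 2/3:
for a smooth convex body the expected face-count area is exactly 3/2 the
true area, so the correction is unbiased for the near-spherical objects
being screened; it is a deliberate, documented estimator rather than a mesh
construction. Sphericity and compactness are clamped to 1.

`fitSignModel()` screens features univariately (Welch t-tests for
continuous features, chi-square for categorical ones, retain $p < 0.05$),
then fits two logistic submodels after LASSO selection (penalty chosen by
internal cross-validated deviance over a default 50-value path): a
*radiomics* model on first-order + 3D shape features and a *morphology*
model on the 2D shape features. Clinical covariates are outside the
synthetic scope, so the morphology model uses shape features only. The
combined score is the unweighted mean of the two probabilities with a 0.5
decision threshold — the simplest faithful integration of two model
outputs, with weights configurable downstream. Evaluation uses stratified
10-fold cross-validation ("10 times cross-validation" is read as 10-fold);
per-fold and pooled sensitivity/specificity are reported. If a submodel's
screening retains nothing the submodel degrades to an intercept; if both
are empty the fit refuses with advice to relax the significance level.

Per-position sign decisions, where computed separately, are fused with the
**OR rule** (`fuseSignDecisions()`): one positive position suffices, since
spiculation may be visible in only one reslicing.

One known property of this protocol: screening is performed once on the
supplied data (the procedure is screen-then-cross-validate, as in the
source protocol), so the permutation-null cross-validated performance sits
slightly above 50% — the classic radiomics selection-bias effect. The
acceptance experiment's null control therefore averages over label
shuffles and checks the 50% ± 15% band rather than exact chance.

## Evaluation metrics

For ground truth $E_g$ and segmentation $E_s$ (`segScores()`):
$\mathrm{Md} = |E_g \cap E_s| / |E_g \cup E_s|$ (Jaccard overlap, %),
$\mathrm{Vd} = |E_s \oplus E_g| / |E_s|$,
$\mathrm{Ud} = |E_g \oplus E_s| / |E_g|$, and
$\mathrm{CM} = (\mathrm{Md} + (100-\mathrm{Vd}) + (100-\mathrm{Ud}))/3$.
The CM average is stated over Md and the complements of both error
fractions; one printed symbol in its source formula is defined nowhere and
is read as Vd — the only reading for which perfect overlap scores
CM = 100. Vd and Ud can exceed 100 for gross mismatches (the XOR can be
larger than either mask); they are reported as computed. Recognition uses
SEN = TP/(TP+FN), SPE = TN/(TN+FP) and FPF = (FP+FN)/total — the label
"false-positive fraction" is kept for fidelity although the quantity is
algebraically the misclassification rate, i.e. 100 − accuracy (an identity
the tests assert). `rocCurve()` sweeps thresholds over distinct scores and
integrates by the trapezoid rule.

## The synthetic phantom generator

`generatePhantom()` renders, with exact ground truth: a soft-tissue body
(+40 HU) on an air background (−1000 HU); two darker lung-field ellipsoids
(−800 HU) whose centres and semi-axes are jittered by ±5% from the seeded
RNG, so anatomy varies across phantoms; spherical nodules (+20 HU, default
6–8 mm) that may be isolated, wall-adherent (centre on the lung-field
boundary) or vessel-attached; optional vessel-like cylinders; and additive
Gaussian noise (default SD 15 HU) rounded to integer HU. Spiculated ground
truth is made by `spiculateBoundary()`: thin cones (base radius ~1.5
voxels) of the requested length grown in seeded pseudorandom radial
directions — reproducible, always a superset of the input mask, and
measurably less circular in the max-area slice.

Default HU levels are round numbers in the plausible tissue ranges (air
≈ −1000, aerated lung ≈ −800, soft tissue ≈ +20…+40); 15 HU noise is a
typical low-dose-CT magnitude. The default full phantom is 96×128×128
voxels at 1 mm isotropic.

**What the phantom does not emulate** — and hence what passing tests do
not show about clinical data: airway trees and lobe fissures, HU texture
(tissue is uniform plus white noise), ground-glass and part-solid nodule
types, the "grid-like increased density" pattern, breathing/metal
artefacts, and anisotropic acquisition blur. Results on phantoms
demonstrate that the machinery is implemented correctly and can be trained
end-to-end, not that clinical-grade accuracy transfers.

## Desk-scale study conditions

All experiments in the test suite run on one CPU at deliberately small
problem sizes, chosen once as the package's desk-scale study conditions:

- *Parenchyma recovery*: 40 training slices (64×64) from seeded phantoms,
  attention U-Net with 3 levels and base width 4, 30 epochs of Adam at
  $10^{-3}$; evaluation on 10 slices from unseen phantoms.
- *Nodule pipeline*: 8 training phantoms and 10 evaluation phantoms of
  48×64×64 voxels, each with one isolated 6–8 mm nodule; per-position
  nodule nets with 3 levels, base width 4, pyramid width 8, 12 epochs at
  $2\times 10^{-3}$; evaluation uses the ground-truth parenchyma mask so
  the experiment isolates the nodule stage.
- *Sign recognition*: 60 nodules (30 spiculated / 30 smooth) in 32×48×48
  phantoms; features from ground-truth masks; stratified 10-fold CV.
  The permutation-null control averages over 12 label shuffles.

The full-size defaults (4/5 levels, base width 16, 200×200 slice
normalization) are the intended configuration for real data; nothing in
the implementation is specific to the reduced sizes.

## Numerical choices and degenerate inputs

- Convolutions are im2col + GEMM with hand-written adjoints; every layer's
  gradient is verified against central finite differences in the tests.
- Window/level display: `clamp((hu - (level - width/2))/width, 0, 1) * 255`
  rounded half-to-even, so `hu == level` maps to 128. Default window is the
  standard lung window (width 1500 HU, level −600 HU). Arithmetic is double
  precision; storage is signed 16-bit, matching CT's 16-bit container.
- Resampling: trilinear for intensities, nearest-neighbour for masks,
  half-pixel coordinate convention, output sizes `round(extent/target)`.
- Empty masks: Md/Ud are undefined for empty ground truth and Vd for empty
  segmentations — errors, not NaNs. Empty candidate lists are valid output.
- Contour tracing of a single-pixel region falls back to the equal-area
  disc perimeter.
- Seeds: every stochastic step (phantom geometry, noise, spike directions,
  shuffles, fold assignment, LASSO path CV) draws from an explicit seed,
  and seeded helpers restore the caller's RNG state.

## Known limitations

- Networks process one slice at a time (no batching across slices) and are
  CPU-oriented; wall-clock cost grows linearly with slice count.
- No DICOM series reader is bundled: volumes enter via NIfTI, and the
  DICOM rescale transform is exposed separately (`applyRescale()`).
- The screen-then-CV protocol carries optimistic selection bias (see
  above); for unbiased error estimates, screening would need to be nested
  inside each fold.
- Majority fusion requires agreement of at least two reslicings at voxel
  level; very small nodules (< 4 mm equivalent diameter) are outside the
  screening band by design.
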