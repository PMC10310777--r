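---
title: "Methods: unpaired CT contrast removal and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unpaired CT contrast removal and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Real-world chest CT collections mix contrast-enhanced and non-contrast
acquisitions. Iodinated contrast brightens blood pools by several hundred
Hounsfield units (HU), which shifts intensity distributions and radiomic
feature values, confounding models trained on pooled data. `decontrast`
implements a data-homogenization approach: learn, from *unpaired* cohorts,
a mapping that synthesizes non-contrast images from contrast-enhanced ones
— plus the evaluation machinery needed to decide whether such synthetic
images can stand in for acquired ones.

## Model

Two generators and two discriminators are trained adversarially on random
64^3-voxel patches (32^3 in the desk-scale presets). Writing $a$ for
contrast patches (domain A) and $b$ for non-contrast patches (domain B),
generator $G_{AB}$ maps A to B and $G_{BA}$ back; patch-GAN discriminators
$D_A, D_B$ score local realism on a grid (input side divided by $2^3$).

The generator is a 3D residual network: a reflection-padded 5^3
convolutional encoding block with instance normalization and ReLU, two
stride-2 down-convolutions (3^3), `n_residual` residual units, two
stride-2 transposed convolutions, and a final 3^3 projection with Tanh so
outputs stay strictly inside $(-1, 1)$. The discriminator stacks three
stride-2 4^3 convolutions (instance norm after the first, LeakyReLU 0.2),
a 3^3 convolution to one channel, and a sigmoid.

Kernel sizes deserve a note: 2D style-transfer networks conventionally
open with a 7×7 encode kernel. Lifted to 3D that becomes a 343-tap
filter which, at the patch sizes used here, accounts for roughly a third
of all training arithmetic while the rest of the network already supplies
a large receptive field through downsampling and the residual stack. The
encode block therefore uses a 5^3 kernel (125 taps) — the same
reflection-pad/conv/instance-norm/ReLU structure at a cost proportionate
to its role; the final projection likewise uses 3^3 rather than the 2D
convention's 7^3.

The generator objective is

$$\mathcal{L} = \mathcal{L}_{adv} + \mathcal{L}_{cyc} + \lambda\,\mathcal{L}_{idn},
\qquad \lambda = 10,$$

with three ingredients:

* **Adversarial** (least-squares form): the generator minimizes
  $\mathbb{E}[(D(\text{fake})-1)^2]$; each discriminator minimizes
  $\tfrac12[\mathbb{E}(D(\text{real})-1)^2 + \mathbb{E}\,D(\text{fake})^2]$.
  The least-squares form is used for both players: the discriminator is
  explicitly a mean-squared-error classifier, and pairing it with a
  log-form generator objective would optimize mismatched potentials;
  least-squares updates are also the stabler choice for this
  architecture.
* **Cycle consistency**: $(\,\text{L1} + (1-\mathrm{SSIM})\,)/2$ between a
  patch and its two-generator reconstruction. SSIM is computed with a
  separable Gaussian window (7^3 voxels, $\sigma = 1.5$), constants
  $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ with dynamic range $L = 2$ for
  normalized intensities. The window size is a package choice (a common
  11^3 window leaves few valid positions in small patches); because no
  window is canonical, absolute loss magnitudes are implementation-
  specific, which is why tests pin closed forms (e.g. the zero-variance
  constant-patch value $C_1/(0.25 + C_1)$) rather than training curves.
* **Identity**: mean absolute change when a generator is fed a patch
  already in its target domain, weighted by $\lambda = 10$. This is what
  keeps non-contrast inputs (and everything outside vessels) near-fixed.

Training uses Adam (learning rate $2\times10^{-4}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$ — the momentum convention of cycle-consistent GAN
practice; the optimizer's moment constants are not otherwise specified),
batch size 1, one generator step then one step per discriminator per
iteration, and a 50-image history pool of past fakes for discriminator
updates (configurable; 0 disables). Kernels are initialized
$\mathcal{N}(0, 0.02)$, biases zero. All randomness — weight init, patch
positions, pool swaps — draws from one seeded stream recorded in the
checkpoint, so runs are bit-reproducible on fixed hardware. Patches wholly
of air are *not* rejected by default; an optional body-threshold rejection
sampler exists but is off, since mostly-air patches also teach the
identity map.

A non-finite loss aborts training with the offending term and iteration
named, rather than continuing into NaN weights.

### Numerical engineering

The convolution forward/backward passes are implemented in compiled code
(im2col + GEMM, chunked to bound working memory; a direct kernel for the
skinny final projection). Training runs convolutions in single precision
— GAN training is robust to that, and it halves memory traffic — while a
double-precision path backs the finite-difference gradient checks in the
test suite, which verify every layer's analytic gradient. Sliding-window
accumulation buffers are double precision so oracle-equivalence is
testable at $10^{-6}$.

## Preprocessing

Volumes are resampled to a target spacing (1×1×2 mm for translation work)
by per-axis linear (trilinear) interpolation at voxel centers — the only
reading of "bilinear" that is well-defined on volumes — then clamped to
$[-1000, 1000]$ HU and divided by 1000. Grids are indexed `(x, y, z)`,
1-based, with spacing stored `(x, y, z)` mm, the native R/NIfTI
convention. The body-contour mask thresholds at HU > −500, applies a 5×5
square-kernel morphological opening per axial slice, and fills holes per
slice (the mask feeds a slice-wise classifier, so 2D hole topology is the
relevant one). Byte normalization for convolutional backbones is
$y = \lfloor 255(x + 1000)/2000 \rfloor$ clipped to $[0, 255]$ after the
floor, replicated onto three channels.

## Whole-volume inference

Synthesis tiles the volume with patch-sized windows on a stride grid
(stride 16 by default), clamping the last window per axis to the boundary
— so coverage is complete without padding the volume with values the
generator never saw. Overlapping predictions are blended with a separable
tent kernel rising linearly from a floor of $\varepsilon = 0.05$ at the
border to 1 at the center: the simplest weighting that privileges
patch-center voxels, with the floor guaranteeing positive weight where a
voxel is covered once. Output voxel = weighted sum / weight sum. The
result is invariant to window order and, at stride = patch size,
degenerates to exact tiling. Because the exact weighting function is a
package choice, fine textures of blended outputs are not bit-comparable
across implementations; tests therefore assert equivalence against an
internal brute-force accumulation oracle.

## The phantom generator

Real training data for this problem (thousands of labelled chest CTs)
cannot ship with a package, so the study conditions are emulated by
procedural phantoms: an ellipsoidal soft-tissue body (40 HU) in air
(−1000 HU), two lung ellipsoids (−800 HU), and tubular "vessels"
(polyline tubes, radius 2–4 voxels, 60 HU) threading the chest — the
simplest geometry with localized, connected enhancement. The contrast
domain adds +300 HU inside the vessel mask; both domains get independent
Gaussian noise (default 20 HU; 10 HU in the training experiments) and are
clipped to $[-1000, 1000]$ HU, matching the preprocessing clamp. Default
grid 64^3 at 1×1×2 mm. Per-subject geometry jitter (±6% scale/offset)
makes subjects distinct; cohorts release only one domain per subject
(the unpaired regime) while a registry keeps the hidden paired
counterpart and masks for evaluation only.

What the phantoms deliberately lack: realistic anatomy and texture,
reconstruction-kernel and slice-thickness effects, and contrast-timing
variability. Passing tests on phantoms therefore demonstrate that the
machinery works — unpaired training removes localized enhancement while
identity holds elsewhere, and the evaluation arms rank models correctly —
not that clinical-grade synthesis is achieved.

## Evaluation arms

**Reader statistics.** Confusions are reconstructed from per-reader
sensitivity/specificity with the positive class fixed as "acquired/real"
— the assignment under which all printed operating points are mutually
consistent. A single-operating-point rater has
AUC = (sensitivity + specificity)/2. Panel summaries are unweighted
means; the headline "fooling rate" is mean(1 − specificity). Fleiss'
Kappa is computed from the N×k rating-count matrix; the large-sample z
statistic against κ = 0 (standard Fleiss variance) is reported as an
extension, clearly beyond the kappa itself.

**Deep-feature classification.** A pluggable backbone maps body-masked,
byte-normalized slices to pooled features (global max per channel). The
desk-scale default is a small random-weight convolutional stack — fixed
random projections preserve enough geometry for the direction checks
while avoiding any dependence on downloaded pretrained weights; an
adapter for an externally supplied pretrained backbone satisfies the same
contract. The classification head is implemented exactly as specified
for the reference experiment — sigmoid hidden activations with He-uniform
initialization and L1 penalties on weights and biases (coefficient
$10^{-5}$ by default, unstated in the reference) — an unusual pairing kept
for fidelity. Each repeat resamples a balanced validation subset from the
training pool; curves are aggregated to mean ± SEM. The shuffled-label
control preserves class counts and provides the chance-level baseline.

**Radiomics drift.** Correlated-feature removal uses the greedy
mean-absolute-correlation heuristic (the behavior of the standard tool
family; cross-checked against `caret::findCorrelation` in tests) with a
lexicographic tie-break for determinism. Kendall selection uses tau-b
(binary labels produce heavy ties) on $|\tau|$, since sign handling is
otherwise unspecified. Drift is $100\,|post - pre| / |pre|$ per subject
and feature; zero denominators exclude the cell and increment a tally —
substitution would fabricate values. AUC is the rank (Mann–Whitney)
statistic with ties at one half; two AUCs on the same subjects are
compared by paired class-stratified bootstrap with a normal approximation
to the resampled difference (degenerate spread gives p = 1). Feature
standardization is available but off by default, as no standardization
recipe is canonical. The seven classical model families of the reference
comparison are represented by a pluggable scorer contract
(fit on training rows, score validation rows); a ridge-penalized logistic
scorer ships as the built-in instance.

## Problem sizes in the shipped experiments

The test suite and acceptance script exercise the pipeline at sizes
chosen so a laptop CPU core completes them comfortably: tiny model preset
(8 base filters, 2 residual units), 32^3 patches, 4+4 training subjects
on 64^3 grids, 500 training iterations per seed (three seeds for the
recovery criterion), 24+24 subjects (16 pooled features from a
16-channel backbone) for the classification direction check with a
scaled head (hidden sizes 16-8-4, trained to convergence at
400 epochs, 6 repeats on balanced 16-subject validation resamples —
enough repeats that the standard error of the null classifier's AUC is a
meaningful yardstick), and 96^3 volumes for the inference-oracle check.
Because a random-weight backbone is itself one draw of the experiment,
the direction AUCs are additionally averaged over three independent
backbone draws.
As in the reference protocol, each evaluation subject contributes the
single slice containing its vascular anatomy (chosen domain-blind from
the evaluation-only masks). The full-scale presets
(64 base filters, 9 residual units, 64^3 patches, 450k iterations) are
configuration values, not shipped experiments.

## Known limitations

* Recovery experiments demonstrate contrast removal on piecewise-constant
  phantoms; texture fidelity on real CT is out of reach of this test
  substrate by construction.
* At a few hundred iterations the generators still perturb the background
  by tens of HU; the identity property is asserted as an ordering (less
  change on same-domain input than on cross-domain input), not as
  near-zero change.
* The reference study's own headline numbers that depend on its private
  data — its Fleiss' Kappa of 0.06 and z = 1.44, absolute learning
  curves, and per-model AUC tables — are not recomputable from published
  material (the raw 200×3 rating matrix and the imaging data are not
  public); the package reproduces the printed reader operating-point
  table exactly and covers the rest with property-based checks.
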