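---
title: "Dual cycle-consistent CT-to-MR synthesis: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual cycle-consistent CT-to-MR synthesis: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Magnetic resonance images offer soft-tissue contrast that CT lacks, but MR
acquisition is slow, expensive and contraindicated for many patients. When
only a CT scan exists, a learned CT→MR translation can add diagnostic
context. The practical obstacle is data: registered CT/MR pairs of the
same patient are scarce (they require dual acquisition plus affine
registration), while CT-only and MR-only studies are plentiful.

`ctmrsyn` trains a single synthesis system on both data regimes at once.
Four networks are optimized jointly:

* `SynMR`: CT → MR synthesis (the deliverable network),
* `SynCT`: MR → CT synthesis (regularizer and cycle partner),
* `DisMR`, `DisCT`: patch discriminators for the two image domains.

Each discriminator has **two heads over a shared trunk**. The *unpaired*
head scores a single image and is trained with the least-squares
adversarial objective (real → 1, fake → 0): squared-error targets give
smoother gradients than the saturating log loss and stabilize unpaired
training. The *paired* head scores a channel-concatenated (CT,
MR-candidate) pair with the original log-likelihood objective, which in
the paired regime produces the sharper results. The heads share the trunk
parameters, so evidence from both regimes accumulates in one feature
extractor while input arity and objective remain regime-specific.

The total objective is

$$
L = L_{adv}(Syn_{MR}, Dis_{MR}) + L_{adv}(Syn_{CT}, Dis_{CT})
  + \lambda\, L_{dual\text{-}cyc} + \gamma\, L_{L1},
$$

with the dual cycle-consistency term summing mean-L1 round-trip penalties
over **four cycles** — forward (CT→MR→CT) and backward (MR→CT→MR), once
with unpaired samples and once with paired samples — and $L_{L1}$ the
voxel-wise L1 distance between synthesized and registered reference images
(paired samples only). Defaults $\lambda = 10$, $\gamma = 100$ weight
reconstruction fidelity strongly relative to the adversarial terms;
$\gamma$ only acts in the paired phase, so in the combined regime the
scarce registered pairs anchor the intensity mapping while the unpaired
pools shape realism.

Setting `mode = "unpaired"` drops the paired phase and recovers a
CycleGAN-style baseline; `mode = "paired"` drops the unpaired phase and
recovers a pix2pix-style conditional adversarial + L1 baseline. Both run
from the same trainer and are compared against the combined mode in the
acceptance suite.

## Training procedure

Each outer iteration runs `niter` unpaired-phase passes followed by
`niter` paired-phase passes (`niter = 1` by default). A pass updates
`DisMR`, `SynMR`, `DisCT`, `SynCT` in that order, each with its own Adam
optimizer at the scheduled learning rate:

* Unpaired phase: `DisMR` descends the least-squares discriminator loss on
  real MR vs `SynMR(CT)`; `SynMR` descends its least-squares generator
  term plus $\lambda$ times the forward cycle; then symmetrically for
  `DisCT`/`SynCT` with the backward cycle.
* Paired phase: `DisMR` ascends
  $\log D(CT, MR) + \log(1 - D(CT, Syn_{MR}(CT)))$ (implemented as descent
  on the negation); `SynMR` descends
  $\log(1 - D(CT, Syn_{MR}(CT))) + \lambda \cdot cycle + \gamma \cdot L1$;
  symmetrically for the CT direction.

The per-step gradients apply $\lambda$ and $\gamma$ exactly as in the
declared total objective. Adam uses $\beta_1 = 0.5$, $\beta_2 = 0.999$
($\beta_1 = 0.5$ is the adversarial-training convention; momentum 0.9
destabilizes GAN discriminators), batch size 1. The learning rate holds at
$\alpha = 2\times10^{-4}$ for `warm_iters` iterations and decays linearly
to exactly zero over the following `decay_iters` (defaults $10^5$ and
$2\times10^5$; the iteration budget is always their sum). Batches are
drawn uniformly **with replacement** from each pool — there is no epoch
structure, matching the sampling semantics of the alternating procedure.

Checkpoints store all four networks' parameters, the full Adam state and
the RNG state, so a resumed run continues bit-identically to an
uninterrupted one — this is asserted over a 50-iteration phantom run in
the test suite.

## Preprocessing and augmentation

CT volumes arrive in Hounsfield units and are windowed with the brain
soft-tissue display window: center 40 HU, length 80 HU, i.e. the interval
$[0, 80]$ HU maps linearly onto $[0, 255]$ with clipping outside
(`window_hu()`). The window is interpreted as
$[center - length/2,\ center + length/2]$, the standard radiological
display convention. Gray slices map affinely to the network domain
$[-1, 1]$ (0 ↦ −1, 255 ↦ +1); the inverse map restores gray levels, and
the round trip is exact on 8-bit integers. Files are written with
round-half-up quantization to integers; in memory full precision is kept
(quantizing only at the file boundary keeps losses and metrics exact and
files reproducible).

Training-time augmentation draws, per sample: a horizontal flip with
probability 0.5, a crop offset uniform over all placements of the target
crop inside a zero-padded canvas (256 → 286; other sizes scale the margin
proportionally, `round(size·30/256)`), and a rotation uniform in ±5°. The
fixed composition order is **flip → pad → crop → rotate** (the transforms
are listed in this order by convention but their composition is otherwise
unspecified; fixing one order makes augmentation reproducible from its
parameter record). Rotation uses bilinear interpolation with zero fill —
zero padding matches the black background of skull-stripped slices. The
contract that matters for the mixed-regime semantics: **one parameter draw
per registered pair** (both members transformed identically, preserving
registration), **independent draws per unpaired slice**.

## Architecture

The synthesis networks are fully convolutional residual translators: a
7×7 convolution (reflection-padded to suppress border artifacts), two
stride-2 3×3 downsampling convolutions doubling the filter count, `n`
residual blocks (default 9) at quarter resolution, two fractionally
strided (transposed) 3×3 convolutions back to full resolution, and a
final reflection-padded 7×7 convolution with tanh output. Instance
normalization and ReLU follow every convolution except the last. Inputs
must be divisible by 4 (two halvings); any such size runs through the
same weights. A `resize` upsampling option (nearest-neighbour ×2 followed
by a 3×3 convolution) is available behind a config flag for users who
prefer to avoid transposed-convolution checkerboard artifacts; the
default follows the fractionally-strided construction.

Discriminators are PatchGANs emitting a grid of per-patch scores that the
losses average. All convolutions are 4×4: stride 1 in the heads and tails,
stride 2 in the shared trunk. Stride-1 convolutions use size-preserving
asymmetric padding (1 before, 2 after): with shrinking valid-style padding
the deeper tail variants could not run on 64×64 inputs after the trunk has
reduced the grid to 4×4, and size preservation keeps the patch-map
geometry a function of the trunk alone. The first convolution of each
head has no normalization (raw image statistics carry information), the
final scoring convolution has neither normalization nor activation; all
others use instance normalization and leaky ReLU (slope 0.2, the community
default). The unpaired tail emits raw scores for the least-squares loss;
the paired tail's scores pass through a sigmoid for the log-likelihood
loss — the split follows directly from mixing squared-error and log terms
in one objective. Both tails of a variant use the same filter
specification; the five named variants (`D1`–`D5`) differ in head, trunk
and tail depth/filters as documented in `?disc_variant`.

## The phantom generator

Real paired/unpaired clinical data cannot ship with a package, so
`phantom_params()`/`generate_dataset()` synthesize the *statistical
structure* the method assumes, not anatomy:

* one outer ellipse ("skull") rendered bright in CT, with random center,
  axes and ring thickness;
* 2–6 interior ellipses ("soft tissue") at low CT contrast on a uniform
  interior;
* the MR member of a pair is produced by applying a stored piecewise-linear
  intensity transfer to the CT member of the **same** geometry: the
  soft-tissue band [80, 160] stretches to [60, 230] (high MR contrast) and
  the skull band inverts (bright CT bone → dark MR bone), mimicking the
  qualitative CT↔MR contrast relationship;
* unpaired slices draw fresh, independent geometries per slice — the MR
  pool never sees the CT pool's geometry;
* optional additive Gaussian noise (independent per modality) and a random
  integer translation of the MR member emulate acquisition noise and
  residual registration error.

The transfer is stored by identifier, so tests can verify *mapping
recovery*: with zero noise and misalignment, `mr` equals the transfer
applied to `ct` exactly, and a trained `SynMR` can be scored against the
known ground truth. What the phantoms deliberately do **not** model:
anatomical texture and detail, 3D slice continuity, scanner physics,
partial-volume effects, nonlinear registration error. Passing desk-scale
tests therefore demonstrates that the optimization recovers a shared
nonlinear intensity mapping under the paired/unpaired data regime — not
clinical image quality.

Phantom defaults follow the data regime the method targets (256×256
8-bit slices; the desk-scale study below uses 64×64 for runtime).

## Evaluation metrics

`mae()`, `psnr()` and `ssim()` compare reference and synthesized MR
stacks slice-wise:

* MAE: mean over slices of the per-slice mean absolute pixel difference
  (per-pixel normalization is the default; a flag exposes the raw
  per-slice L1 sum).
* PSNR: $10\log_{10}(MAX^2/MSE)$ with $MAX = 255$ and MSE the mean over
  slices of per-slice mean squared differences. Identical stacks return
  `Inf`, which report averaging excludes.
* SSIM: computed per slice from **global** (whole-slice) means, variances
  and covariance with population (biased) estimators, then averaged over
  slices — this is the definition implemented here, not the common sliding
  11×11 Gaussian-window variant. The windowed variant exists behind
  `method = "windowed"` for comparison but is never the default. Global
  and windowed SSIM values are not comparable across publications; the
  stabilizers default to the universal $C_1 = (0.01\,MAX)^2$,
  $C_2 = (0.03\,MAX)^2$ and are configurable.

Metrics run over the full slice by default; a foreground mask flag exists
but is off (masking conventions vary and silently change the scale of all
three metrics).

## Numerical choices

* Paired-head probabilities are clamped to $[\epsilon, 1-\epsilon]$,
  $\epsilon = 10^{-7}$, before logs.
* L1 terms use the sign subgradient (zero measure ties; the subgradient at
  0 is taken as 0).
* Instance normalization uses variance floor $10^{-5}$.
* Weight init: Gaussian, sd 0.02 (the DCGAN-lineage convention).
* All losses are means over patches/pixels, making λ and γ independent of
  image and patch-map size.
* A generated-image history pool for the unpaired discriminators (common
  in cycle-consistency frameworks) is **off by default** — it is not part
  of this training procedure — but available via `use_history_pool` for
  experimentation.
* No identity-mapping loss is used.

## Desk-scale study sizes

The automated acceptance study runs on one CPU in minutes with:
64×64 phantoms; 20 paired + 60/60 unpaired training slices; 5 held-out
pairs from an independent geometry seed; generators with 8 base filters
and 2 residual blocks; a reduced custom discriminator (head 16, trunk
16/32, tail 16/1); 150 iterations of combined or unpaired-only training;
three seeds per mode. Under these conditions combined training reduces
held-out MAE from ~95 gray levels (untrained) to under 10, and
unpaired-only training plateaus several-fold higher — the qualitative
ordering expected when registered pairs anchor the intensity transfer.
These sizes are the package's reproducible study configuration; the
full-scale configuration (256×256, 64 base filters, 9 residual blocks,
$3\times10^5$ iterations) is the documented default of
`generator_spec()`/`train_config()`.

## Package shape

Core objects are image tensors (matrices/arrays) and mutable network
states, which are not naturally tabular, so the synthesis API is
array-based rather than data-frame-first. The tabular surfaces — training
logs and metric reports — are tibbles with `tidy()`/`glance()` accessors
and `autoplot()` methods, so downstream analysis composes with the usual
data-frame tooling.

## Known limitations

* The engine is CPU-only and single-threaded beyond BLAS; full-scale
  training (256×256, $3\times10^5$ iterations) is out of reach without GPU
  hardware and is not attempted.
* Phantom realism is deliberately minimal (see above); results quantify
  optimization behavior, not clinical fidelity.
* Registration and skull stripping are upstream concerns: the package
  consumes already-registered pairs (phantoms are born registered).
* 2D slices only; no 3D convolutions or multi-contrast inputs.
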