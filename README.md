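# ctmrsyn

Cross-modality CT-to-MR image synthesis from **mixed paired and unpaired
training data**, for settings where MR imaging is unavailable (metal
implants, pacemakers, claustrophobia, emergencies, cost) but CT is routine
— e.g. CT-based radiotherapy planning or screening reads that would
benefit from soft-tissue contrast.

Clinical archives typically hold a few registered CT/MR pairs and a large
number of CT-only and MR-only studies. Purely paired (conditional
adversarial + voxel-wise) training needs rigid registration and blurs;
purely unpaired (cycle-consistent) training loses anatomical context.
`ctmrsyn` trains one synthesis system on both regimes at once.

## The model

Two synthesis networks and two patch discriminators are trained jointly:
`SynMR` (CT→MR), `SynCT` (MR→CT), `DisMR`, `DisCT`. Each discriminator has
two heads over a shared trunk: an unpaired head scoring single images with
a least-squares objective, and a paired head scoring (CT, MR-candidate)
pairs with a log-likelihood objective. The total objective is

```
L = L_adv(SynMR, DisMR) + L_adv(SynCT, DisCT) + λ·L_dual-cyc + γ·L_L1
```

where `L_dual-cyc` sums the L1 cycle-consistency penalties of four cycles
(forward CT→MR→CT and backward MR→CT→MR, in both the paired and unpaired
regimes), `L_L1` is the voxel-wise L1 distance to the registered reference
(paired regime only), and λ = 10, γ = 100 by default. Training alternates
an unpaired-data phase and a paired-data phase per iteration, updating
DisMR, SynMR, DisCT, SynCT in order with Adam (β₁ = 0.5) at a learning
rate of 2e-4 with linear decay. At inference only `SynMR` runs.

Generators are fully convolutional residual networks (9 residual blocks by
default, instance normalization, tanh output); discriminators are
PatchGANs whose head/trunk/tail filter counts follow the five named
variants `D1`–`D5` (see `?disc_variant`).

Everything is exercisable end-to-end on synthetic two-modality head
phantoms (shared geometry per pair, a stored nonlinear CT→MR intensity
transfer, independent geometries across unpaired pools), so no clinical
data are required for development or testing.

## Worked example

```r
library(ctmrsyn)

params <- phantom_params(image_size = 64, seed = 7)
ds <- generate_dataset(params, n_paired = 10, n_unpaired_ct = 30, n_unpaired_mr = 30)
ds
#> <ctmr_phantom_dataset> 10 paired, 30 unpaired CT, 30 unpaired MR slices (64x64)

cfg <- train_config(
  warm_iters = 60, decay_iters = 0,
  gen_spec = generator_spec(base_filters = 8, n_residual_blocks = 2),
  disc_variant = disc_variant("custom", head_filters = 16,
                              shared_filters = c(16, 32),
                              tail_filters = c(16, 1)),
  image_size = 64, seed = 1, mode = "both")
fit <- train(ds, cfg)
tail(tidy(fit), 2)
#> # A tibble: 2 × 10
#>   iteration phase    adv_mr adv_ct dual_cyc voxel_l1   d_mr   d_ct total     lr
#>       <int> <chr>     <dbl>  <dbl>    <dbl>    <dbl>  <dbl>  <dbl> <dbl>  <dbl>
#> 1        60 unpaired  0.278  0.388    0.194    0      0.482  0.412  2.60 0.0002
#> 2        60 paired   -0.609 -0.556    0.222    0.214 -1.35  -1.20  22.5  0.0002
```

One log row per phase and iteration: generator adversarial terms
(`adv_*`; least-squares in unpaired phases, log-likelihood — negative by
construction — in paired phases), the dual cycle-consistency mean
(`dual_cyc`, network-domain units), the voxel-wise L1 term (paired phases
only), discriminator losses and the λ/γ-weighted `total`.

Synthesize MR for held-out CT slices and evaluate per patient:

```r
test <- generate_dataset(phantom_params(image_size = 64, seed = 99), 3, 0, 0)
ct <- simplify2array(lapply(test$paired, `[[`, "ct"))
mr <- simplify2array(lapply(test$paired, `[[`, "mr"))
syn <- synthesize(fit, ct)
build_report(list(
  `Pat-01` = list(reference = mr[, , 1, drop = FALSE], synthesized = syn$slices[, , 1, drop = FALSE]),
  `Pat-02` = list(reference = mr[, , 2, drop = FALSE], synthesized = syn$slices[, , 2, drop = FALSE]),
  `Pat-03` = list(reference = mr[, , 3, drop = FALSE], synthesized = syn$slices[, , 3, drop = FALSE])))
#> # A tibble: 4 × 4
#>   patient   mae  psnr  ssim
#>   <chr>   <dbl> <dbl> <dbl>
#> 1 Pat-01  10.1   24.7 0.958
#> 2 Pat-02  11.3   21.9 0.940
#> 3 Pat-03   9.49  24.5 0.963
#> 4 Average 10.3   23.7 0.954
```

MAE is in 8-bit gray levels (lower is better); PSNR in dB and SSIM in
[-1, 1] (higher is better; SSIM here uses global per-slice statistics —
see the methods vignette). After only 60 desk-scale iterations the
synthesized MR is already ~10 gray levels from the phantom ground truth,
versus ~95 for an untrained generator.

A command-line interface with the same functionality ships as
`exec/ctmrsyn` (subcommands `phantoms`, `train`, `synth`, `eval`; see
`?run_cli`).

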