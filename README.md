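# optiqat

Quantization-aware training (QAT) for diffractive optical networks, in R.

## The problem

A diffractive deep neural network (D2NN) is a stack of passive phase-only
layers: coherent light propagates through them, and the per-pixel phase delay
of each layer is a learnable parameter (an "optical neuron"). Such networks
can classify phase objects or perform all-optical quantitative phase imaging
(QPI) — turning the invisible phase delay of a transparent specimen, such as
a red blood cell, into a detector intensity image — with no electronic
computation at inference time.

Fabrication is the obstacle: 3D microfabrication realizes only a few
discrete phase levels per neuron. Training with continuous phases and
rounding afterwards (*post-quantization*) changes the model the optics
actually implements, and this *model mismatch* collapses performance at low
bit depth. `optiqat` puts the quantizer inside the differentiable forward
model so the network is trained as it will be built.

## What is inside

* **Optics** — band-limited angular-spectrum propagation between planes
  (exact scalar free-space diffraction, FFT-based, unitary on the
  propagating band), phase-only modulation, phase-object input encoding
  `E = exp(i*pi*image)`. Analytic adjoints for every operation; no autodiff
  framework is used or needed.
* **Quantizers** — hard round-to-nearest with clamping; progressive sigmoid
  quantization (PSQ), a sum of shifted logistics
  `Q(x, tau) = l + sum_i Delta * sigmoid(tau * (x - l - Delta/2 - i*Delta))`
  that converges to the hard staircase as the temperature `tau` grows, with
  no out-of-range clamping so every coefficient keeps a gradient; tanh-based
  DSQ with fixed bounds; the straight-through estimator; Gumbel-Softmax
  relaxation; post-quantization.
* **Schedules** — fixed temperature, linear growth
  `tau(t) = tau0 + (dtau/dt) * t`, and the learnable scheme
  `tau = 1/(k + gamma)` with the progressive regularizer
  `R_t = lambda1 * (s_t * ||k||^2 - lambda2)^2`, `s_t = 2^floor(t/beta)`,
  which halves the target `||k||^2` every `beta` epochs and so drives the
  temperatures up on a doubling clock.
* **Tasks** — 10-patch detector readout with a weighted squared-error loss
  for classification; reverse Huber (berHu) intensity-vs-phase regression
  for QPI; SSIM and binned phase-error evaluation.
* **Pipeline** — two-stage protocol (full-precision pre-training, phase
  wrapping into `[0, 2*pi)`, QAT fine-tuning), Adam, deployment-condition
  evaluation (wrapped + hard-quantized phases), JSON checkpoints, TIFF/CSV
  mask export, YAML-configured runs and a small CLI
  (`inst/scripts/optiqat`).
* **Synthetic data** — stroke-built digit-like classes, RBC-like biconcave
  disks, sparse smooth blobs, and analytic controls, all deterministic per
  seed, so nothing needs downloading.

## A worked example

Train a 2-layer D2NN for all-optical QPI on synthetic blob specimens at
4 phase levels, compare post-quantization against PSQ fine-tuning:

```r
library(optiqat)

batch <- synth_phase_objects(120, "blob", size = 32, seed = 1)
train <- batch[1:96, ]; test <- batch[97:120, ]
g4 <- quant_grid(0, 1.99 * pi, 4)
quant_levels(g4) / pi
#> [1] 0.0000000 0.6633333 1.3266667 1.9900000

model <- d2nn(n_layers = 2, grid_size = 32, quant_kind = "fp",
              grid = g4, seed = 1)
fp <- train_fp(model, train, task_qpi(), epochs = 30, lr = 0.1,
               batch_size = 16, seed = 1)

evaluate_model(fp, test, task_qpi())$metrics$mean_ssim      # full precision
#> [1] 0.4124291
evaluate_model(post_quantize(fp, g4), test, task_qpi())$metrics$mean_ssim
#> [1] 0.115446                                              # naive rounding

qat <- train_qat(fp, train, task_qpi(), quant_kind = "psq", grid = g4,
                 schedule = sched_fixed(10), epochs = 30, lr = 0.1,
                 batch_size = 16, seed = 2)
evaluate_model(qat, test, task_qpi())$metrics$mean_ssim
#> [1] 0.1751891                                             # QAT recovers
```

The three SSIM values tell the story: rounding a continuously trained model
onto 4 levels loses most of its imaging fidelity, while fine-tuning with the
soft quantizer in the loop recovers a substantial part of the gap — the
deployed masks in both cases lie exactly on the same 4-level grid
(`export_masks()` writes them as TIFF plus CSV level indices). `tidy()` on a
fit returns the per-epoch loss/temperature log; `autoplot()` draws fields,
training histories and phase-error curves.

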