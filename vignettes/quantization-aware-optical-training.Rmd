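---
title: "Quantization-aware training of diffractive optical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantization-aware training of diffractive optical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optiqat)
```

## The problem

A diffractive deep neural network (D2NN) is a cascade of passive phase-only
layers. Light from a coherent source passes through the stack; free-space
diffraction between layers plays the role of a (fixed, unitary) fully
connected linear map, and the per-pixel phase delays of each layer are the
learnable parameters — "optical neurons". Once trained, the stack computes at
the speed of light with no electronics. The catch is fabrication: 3D
microfabrication can only realize a small number of discrete phase levels per
neuron. Training with continuous phases and then rounding them onto the
fabricable levels (*post-quantization*, PQ) changes the parameter
distribution the network was trained with, and this *model mismatch* can
destroy performance, especially at 2–4 levels.

`optiqat` implements quantization-aware training (QAT) for this setting: the
quantizer sits inside the forward model during training, so the deployed
(hard-quantized) network is the network that was optimized.

## Forward model

The simulator operates on sampled complex fields (`complex_field`): a square
grid of complex amplitudes with a physical pitch and wavelength. The network
forward pass is

$$E_\mathrm{out} = G_\mathrm{out} \circ F_N \circ G \circ \cdots \circ F_1
  \circ G_\mathrm{in}\,(E_\mathrm{in}),$$

where each $G$ is free-space propagation over a fixed distance and each
$F_n(E) = E \cdot e^{\,i\,Q(\varphi_n, \tau_n)}$ multiplies by a unit-modulus
phasor built from that layer's raw coefficients $\varphi_n$ through the
quantizer $Q$. A detector records $I = |E_\mathrm{out}|^2$.

Propagation uses the band-limited angular-spectrum method: multiply the
field's 2D spectrum by
$H(f_x,f_y)=\exp\!\big(i\,2\pi d\sqrt{1/\lambda^2-f_x^2-f_y^2}\big)$ on the
propagating band and zero the evanescent band. On the band $|H|=1$, so the
operator is exactly unitary on the periodic grid, linear, and forms a
semigroup in the distance — all three properties are tested to 1e-6. By
default each propagation zero-pads the grid to twice its side and crops back,
which suppresses periodic wrap-around at the cost of letting wide-angle light
leave the simulation window; `pad = FALSE` gives the strictly unitary
periodic operator and is what the conservation tests use.

Phase objects enter through `field_from_phase_image()`: an image in
$[0,1]$ becomes $E_\mathrm{in} = e^{\,i\pi\,\mathrm{image}}$ — unit
amplitude, information purely in the phase over $[0,\pi]$.

### Physical defaults

Wavelength 632.8 nm (HeNe), neuron pitch one wavelength, and 40 wavelengths
between planes. Diffractive neurons are physically on the order of half a
wavelength to a wavelength; the geometry is configurable and nothing in the
method depends on these particular values. At pitch $\lambda$ the sampled
spectrum sits entirely inside the propagating band, which keeps the discrete
operator unitary.

## Quantizers

All quantizers share a uniform level grid (`quant_grid`): $N$ levels between
$l$ and $u$ with step $\Delta=(u-l)/(N-1)$. Phase coefficients live on
$[0, 1.99\pi]$ — 0 and $2\pi$ are the same phase shift, so the top level
stops one percent of $\pi$ short of a full cycle; 2-level classification
grids use $\{0, \pi\}$. For $N = 4$ the levels are
$\{0, 0.663\pi, 1.327\pi, 1.990\pi\}$.

* **Hard quantization** rounds to the nearest level with clamping at the
  bounds. Its gradient is zero almost everywhere — useless for training,
  but it *is* the deployment condition, so every evaluation in the package
  hard-quantizes (after wrapping phases into $[0,2\pi)$).
* **PSQ** (progressive sigmoid quantization) replaces the staircase with a
  sum of shifted logistics,
  $Q_s(x,\tau)=l+\sum_{i=0}^{N-2}\Delta\,\sigma(\tau(x-l-\Delta/2-i\Delta))$.
  It is strictly monotone, bounded in $(l,u)$, analytic, and converges to
  the hard quantizer as the temperature $\tau$ grows. Deliberately, no
  clamping is applied outside $[l,u]$: out-of-range coefficients keep a
  nonzero gradient and get pulled back during training.
* **DSQ** is the tanh-based soft quantizer: within each cell between
  adjacent levels the curve is
  $m + \tfrac{\Delta}{2}\tanh(\tau(x-m))/\tanh(\tau\Delta/2)$ about the cell
  midpoint $m$, with fixed range bounds and clamping outside — phases live
  in a fixed range, so learning the bounds is disabled.
* **STE** uses the hard quantizer forward and an identity Jacobian backward.
* **Gumbel-Softmax** treats quantization as a noisy categorical choice among
  the levels, with logits $-(x-\mathrm{level}_i)^2/\Delta^2$; its output is
  the softmax-weighted level average, annealed from temperature 50 downward
  by 0.5 per epoch (the conventional schedule).
* **PQ** is not a training method at all: wrap, hard-quantize, done.

The Gumbel logit construction is distance-based; the original construction
for optical networks is not published in detail, and any logits that collapse
onto the nearest level at low temperature satisfy the same contract.

## Temperature schedules

Progressive training starts soft (small $\tau$, smooth loss surface) and
hardens the quantizer as training proceeds:

* **Fixed** (PSQ-FT): constant $\tau$. Default 10, i.e. $\tau\Delta\approx21$
  on the 4-level phase grid — transitions occupy roughly a tenth of a step.
* **Linear** (PSQ-LI): $\tau(t)=\tau_0+\frac{\Delta\tau}{\Delta t}\,t$.
  Defaults $\tau_0=1$, $\Delta\tau=1$, $\Delta t=1$.
* **Learnable** (PSQ-LT): each layer carries a raw parameter $k_m\ge0$ with
  $\tau_m = 1/(k_m+\gamma)$; the constant $\gamma>0$ caps the temperature at
  $1/\gamma$. The grouping $1/(k+\gamma)$ (rather than $1/k+\gamma$) is the
  one for which $\gamma$ actually bounds $\tau$, which is its stated
  purpose. The regularizer
  $R_t(k)=\lambda_1\,(s_t\lVert k\rVert_2^2-\lambda_2)^2$, with
  $s_t=2^{\lfloor t/\beta\rfloor}$, is added to the loss only in this
  scheme; it is zero when $\lVert k\rVert^2=\lambda_2/s_t$, a target that
  halves every $\beta$ epochs, so the temperatures are pushed up on a
  doubling clock while remaining free to adapt by backpropagation. The
  squared-penalty grouping is likewise the only reading under which the
  term *forces* the increase. Defaults: $\gamma=0.05$, $\lambda_1=\lambda_2=1$,
  $\beta=10$, $k$ initialized to $1-\gamma$ so every $\tau$ starts at 1.
  After each optimizer step $k$ is projected onto $k\ge0$.

These default values are the package's own choices (the granularity — one
temperature per diffractive layer — follows from treating each layer as one
quantization instance).

## Tasks

**Classification.** Ten disjoint square patches on the detector (default a
regular 2×5 grid; any disjoint layout is valid); the class is the patch with
the highest mean intensity, ties to the lowest index. The training loss is a
weighted squared error between the detector intensity and the binary label
map $Y$: non-target pixels have weight 1, target-patch pixels weight
$1-c_w$ (default $c_w = 10/11$, i.e. target weight $1/11$), penalizing
stray light harder than imperfect concentration. $c_w$ is exposed because
the exact published weight is ambiguous.

**Quantitative phase imaging (QPI).** The detector intensity is trained to
reproduce the input phase scaled to $[0,1]$ ($\phi/\pi$) under the reverse
Huber (berHu) loss: $|e|$ below the threshold $c$, $(e^2+c^2)/2c$ above,
continuous with continuous derivative at $|e|=c$. Default $c$ is adaptive,
$0.2\max|e|$ per sample (treated as constant in the gradient), overridable
to a fixed value.

## Gradients without autodiff

R has no automatic differentiation, so the backward pass is derived
analytically (as the physical system's adjoint) and audited against central
finite differences:

* intensity: $\partial L/\partial E^* = (\partial L/\partial I)\,E$
  (Wirtinger calculus, real loss);
* propagation: the adjoint of the band-limited angular-spectrum operator is
  the same operator with conjugated transfer function (back-propagation by
  $-d$);
* modulation: $g \mapsto g\,e^{-i\theta}$, and the real-parameter gradient
  at a layer is $\partial L/\partial\theta = 2\,\mathrm{Im}(g_B
  \overline{B})$ where $B$ is the field leaving the layer;
* quantizers: analytic $\partial Q/\partial x$ and (PSQ)
  $\partial Q/\partial\tau$, chained into $\partial L/\partial\varphi_n$ and
  $\partial L/\partial k_n$.

The full-chain audit (2-layer network, berHu loss, 8×8 grid) agrees with
finite differences to better than 1e-6 relative; the test suite enforces
1e-4. Optimization is Adam (defaults $\beta_1=0.9$, $\beta_2=0.999$); the
package-default learning rates are 1e-2 for phases and 1e-3 for $k$.

## Two-stage protocol

`train_fp()` first trains the network with unconstrained phases (the FP
reference). Before fine-tuning, `wrap_phases()` maps all coefficients into
$[0,2\pi)$ — the forward model is invariant, but unwrapped coefficients
spread over several cycles would otherwise be clamped to the extreme levels
at the start of QAT. `train_qat()` then fine-tunes with the chosen quantizer
and schedule. Every evaluation (`evaluate_model()`) runs the deploy
condition: wrapped, hard-quantized phases — the quantity of scientific
interest is precisely the performance *after* model mismatch is imposed.

## Synthetic phase objects

`synth_phase_objects()` makes the package self-contained: `digit_like`
(ten stroke-built archetypes with affine jitter; nearest-centroid separable,
so a classifier has signal to find), `rbc_like` (biconcave disk with bright
rim and central dip — red-blood-cell morphology in quantitative phase
imaging), `blob` (a few smooth Gaussian bumps on a dark background with mild
band-limited texture — generic sparse phase specimens), and two analytic
controls (`flat`, `checker`). All images are in $[0,1]$ and deterministic
per seed.

The `blob` family is deliberately *sparse*. A dense random field filling the
whole window gives a shallow phase-only network no achievable
intensity-matching strategy (total power through the stack is conserved up
to window losses, so a full-field target over-constrains throughput), and
training plateaus at near-zero structural similarity; compact objects on a
dark background are both more like real specimens and learnable at desk
scale. These generators emulate morphology only — no camera noise, no
partial coherence, no dataset-specific intensity statistics — so passing
tests demonstrate the training machinery, not performance on any real
instrument's data.

## The desk-scale method comparison

`method_ranking_experiment()` reruns the central claim at a size a laptop
handles in minutes: 32×32 grid, 2-layer network, 300 synthetic blobs (80/20
split), 30 FP + 30 QAT epochs, 4 levels, three seeds, Adam with learning
rate 0.1 (a 30-epoch schedule is ~240 Adam steps, which bounds total phase
movement by roughly lr × steps; the package-default 1e-2 cannot traverse a
phase cycle in that budget — the same reasoning sets `lr_k = lr/10`,
preserving the default ratio between the two rates, and shortens the
regularizer's doubling period to `qat_epochs/10` so the run keeps the ten
doubling windows the default `beta = 10` gives a 100-epoch schedule).
Methods: PQ, PSQ-FT, PSQ-LT, with the FP model as reference.

The robust finding at this scale, reproduced by the acceptance tests, is
that both QAT variants clearly beat post-quantization at 4 levels in every
seed, with gaps well above the seed-to-seed variability of the (paired,
shared-pre-training) comparison. The second-order ordering between the two
progressive flavors is budget-dependent: over a 30-epoch fine-tune the
learnable schedule spends its first third training near-soft (τ of a few)
and hardens late, so the fixed schedule — which trains at its
deployment-matched temperature throughout — typically ends slightly ahead;
the advantage of learnable schedules reported for 100-epoch trainings does
not have room to materialize here. Absolute SSIM values at this scale are
far below what a 5–7-layer network trained for hundreds of epochs on a real
dataset reaches; only the orderings, not the absolute levels, are the claims
under test.

## Numerical choices and edge cases

* Sigmoids and softmaxes are computed in overflow-safe forms; PSQ is exact
  at machine precision for $|\tau x| > 700$ where naive `exp` overflows.
* At very high temperature PSQ saturates to the hard staircase *exactly* in
  double precision, so "strictly increasing" degrades to nondecreasing —
  the documented behavior, not a bug.
* `distance = 0` propagation is the identity (no band-limit filtering).
* Hard quantization uses R's `round()` (banker's rounding); exact midpoint
  ties are measure-zero and land on either adjacent level.
* Classification ties resolve to the lowest class index, documented in
  `classify_intensity()`.
* SSIM follows the standard 11×11 Gaussian-window ($\sigma=1.5$) population
  formulation with the mean taken over the valid region; it matches the
  reference implementation to 1e-9 on frozen fixtures.
* The phase-error curve bins $[0,\pi]$ into 20 equal bins of mean
  $|I\pi-\phi|$.
* Training aborts with a diagnostic on non-finite coefficients rather than
  silently continuing.

## Known limitations

Scalar, fully coherent, phase-only optics — no polarization, no partial
coherence, no absorption, no fabrication noise model. The Rayleigh–Sommerfeld
propagator is realized in its angular-spectrum form; direct-integral
discretizations differ at extreme angles that the band limit excludes. The
learnable-temperature scheme is implemented for PSQ only (DSQ keeps a
scheduled temperature, per the fixed-bounds variant used here). Non-uniform
level grids are out of scope.
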