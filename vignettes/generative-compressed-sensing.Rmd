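---
title: "Task-driven compressed sensing with a learned sampler and a generative rebuilder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-driven compressed sensing with a learned sampler and a generative rebuilder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencs)
```

## The problem

Classical compressed sensing recovers a signal $x \in \mathbb{R}^n$ from
$m \ll n$ linear measurements $y = \Phi x$ by exploiting sparsity in a known
basis. For natural images in *task-driven* acquisition systems — a camera
that only ever photographs seedling trays, or only faces — sparsity is a
weak prior: the images concentrate near a low-dimensional manifold specific
to the task, and a generic Gaussian $\Phi$ with a generic sparse recovery
algorithm wastes most of its measurement budget at the very low sampling
rates ($sr = m/n$ of a few percent) that energy-limited sensors want.

This package implements a fully learnable alternative in which every stage
of the pipeline is trained on images of the task at hand:

* **Sampler** $Sp(x) = \Phi x$ — a single linear layer with no bias and no
  activation. Its weight matrix *is* the measurement matrix, learned
  jointly with the rest of the model (or frozen at an i.i.d. $N(0,1)$
  Gaussian draw for the classical baseline).
* **Solver** $Sv(y) = (\mu, \log\sigma^2)$ — a fully connected network
  (hidden widths 1024, 512, 256 with ReLU and batch normalisation; linear
  output of width $2k$) that maps measurements to a diagonal Gaussian over
  the $k$-dimensional latent space.
* **Rebuilder** $R(z)$ — a generative decoder: a linear projection of $z$
  to a $4 \times 4$ seed feature map, then stride-2 transposed
  convolutions with $5 \times 5$ kernels up to the image side, hyperbolic
  tangent on every layer, so outputs live in $(-1, 1)^n$.
* **Discriminator** $D(x)$ — a DCGAN-style critic used only during
  training: stride-2 convolutions with leaky-ReLU (slope 0.2) and a
  sigmoid head.

Images are handled at model scale $[-1, 1]$ (8-bit value $v$ maps to
$v/127.5 - 1$) and flattened row-major over (height, width, channel); the
flattening order is fixed and recorded in checkpoints because the learned
$\Phi$ is only meaningful relative to it.

## Training losses

Training combines a variational autoencoder view (the Sampler + Solver are
the encoder; the Rebuilder is the decoder) with an adversarial one (the
Rebuilder doubles as a GAN generator fed standard-normal noise latents
$z_n$). Per batch, with $x_z = R(z)$, $z = \mu + \sigma \odot \varepsilon$
(the reparameterised sample) and $x_n = R(z_n)$:

* Discriminator: $L_D = -\log D(x) - \log(1 - D(x_n))$.
* Rebuilder: $L_R = \lVert x_z - x \rVert_p^p
  + \lVert D(x_z) - D(x) \rVert_2^2 - \log D(x_n)$.
* Encoder (Sampler + Solver): $L_E = \lVert x_z - x \rVert_p^p
  + \lVert z \rVert_2^2 + L_l(\mu, \sigma)
  + \lVert D(x_z) - D(x) \rVert_2^2$, with the latent loss
  $L_l = -\sum_i \tfrac12 (1 + \log\sigma_i^2 - \sigma_i^2 - \mu_i^2)$,
  the KL divergence from $N(\mu, \sigma^2)$ to $N(0, I)$.

Design choices where the formulation leaves room:

* **$\lVert D(\cdot) - D(\cdot) \rVert^2$ is feature matching** by
  default: the distance is taken between the activations of the last
  convolutional layer of the critic (the VAE-GAN "learned similarity"
  convention), because with scalar probabilities the term is nearly
  redundant with the adversarial log terms. A `scalar_output` switch
  restores the literal reading.
* **The Solver outputs log-variance**, $\sigma = e^{\text{logvar}/2}$, so
  positivity is structural rather than hoped for from a raw linear
  "variance" output, and $\log \sigma^2$ in $L_l$ is exact.
* **Update schedule.** The three losses and their gradients are computed in
  one forward pass at the step-start parameters; Adam steps are then
  applied in the order Discriminator → Rebuilder → Encoder, one step each
  per batch. The formulation specifies the three losses and this ordering
  but not whether forward passes are recomputed between sub-steps;
  single-forward is the usual VAE-GAN practice and 2–3× cheaper, and the
  gradient-check tests cover exactly this composition.
* **Double latent regularisation.** $L_E$ contains both
  $\lVert z \rVert^2$ and $L_l$, which overlap in purpose; both are kept,
  as written, with independent non-negative weights exposed in
  `loss_config()` (all default 1).
* **Reductions.** Image terms are summed over pixels (as the norms are
  written) and averaged over the batch; a per-pixel mode exists.
  Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before logarithms.
* The discriminator sees the real image (label 1) against the
  noise-generated one (label 0), exactly as the loss is written; $x_z$ is
  not a discriminator target by default.

Defaults follow the reference setting: Adam with learning rate $10^{-3}$,
batch size 32, $\beta = (0.5, 0.999)$ (the DCGAN convention; only the
learning rate is prescribed), reconstruction norm $p = 1$ (the variant the
ablation recommends; $p = 2$ available), latent dimension $k = 100$ at the
reference geometry.

## Reconstruction by latent optimisation

After training, the Discriminator is discarded. Given measurements $y$, the
latent is initialised at the Solver mean, $z_0 = \mu(Sv(y))$ — the
deterministic reading of "initialise $z$ from the Solver", and the reason
reconstruction needs only a few iterations — and updated for `imax`
iterations against the measurement-consistency loss

$$\mathrm{loss}(z) = \lVert Sp(R(z)) - y \rVert_2^2,$$

with Adam at learning rate 0.05 (defaults `imax = 100`, `lr = 0.05`). The
text of the method prescribes Adam even though the pseudo-code prints a
plain gradient step; a plain-SGD mode is switchable. A `random`
initialisation ($z_0 \sim N(0, I)$) provides the random-restart baseline of
generative-model compressed sensing. The loss is recorded *before* the
first update, so the trace has `imax + 1` entries and the quality of the
initialisation is measurable; with `imax = 0` and solver initialisation the
result is bitwise the plain forward pass $R(Sv(Sp(x)))$. Batch
normalisation always runs in eval mode here, so a reconstruction cannot
depend on which other images share the batch, and no model parameter is
touched (the suite checks this bitwise).

The squared norm is not averaged over measurement entries; with Adam's
per-coordinate scaling the iterate path is invariant to that choice except
through the fixed learning rate.

## Measurement diagnostics

`estimate_srec()` reports the empirical set-restricted eigenvalue
$\hat\gamma = \min_{x_1 \ne x_2} \lVert \Phi(x_1 - x_2) \rVert_2^2 /
\lVert x_1 - x_2 \rVert_2^2$ over image pairs, the one-parameter proxy for
the set-restricted eigenvalue condition (the additive slack is fixed at 0,
since the two-parameter form is underdetermined from data). It doubles as a
restricted-isometry diagnostic; no certified verification is attempted
(that problem is NP-hard). Gaussian baselines use raw $N(0,1)$ entries
without row normalisation.

`measurement_count()` maps a sampling rate to $m = \max(1,
\mathrm{round}(sr \cdot n))$ with half-up rounding — the rounding is not
prescribed anywhere, and half-up keeps $m/n$ closest to the nominal rate.

## Image-quality metrics

PSNR and SSIM are computed on the 8-bit scale (images mapped back from
$[-1,1]$ to $[0,255]$), over all channels jointly for the global variants:
$\mathrm{PSNR} = 10 \log_{10}(255^2 / \mathrm{MSE})$, with an infinite
sentinel at zero MSE. Printed forms of PSNR occasionally drop the division
by the MSE; the standard form above is the only reading under which the
metric decreases with error.

SSIM ships in three variants. `standard_windowed` (the reporting default)
is the standard structural similarity with an $11 \times 11$ Gaussian
window ($\sigma = 1.5$), weighted uncorrected moments over every fully
interior window position, and the SSIM map averaged (colour images average
per-channel values). It matches an independent reference implementation to
machine precision on random pairs — the suite pins this with frozen
reference values. `standard_global` applies the standard formula to global
image moments. `as_printed` reproduces a formula variant whose luminance
numerator is $(\mu_x \mu_{\hat x} + c_1)$ instead of
$(2\mu_x\mu_{\hat x} + c_1)$; whether that factor-2 omission is a typo
cannot be settled from the printed formula alone, so both are implemented
and labelled — note `as_printed` is not 1 for identical images, which is
why it is never the reporting default. Stabilisers default to
$c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$.

## Synthetic study worlds

No external dataset is required; two seeded generators emulate the
*statistical character* of task-driven acquisition — many images of one
scene class with strong structural similarity and a genuinely
low-dimensional family of variation:

* `rosette`: a dark, weakly textured soil background plus a centred
  multi-lobed green rosette; jittered centre (±0.15 of the half-width),
  radius (20–40% of the side), lobe count (4–8), lobe depth, hue (±10%).
* `facelike`: a skin-tone oval with two eye ellipses and a mouth ellipse,
  with jittered geometry and hue.

Scenes are rasterised at 2× resolution and box-downsampled, so edges are
anti-aliased rather than binary — hard edges at small sides produce
degenerate gradients. What these worlds deliberately do **not** emulate:
photographic texture, lighting, occlusion, background clutter, or the
heavy-tailed variability of real plant/face datasets. Tests passing on
them demonstrate that the machinery (losses, gradients, optimisation,
metrics) is correct and that the method's qualitative claims hold in a
controlled world — not that the quantitative gains transfer to any
particular real dataset.

The `linear world` replaces the Rebuilder with a known linear map $A$ with
orthonormal columns ($x = A z^*$, $y = \Phi x$ exactly). Because
$\mathrm{argmin}_z \lVert \Phi A z - y \rVert^2$ has a closed-form
normal-equations solution, iterative latent-space reconstruction can be
validated against an analytically known answer; the suite requires
recovery to $10^{-2}$ relative latent error from random initialisation on
well-conditioned instances ($\mathrm{cond}(\Phi A) \le 10$).

## Numerical and scale choices

* **Precision.** Dense algebra runs in R's double precision via BLAS; the
  convolution/transposed-convolution kernels (im2col + GEMM in C++) run in
  single precision by default — the customary deep-learning training
  precision — with a double-precision path that the finite-difference
  gradient checks use. Single-seeded runs are bit-reproducible on a given
  platform either way.
* **Initialisation.** Weights $N(0, 0.02)$, biases zero (DCGAN
  convention); the learned $\Phi$ starts from the same small-weight
  initialisation, the Gaussian variant from $N(0,1)$ and stays frozen.
* **Geometry.** The decoder needs $\log_2(\mathrm{side}) - 2$ stride-2
  stages from its $4 \times 4$ seed, hence sides must be powers of two
  $\ge 8$. `width_base` scales all channel counts; 64 reproduces the
  reference geometry (a $4 \times 4 \times 512$ seed at side 64).
* **Desk scale.** The bundled study runs (tests and the acceptance script)
  use side 32, $k = 16$, `width_base = 32`, 500 training images, 10
  epochs, and 50-image test sets with 100 reconstruction iterations —
  sizes chosen so the whole replication grid trains on one ordinary CPU
  core in minutes while keeping every architectural motif (projection +
  reshape, stride-2 upsampling, mirrored critic) intact. At this scale the
  learned-sampler advantage over the Gaussian matrix is a directional
  effect of fractions of a dB, clearest at the lowest sampling rates,
  because the synthetic scene family is simple enough that moderate
  numbers of random projections already pin down its latent coordinates.
* **Ties and degenerate inputs.** `measurement_count` floors at one
  measurement; SSIM falls back from windowed to global moments below the
  11-pixel window (reconstruction summaries do this automatically);
  identical-image sets make the restricted-eigenvalue ratio undefined and
  raise an error rather than returning 0/0.

## Limitations

* Square, power-of-two, fixed-channel images only; no block-based scheme
  for large images.
* Training is single-threaded CPU; the implementation is written for
  correctness and desk-scale experiments, not for GPU-scale throughput.
* The Discriminator architecture is not prescribed by the formulation; the
  DCGAN critic used here is a convention, exposed via the model
  configuration.
* No perceptual metrics, no multiple-restart reconstruction beyond the
  single random-initialisation baseline.
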