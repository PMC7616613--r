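---
title: "Label-conditioned diffusion synthesis for echocardiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-conditioned diffusion synthesis for echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echosynth)
```

`echosynth` generates synthetic 2D echocardiograms from semantic label maps
with a conditional denoising diffusion model, builds augmented synthetic
datasets from them, and trains and scores segmentation U-Nets on the result.
This vignette is the package's own account of the science: the models and
their assumptions, the parameters that matter, what the phantom generator
does and does not emulate, and the design decisions taken where more than
one reasonable choice existed.

## 1. The diffusion core

The forward process corrupts a clean image $y_0 \in [-1,1]^{H\times W}$ over
$T$ steps,

$$ q(y_t \mid y_0) = \mathcal N\!\big(\sqrt{\bar\alpha_t}\,y_0,\;
   (1-\bar\alpha_t) I\big), \qquad
   \bar\alpha_t = \prod_{\tau\le t}(1-\beta_\tau). $$

`cosine_schedule()` sets $\bar\alpha_t = f(t)/f(0)$ with
$f(t)=\cos^2\!\big(\frac{t/T + s}{1 + s}\cdot\frac{\pi}{2}\big)$ and offset
$s = 0.008$, clipping $\beta_t$ at 0.999 to avoid a singular final step.
Relative to a linear schedule the cosine profile retains signal longer at
early $t$ (the package tests compare $\bar\alpha_{T/4}$ between the two),
pushing more of the corruption into late steps where the denoiser works on
nearly pure noise.

$T$ is configurable; 1000 is the default, the convention of the
improved-DDPM lineage whose hybrid objective we adopt. Tests exercise
$T \in \{1, 50, 100\}$ — every property checked is $T$-independent.

The training loss is

$$ L = \big\|\epsilon_\theta(y_t \mid x) - \epsilon\big\|^2_{\text{mean}}
   + \lambda\, \mathrm{KL}\big(\mathcal N(\mu_\theta, \sigma_\theta^2)\,\|\,
     q(y_{t-1}\mid y_t, y_0)\big), \qquad \lambda = 0.001, $$

with the mean path of the KL term detached so only the variance head learns
from it — with a fixed variance the KL term would be meaningless, which is
why the denoiser predicts a per-pixel interpolation coefficient
$v \in (0,1)$ between $\log\beta_t$ and $\log\tilde\beta_t$ (the posterior
variance), the learned-range parameterisation. The small $\lambda$ keeps the
variance objective from destabilising noise prediction. At $t=1$ the
posterior variance is exactly 0; the sampler adds no noise there, and where
a log-variance is needed the degenerate first entry is replaced by its
$t=2$ neighbour, the usual clipping.

Classifier-free guidance
$\hat\epsilon = \epsilon_c + s(\epsilon_c - \epsilon_\varnothing)$ is
implemented (`guided_noise()`), with the null condition $\varnothing$
represented as an all-zero one-hot label tensor — the simplest representable
"no semantics" input. Guidance is disabled by default at inference: it
doubles denoiser evaluations, and conditional-only sampling is the package's
default operating point. Training the null branch (random condition
dropping) sits behind `cfg_dropout`, default off.

## 2. The denoiser and its engine

`build_denoiser()` constructs a U-Net-shaped conditional noise predictor:
the noisy image enters the encoder; the one-hot label map conditions the
*decoder* through spatially-adaptive normalisation — instance-normalised
features are modulated as $h \cdot (1+\gamma(x)) + \beta(x)$ where
$\gamma,\beta$ are convolutions of the label map at each resolution; the
timestep enters every residual block as a per-channel bias projected from a
sinusoidal embedding. The head emits the noise estimate and the variance
coefficient. Residual-branch output convolutions, SPADE modulations and the
head are zero-initialised so the untrained network is near-identity; this
initialisation was decisive for stable toy-scale training.

There is no R deep-learning framework in the package's dependency set, by
design: the networks run on a compact reverse-mode autodiff engine written
for this package — a tape of array operations (3×3 same-padding
convolutions via Armadillo im2col+GEMM, factor-2 pooling/upsampling,
instance norm, dense layers, pointwise nonlinearities) with hand-derived
backward passes, verified against finite differences in the test suite, and
Adam with bias correction. Attention layers are not implemented; the config
field that would place them must stay empty. This bounds the architecture
space but is sufficient for the conditioning mechanism that defines the
model, and keeps every gradient auditable.

"Annealing learning rate" is realised as linear decay to zero over the
configured steps — the simplest schedule consistent with the phrase. One
model is trained per view (2C and 4C), on ED frames, via a dataset filter
rather than hard-coding.

## 3. The phantom generator

`make_phantom_dataset()` emulates the *structure* of a clinical
echocardiography segmentation dataset: per case, four frames (2C/4C views ×
ED/ES phases) of a cone-shaped ultrasound sector containing an elliptical
LV cavity, a myocardial ring of prescribed thickness, and an elliptical left
atrium; class codes are background 0, LV endocardium 1, myocardium 2, LA 3,
sector 4, mutually exclusive per pixel (one-hot expansion happens at the
model boundary). ES frames scale the LV cavity axes by a systolic factor
(default 0.7 — any value that makes ES strictly smaller than ED exercises
the pairing; 0.7 is a plausible linear-dimension contraction). Geometry is
jittered per case; ED and ES share the jitter so contraction is guaranteed.

Rendering assigns each class a mean intensity in $[0,1]$ (blood pools dark,
myocardium bright), multiplies by unit-mean gamma-distributed speckle with
spread `speckle_scale` (speckle is multiplicative in ultrasound; the gamma
family is a convenient positive unit-mean choice — the exact family is a
profile option, not a claim about tissue physics), blurs, clips, and zeroes
everything outside the sector. Coordinates are 0-based, row-major,
origin top-left throughout.

What the phantom does *not* emulate: beamforming, point-spread-function
anisotropy, attenuation and shadowing, valve/papillary structures, real
intensity statistics. Tests passing on phantoms therefore demonstrate that
the pipeline's machinery works — conditioning drives content, datasets have
the right shape, segmentation learns the label→intensity relation — not
that the models reach clinical-image fidelity. Full-scale results on real
data require real data and GPU-scale training, which are out of scope here.

## 4. Augmentation and dataset construction

`random_affine_elastic()` composes one affine draw — rotation
$U(-5^\circ,5^\circ)$, translation magnitude $U(0,0.05)\cdot S$ with a
random sign per axis (the sign convention is not dictated by the parameter
pair, so the package makes the symmetric choice), isotropic scale
$U(0.8,1.05)$, shear $U(-5^\circ,5^\circ)$, about the image centre — with
one elastic field. The elastic parameters follow the 3D-volume convention
of (out-of-plane, row, col) triples applied to a single-slice 2D image:
control points $(10,10,4)$ give an in-plane $10\times10$ coefficient grid
(the third component is unused in 2D), max displacement $(0,30,30)$ bounds
the in-plane components with the first, out-of-plane component inert.

Two numerical choices matter here. First, the control values are cubic
B-spline *coefficients* on a free-form-deformation lattice (mesh spacing
$S/(g-3)$), not interpolation knots: interpolating splines overshoot
between independently drawn control values, producing local area changes
far beyond what the parameters suggest, while the B-spline convex
combination keeps the field within the coefficient bound and smooth. With
coefficients drawn $U(-d/2, d/2)$ — `max_displacement` read as a
peak-to-peak bound, the convention of the mesh-based deformation libraries
this parameterisation comes from — anatomy-class areas over random draws
stay within the scale-range-implied bounds with the expected slack, which
the test suite checks by Monte Carlo. Second, the displacement bound is
interpreted at a 256-px reference resolution and scaled with image size, so
toy-sized maps deform proportionally rather than being destroyed.

Label maps are always resampled nearest-neighbour (no new class values can
appear), out-of-bounds pixels become background, and each draw's rng stream
is keyed by (seed, source id, draw index), making dataset construction
order-independent and reproducible. `build_synthetic_datasets()` then pairs
every augmented map with an image sampled from the view's trained denoiser
(the same model serves ED and ES of a view) and records full provenance in
the manifest; with 400 + 50 sources and 5 transforms per map this yields
2000 + 250 entries per view/phase dataset, and the fifth dataset is their
plain concatenation.

`add_sector_label()` reproduces the sector-class operation on real data:
pixels brighter than a threshold that carry no anatomy label become sector;
anatomy is never overwritten.

## 5. Segmentation and evaluation

`seg_config()` describes the U-Net: encoder depth `n_layers` (default 8)
with $2^L$ channels at layer $L$, capped by `max_channels` so desk-scale
instantiations stay tractable; Adam at lr $10^{-3}$, $\beta_1=0.9$,
$\beta_2=0.999$; 300 epochs at full scale. The segmentation loss is not
dictated by the architecture description, so the package defaults to
cross-entropy plus soft Dice — the standard pairing for multi-class medical
segmentation with small structures — with plain cross-entropy as a config
option; the choice is visible in the config and hence auditable. The best-
validation-loss weights are retained.

Scoring is 2D Dice per case and label with mean ± sd summaries. Two
conventions are recorded in the report metadata because they are genuinely
underdetermined: (1) the epicardium score is computed on the union of
cavity and myocardium masks (the epicardial contour encloses both; the
alternative — the ring alone — is available as `lv_myo`); (2) when both
masks are empty the score is 1.0, flagged per row. The sector class is a
training target but excluded from the headline summary, which reports LV
endocardium, LV epicardium and LA. Every fitted segmenter carries the
md5 hash of its training manifest, and evaluation refuses test sets whose
case ids overlap the training manifest — the synthetic-trained/real-tested
claim structure enforced at the engineering level.

## 6. Pipeline, determinism and problem sizes

`run_pipeline()` executes phantom generation → per-view diffusion training
→ augmented dataset construction → segmentation training → held-out
evaluation, with per-stage artifact directories carrying the config hash;
re-running an identical config skips completed stages. The "real data"
test stage is held-out phantom cases by default; a user with clinical
MetaImage data can mount it through the format adapters.

All stochastic operations take explicit seeds derived from the global seed;
no hidden RNG state is used, and two runs from one seed produce
byte-identical manifests and Dice rows (tested).

The shipped problem sizes were chosen as the package's study conditions:
the toy profile uses 8 cases at 24 px, $T=12$, 300 diffusion steps and a
depth-3 U-Net — enough for an end-to-end smoke run in well under a minute;
the conditioning-recovery study uses 16-px phantoms with flat per-class
intensities, $T=100$ and 2000 steps, where held-out per-class mean
intensities land within 0.15 of target; the segmentation study uses 200
pairs at 64 px with a depth-3, (16, 32, 64)-channel U-Net for 3 epochs,
reaching mean anatomy Dice above 0.9 on 50 held-out phantoms. The paper
profile (256 px, $T=1000$, 50,000 steps, batch 12, depth-8 U-Net, 300
epochs) is expressible and exportable but not something to run on a
desktop CPU.

## 7. Known limitations

- The autodiff engine supports exactly the operations these networks need;
  no attention, no strided convolutions, no mixed precision.
- The phantom's geometry is convex-elliptical; it cannot probe robustness
  to the irregular shapes real ventricles take (the augmenter's API accepts
  user-edited maps for that purpose).
- Checkpoints are R serialisations, not a cross-language format.
- The guidance scale used before guidance was disabled is not specified by
  the configuration it mirrors; `guidance_setting()` defaults to 0.
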