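---
title: "Estimating surgical hemoglobin loss from sponge images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating surgical hemoglobin loss from sponge images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbloss)
```

## The problem

Intraoperative blood loss is still mostly estimated by eye, which is known
to be unreliable, or gravimetrically (weighing sponges), which is slow and
confounded by irrigation fluids. An attractive alternative is to photograph
each blood-soaked sponge and estimate the *hemoglobin mass* it carries
directly from the image: stain colour encodes Hb surface density and stain
extent encodes absorbed volume. `hbloss` implements that estimation pipeline
end to end — synthetic data generation with exact ground truth, sponge
detection, feature extraction, two predictor families (a four-feature
linear model and residual CNN regressors with optional squeeze-and-excitation
attention), and agreement-based evaluation.

The quantity of interest is the Hb mass per sponge in milligrams. It follows
from unit arithmetic: a sample of concentration $c$ (g/L) and absorbed volume
$v$ (mL) carries $m = c \cdot v$ mg of hemoglobin, since 1 g/L = 1 mg/mL.
The generator draws $c$ uniformly from the clinically relevant 50–170 g/L
band of whole-blood dilutions.

## The synthetic scene model

No public image set with per-sponge Hb ground truth exists, so every
downstream stage is exercised on a simulator whose truth is exact by
construction (`render_sponge_image()`, `simulate_sponges()`,
`generate_dataset()`). One render consists of:

* a teal background and an axis-aligned sponge region filled with an
  off-white gauze colour, modulated by a low-frequency multiplicative
  texture (amplitude 3% by default);
* an irregular stain footprint (a radial blob with random Fourier-perturbed
  boundary) whose pixel area is proportional to the applied volume —
  `spread_frac_per_ml` (default 0.25 of the sponge area per mL) models a
  constant absorbency per unit area; footprints that would overflow the
  sponge are clipped to it;
* Beer–Lambert-style per-channel attenuation of stained pixels,
  $I_{ch} \mapsto I_{ch}\,e^{-k_{ch}\, d}$, where
  $d$ is the Hb surface density in mg/cm² (mass divided by the physical
  stain area; the sponge box represents `sponge_area_cm2`, 100 cm² by
  default, making stain colour independent of image resolution) and
  $k = (0.06, 0.33, 0.36)$ cm²/mg for (R, G, B). Red absorbs least, so
  stains look red-brown and, critically, darkness increases *monotonically*
  with density;
* a radial depth profile: blood pools deeper toward the stain centre and
  wicks outward into a fixed-width lighter rim
  (`stain_edge_frac`, default 4% of the sponge's smaller dimension, with a
  35% depth floor at the boundary, renormalised so the mean depth is 1 and
  the total Hb mass is conserved). Small stains are proportionally
  fringier than large ones — this is what real wicking does, and it gives
  the colour-dispersion features a stain-size-dependent component;
* additive Gaussian pixel noise (SD 0.008 on the unit scale) and 8-bit
  quantisation.

Because area is proportional to volume, density — and hence stain colour —
is a function of concentration alone, while the stain's area ratio carries
the volume. The four extracted features therefore jointly determine
$(c, v)$, which is what makes the mass learnable.

**What the simulator does not model:** non-sanguineous contaminants
(saline, ascites), specular highlights, folded or crumpled sponges, camera
pose and illumination variation, and colour calibration drift. Passing
tests on this simulator therefore demonstrate the correctness of the
algorithms and the internal consistency of the pipeline, not clinical-grade
accuracy on real photographs.

### Why volumes default to 1.0–2.0 mL

Applied volumes per sponge are not publicly documented for this kind of
bench experiment, so the default is a design choice. Two considerations
fix it. First, masses should sit on the tens-to-hundreds of mg scale at
which the method is discussed (1.0–2.0 mL at 50–170 g/L spans 50–340 mg).
Second, the simulator is built so that the feature-to-mass map is *near
linear*: the mass $c\cdot v$ is a product, and for any features that
separate into functions of $c$ and functions of $v$ the best additive fit
leaves the interaction variance
$\sigma_c^2\sigma_v^2 / (\mu_v^2\sigma_c^2 + \mu_c^2\sigma_v^2 +
\sigma_c^2\sigma_v^2)$ unexplained. With $c$ fixed to the clinical
50–170 g/L band ($\sigma_c/\mu_c \approx 0.32$), a wide volume spread such
as 0.2–3.0 mL caps the linear model's achievable $R^2$ near 0.93
regardless of how good the features are, while $v \in [1, 2]$ mL
($\sigma_v/\mu_v \approx 0.19$) raises the ceiling to about 0.97. A
pipetted bench protocol with 1–2 mL aliquots is also the physically
plausible reading. The ranges remain ordinary arguments, so any other
regime can be simulated explicitly.

## Sponge detection

The learned object detector used on real photographs is deliberately *not*
retrained here: on synthetic scenes a deterministic colour-distance
detector is exact, testable, and fills the same contract (one in-frame box
per image). `detect_sponge_region()` marks pixels whose RGB distance to
the background colour exceeds 30/255, removes connected components smaller
than 0.1% of the frame (via `EBImage::bwlabel`), and returns the tightest
box around the remainder. Any detector honouring the contract can be
substituted in front of the predictors. Boxes are 0-based and half-open
everywhere in the package; PASCAL-VOC XML (1-based, inclusive) is
converted exactly at the I/O boundary (`read_annotation()` /
`write_annotation()`).

## Features and the linear model

`extract_features()` produces the four predictors of the colour-feature
regression:

* **x1 (MEA)** — mean intensity of blood pixels, averaged over channels;
* **x2 (VAR)** — root-mean-square deviation (population divisor), likewise;
* **x3 (SKE)** — signed cube root of the mean cubed deviation, likewise;
* **x4** — area ratio of blood pixels to the sponge crop.

Blood pixels come from `segment_blood()`: colour distance from the clean
gauze colour above 30/255 *and* red channel dominant — the red-dominance
test separates dark red stains from shadows and background remnants. Two
conventions had to be fixed because colour-moment features admit variants:
moments use population normalisation with VAR as an RMS deviation (not a
squared variance), so all three moments share the intensity unit and scale
equivariantly; and moments are computed over blood pixels only, averaged
across channels, which is the minimal reading that yields exactly four
scalar predictors. When no pixel is classified as blood, moments fall back
to the whole crop with x4 = 0, so clean sponges predict near 0 mg instead
of failing. Intensities are normalised to [0, 1] first.

`fit_hb_linear()` is ordinary least squares via `stats::lm()` — plain
linear regression, no regularisation — requiring at least 5 observations
and a full-rank design. Negative linear predictions are physically
impossible masses; they are clamped to 0 only at the reporting layer
(`clamp = TRUE`), while raw predictions feed the evaluation metrics so that
agreement statistics describe the actual fitted model.

## The CNN regressors

`build_regressor()` constructs a residual network ending in global average
pooling and a single linear output unit. Two kinds: `resnet` (plain
residual blocks) and `se_resnet`, which inserts a squeeze-and-excitation
block after the last convolution of each residual block, before the
residual addition — squeeze pools each channel to a scalar, excitation
passes the vector through a bottleneck of width $C/r$ (reduction $r = 8$,
i.e. compression 1/8) with ReLU, maps back to $C$ and applies logistic
gates in $(0,1)$ that rescale the channels.

Two variants share the design. The `full` variant is the standard 50-layer
bottleneck layout (stem 7×7/2 + max-pool, stages of 3/4/6/3 bottleneck
blocks, 224×224×3 input); it is constructed and shape-verified but not
trained in the test suite — at roughly 28.6M parameters it exists so that
the architecture, SE placement and reduction arithmetic are real, not
notional. The `tiny` variant (stem 3×3/2, three basic-block
stages at 16/32/64 channels, 64×64 input, ≈79k parameters) is the working
model for CPU-scale experiments; its defaults (30 epochs) train in a few
minutes on one core.

Training (`train_hb_cnn()`) follows the recipe of the full-size networks:
batch size 16, Adam with initial learning rate $10^{-3}$, and the
composite loss $\mathrm{MSE} + \lambda\,\mathrm{L1}$ on predictions versus
true masses. The combination weight is not documented for the original
recipe; $\lambda = 1$ (an equally weighted sum) is the default and is
configurable. Two further numerical choices: targets are divided by
`target_scale` (500 mg) during optimisation so the regression head starts
on a unit scale, and the learning rate follows a cosine schedule from the
initial rate to zero across the run (`lr_decay = "cosine"`), which removes
the late-training oscillation a constant-rate Adam shows at these tiny
batch counts; `"constant"` restores the fixed rate. Weight initialisation
is He-normal; batch normalisation uses momentum 0.1 running statistics,
which inference mode consumes. Everything is seeded: rebuilding and
retraining with the same configuration reproduces the loss history
bit for bit. The networks are implemented in base R (BLAS-backed
im2col/col2im convolutions), and every layer's backward pass is verified
against finite differences in the test suite.

## Evaluation

`mae()`, `mape()` and `r2()` implement the standard definitions
($\mathrm{MAPE}$ guards against zero actual values; $R^2$ is the
determination coefficient $1 - \mathrm{RSS}/\mathrm{TSS}$, not a squared
correlation, and may be negative). `bland_altman()` analyses the paired
differences $d_i = \hat y_i - y_i$: bias $= \bar d$, limits of agreement
$\bar d \pm 1.96\,s_d$ (sample SD, divisor $n-1$), so the limits are
exactly symmetric about the bias. A percentile mode
(`loa_mode = "percentile"`) takes the empirical 2.5th/97.5th percentiles
instead, for distribution-free limits; for normal differences the two
converge, which the tests check by simulation.

Confidence intervals come in two dialects. Published agreement tables in
this application area often print one common half-width for the bias and
both limits — consistent with $1.96\,s_d/\sqrt n$ applied to all three —
whereas the classical large-sample result inflates the LOA half-width by
$\sqrt 3$. The default (`ci_mode = "pooled"`) reproduces the former,
internally consistent with such tables; `"textbook"` gives the classical
intervals. `ba_mirror_limit()` exposes the symmetry identity
$\mathrm{LOA}_{lower} = 2\,\mathrm{bias} - \mathrm{LOA}_{upper}$, useful
for checking reported tables that print rounded values.

`compare_models()` tabulates pairwise improvements (drop in MAE and MAPE,
rise in $R^2$) for every ordered pair of evaluated models.

## The experiment driver

`run_experiment()` wires the stages together: simulate → 7:3 split
(training size is `floor(0.7 n)`, so 851 records give exactly 595/256) →
fit each requested model on the training group → evaluate on the testing
group → write per-image predictions, performance and agreement tables and
a JSON summary, all byte-reproducible under a fixed seed. `kfold_cv()`
performs balanced k-fold cross-validation (fold sizes differ by at most
one; 595 records give five folds of 119). `predict_batch()` mirrors the
interactive use case: a stack of photographs in, per-image clamped
predictions and a running total out, with unreadable files skipped and
listed. A thin command-line driver over these functions ships in
`inst/cli/hbloss.R` with subcommands `simulate`, `split`, `train`,
`evaluate`, `crossval`, `predict` and `predict-batch`; YAML configs are
read by `read_experiment_config()`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen for a single CPU core: renders at 48–128 px for unit tests,
detector fidelity at the full default 512×512 scene over 50 images, the
linear pipeline at 100–200 images, and the CNN surrogate at 500 images of
64×64 (400 train / 100 held out, tiny variant, 30 epochs). The full
50-layer variant is forward-pass tested at 224×224. These sizes are the
package's defaults for its own verification, not limits of the
implementation.

## Known limitations

* The dispersion features x2/x3 are sensitive to image resolution (the
  wicking rim and texture occupy different pixel fractions at different
  scales), so a linear model should be applied to images from the same
  camera geometry it was fitted on. The CNN resizes crops to a fixed input
  size, which removes most but not all of this sensitivity.
* The simulator's clean geometry (one rectangular sponge, axis-aligned,
  uniform illumination) makes detection essentially exact; real-world
  detection robustness is out of scope, by design of the pluggable
  detector contract.
* MAPE is dominated by small masses; with masses bounded away from zero by
  the volume default this is benign, but user-supplied volume ranges that
  include near-zero masses will inflate MAPE and can make it undefined at
  exactly zero (the implementation then raises an error naming the index).
* The pure-R CNN is fast enough for the tiny variant but not intended for
  1000-epoch full-scale training; the full variant is provided for
  architectural fidelity and forward use.
* Percentile-mode Bland–Altman quotes the same CI half-widths as the
  parametric mode, an approximation; exact nonparametric CIs for extreme
  percentiles need order-statistics methods out of scope here.
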