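---
title: "Stress-testing visual recognition with SSNR-controlled noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing visual recognition with SSNR-controlled noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

How robust is object recognition -- in humans, in convolutional networks, in
visual cortex -- when the image is progressively buried in noise?  The
package implements a complete desk-scale pipeline for that question: noise
stimuli whose signal content is controlled by a single interpretable
parameter, a training protocol that confers noise robustness on a network, a
psychometric analysis that turns accuracy curves into thresholds, layer-wise
diagnostics of where noise disrupts a network, relevance-based maps of which
pixels drive its decisions, and representational analyses of (simulated)
multivoxel response patterns.

# Stimuli: the SSNR blend

Every stimulus is a pixel-wise convex combination of a source image `S` and
a noise field `N`:

    T = w * S + (1 - w) * N,    w in [0, 1]

`w` is the *signal-to-signal-plus-noise ratio* (SSNR): 0 is pure noise, 1 the
clean image.  Unlike conventional SNR it is bounded, which makes thresholds
directly comparable across observers and models.  Two noise families are
provided:

* **Pixelated Gaussian noise** (`make_gaussian_noise()`): each pixel is an
  independent draw from Normal(127.5, 255/6), so the 0--255 intensity range
  spans six standard deviations.  Fields are generated *unclipped*; clipping
  to [0, 255] is applied once, after blending (`blend_ssnr()`).  Clipping
  before blending would bias the noise mean and variance; applied after the
  sum it only trims the modest tails.
* **Fourier phase-scrambled noise** (`make_phase_scrambled_noise()`): a
  target amplitude spectrum (typically `mean_amplitude_spectrum()` of an
  image set, which is approximately 1/f for natural-looking images) is
  combined with random phases drawn uniformly on (-pi, pi] under Hermitian
  symmetry, so the inverse transform is exactly real.  The result is
  spatially correlated, cloud-like noise with no coherent edges.

Numerical conventions for the phase scramble, chosen where the procedure is
otherwise underdetermined: the DC phase is fixed at 0 (preserving the sign
of the mean), Nyquist bins receive phase 0 or pi only (they must stay real),
and the real part is shifted to mean 127.5 with *no* variance rescaling --
the contrast of the field is carried entirely by the supplied spectrum.
With that mapping, the off-DC Fourier magnitudes of the output equal the
input spectrum exactly, which the tests assert.

Two presentation regimes are supported: fresh noise per presentation (the
fixed-level design) and a single frozen field across an ascending series
(`ssnr_series()`, default step 0.025, i.e. 41 frames from 0 to 1), matching
the stop-when-confident design.

A useful closed form anchors the analysis code: for zero-mean, equal
variance, independent `S` and `N` on unclipped blends, the correlation
between `T` and `S` is `r(w) = w / sqrt(w^2 + (1 - w)^2)`, which crosses 0.5
at `w = 1/(1 + sqrt(3)) ~ 0.366`.  The test suite and the acceptance script
drive the full susceptibility machinery over an identity "layer" and check
it recovers this number.

# The compact network and the noise-training protocol

The network (`small_cnn()`) is a deliberately small stand-in for large
feedforward vision models that preserves their layer taxonomy --
convolution + rectification blocks with early max pooling, fully connected
layers, a softmax output -- while training in minutes on one CPU.  The
engine (forward, backprop, momentum SGD) is implemented directly on base R
matrix algebra via im2col/GEMM, because every analysis in the package needs
raw access to weights, pre-activations and pooling winners; the transposed
convolution used in backprop and relevance propagation is computed as a
same-convolution with the 180-degree-rotated kernel and is verified against
an explicit scatter-add implementation in the tests.

Defaults: 4 blocks with 3x3 kernels and channels (8, 16, 16, 32), canvas
64 px, one rectified fully connected layer of 64 units.  Inputs are
standardized as `(x - input_mean)/127.5`, where `input_mean` is estimated
once from a pre-pass over the training stream and then frozen -- the
mean-subtraction constant is part of the model, not of the data.

Training (`train_model()`) follows the standard recipe for this protocol:
stochastic gradient descent on the multinomial logistic loss, 20 epochs,
fixed learning rate 0.001, batch size 24, weight decay 0.0005, momentum
0.9.  The clean/noisy composition of the stream is a `noise_mix()`: each
sample of each minibatch *independently* draws its condition (per-sample
stochastic mixing, rather than epoch interleaving), and noisy conditions
draw their SSNR uniformly from the configured range -- the within-range
distribution is not otherwise constrained, and uniform is the least
committed choice.  The canonical noise-training mix is half clean images,
half Gaussian noise at SSNR 0.2--0.99.  Augmentation crops a region
subtending 87.5% of the image's linear extent at an aspect ratio uniform in
[2/3, 3/2], resizes back to the canvas, and adds a per-image intensity
offset from Normal(0, 3); SSNR blending happens after augmentation.

# Psychometrics

Accuracy-by-SSNR curves are summarized by a 4-parameter logistic

    f(w) = L + (U - L) / (1 + exp(-k (w - m)))

fitted by nonlinear least squares on the accuracies (`fit_logistic4()`,
Levenberg-Marquardt, one heuristic start plus five random restarts under a
fixed restart seed, best residual wins).  Both asymptotes are free, but the
lower asymptote is bounded to `[0, 1/K + 0.2]` when the guessing floor `1/K`
is known, which prevents degenerate fits on shallow curves.  Fitting
accuracies rather than a binomial likelihood matches the curve-fitting
convention of this literature.  Thresholds (`threshold_at()`) invert the fit
analytically; a criterion outside `(L, U)`, or a crossing beyond SSNR 1, is
reported as invalid rather than extrapolated, and a crossing below 0 clamps
to 0.  Criteria in use: 50% accuracy for observer- and model-level curves,
90% for per-image model thresholds, correlation 0.5 for layer
susceptibility.

Per-image thresholds (`per_image_thresholds()`) present each object with
freshly drawn noise fields at each level (50 per level at full scale) and
apply two exclusion rules: images of the category the model is modally
biased toward under pure noise, and images whose fitted curve never reaches
the criterion by SSNR 1.  Observer-side thresholds in the ascending design
are averages of correct-trial stop levels, while model thresholds come from
curve fits -- the two designs measure the same quantity through different
estimators, so the package keeps both conventions.

Supporting statistics: row-stochastic confusion matrices
(`confusion_matrix()`), split-half reliability over random observer halves
(`split_half_reliability()`, 10,000 splits at full scale; the tests check
its mean against the Spearman-Brown closed form on synthetic observers),
the Fisher z comparison of two independent correlations
(`compare_correlations_fisher()`), and model-vs-human threshold regression
with human thresholds as predictor (`threshold_regression()`; the axis
convention is recorded because the published convention is ambiguous).

# Layer-wise analyses

`corr_susceptibility()` correlates each analyzed layer's response to a
clean image with its response to the same image in noise, per SSNR level,
averaged over images and noise draws (averaging r per level *before*
fitting; the alternative order is not distinguishable from the published
description).  If the correlation at SSNR 0 is still positive -- common in
early layers, where much of the response is stimulus-unspecific -- the
curve is linearly rescaled to span [0, 1] before the logistic fit, so the
threshold always refers to the informative part of the dynamic range.
`clf_susceptibility()` instead trains linear one-vs-one support-vector
classifiers (cost 1, the library default; features standardized by
clean-training statistics) on clean activations and tests them under noise.
Layers with more than 50,000 units are randomly subsampled under a fixed
seed before correlation or classification; Pearson correlation is
consistent under random coordinate subsampling, so this only adds sampling
noise.  `threshold_slope()` summarizes a profile by the OLS slope of
threshold against 1-based layer depth.

`weight_cca()` quantifies how much a layer's features changed between two
models.  Weights are reshaped to units x incoming-coordinates; CCA then
treats incoming coordinates as observations and units as variables, making
the measure invariant to any invertible mixing of one model's units (unit
permutation or rotation leaves it at 1) -- it compares the *subspaces*
spanned by the layer's kernels.  Covariance whitening uses a small ridge
(1e-6 of the mean diagonal) and truncates to the numerically positive
spectrum, flagging rank deficiency.  Caveat: layers whose kernel space is
very small (a 3x3 single-channel input convolution has only 9 coordinates)
saturate the measure; interpret those values as degenerate, not as
similarity.

# Relevance propagation

`lrp()` decomposes a network decision into pixel contributions by
propagating relevance backward, layer by layer, as `R_i = sum_j x_i w_ij /
z_j * R_j`.  The composite rule schedule (`lrp_schedule()`) assigns, by
fractional depth, z-beta to the input layer, the gamma rule (w + 0.05
max(w, 0)) to roughly the first 40% of remaining layers, the epsilon rule
(sign-matched stabilizer, 0.25) to the next 35%, and the basic rule to the
final 25%; for a 19-weight-layer network this reproduces the canonical
assignment exactly.  The published index range for the gamma rule
("second and eighth") is read as second *through* eighth, since otherwise
intermediate layers would carry no rule.  The z-beta bounds default to the
model's own standardized input range rather than any fixed constants, since
such bounds are meaningful only relative to a model's input normalization.

Conventions: biases enter the denominator but receive no relevance (so
conservation is exact only on bias-free networks, which the tests exploit);
relevance follows the pooling winner through max-pooling and passes
unchanged through rectification; negative pixel relevances are zeroed and
the map rescaled to [0, 1] only at the very end, which also makes maps
invariant to positive rescaling of the seeded relevance.  Model maps are
smoothed with a sigma = 3 px Gaussian before comparison with human maps
(painted with a 15 px pen, hence already thick), binarized at 0.2 (model)
vs 0.5 (human), and compared by spatial correlation and
intersection-over-union (`diagnostic_comparison()`, 50 bins of one image
per category).

# Neural analysis

`amplitudes_from_timeseries()` converts each voxel's series to percent
signal change relative to its run mean and averages TRs 3--5 post-onset
(1-based, onset inclusive); amplitudes are then z-normalized per run as a
whole (a scalar shift and scale, which preserves all pattern correlations).
Because event responses contribute to the run mean, percent signal change
carries a small per-voxel baseline offset in short runs; the dual-path test
accounts for this explicitly.  `decode_category()` runs leave-one-run-out
linear SVM decoding; training always uses held-in runs only, even when the
train and test conditions differ, which is the leakage-safe reading of
cross-condition decoding.  `qc_subject()` implements the inclusion rule
(mean accuracy over the three viewing conditions at least 20%, boundary
inclusive).  `build_rdm()`/`rsa_compare()` implement representational
similarity: pattern-correlation matrices compared over the upper triangle
(the full off-diagonal set adds only duplicates), Fisher-z transformed for
group statistics (`group_layer_profile()`, two-sided t tests at p < 0.01
uncorrected).

# What the synthetic generators emulate -- and what they do not

`generate_image_dataset()` draws K parametric shape families (blobs, bars,
rings, crosses, ...) with jittered pose, size, intensity and pixel texture.
They are linearly separable from raw pixels by design -- a sanity oracle
the tests assert -- which natural images are not; passing tests therefore
demonstrate that the *pipeline* behaves correctly and that the training
protocol's effects are directionally reproducible, not that any number
generalizes to photographs.

`observer_model()` fixes per-image true thresholds (Normal, default mean
0.3, SD 0.08, clamped to [0.05, 0.9]), a shared logistic slope (20 per SSNR
unit), lapse rate 0.02, guess rate 1/K, and a block-structured confusability
matrix (errors fall preferentially within one of two superordinate clusters,
default 75% of error mass, emulating the higher mutual confusability of
related categories).  The ascending design needs a stopping rule the
human experiments did not specify (participants chose when to stop); the
generator stops when internal detectability crosses the per-image threshold
plus Gaussian decision noise (SD 0.05 SSNR), the simplest rule that makes
stop levels threshold-correlated, quantized upward to the 0.025 grid.
These choices give the recovery tests known ground truth.

`simulate_voxel_patterns()` models voxels as a fixed random linear readout
of a chosen layer's features plus run-specific unit-variance noise, scaled
by an `snr` parameter; standardization of the readout is deliberately
global (a scalar), since per-feature or per-voxel z-scoring would distort
the stimulus correlation structure the readout is supposed to carry.  Runs
contain every stimulus exactly once in randomized order.  Real fMRI
hemodynamics, autocorrelated noise, and voxel selection are out of scope.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the full design at desk
scale, a deliberate configuration of the package rather than a limitation
of the method: 4 categories, 50 training + 10 test images per category on a
64 px canvas, 20 training epochs, 2--3 noise resamples per evaluation
point, 20 levels for accuracy curves and 11 for layer profiles, 20-image
subsets for susceptibility, 16 stimuli x 6 runs x 200 voxels for the
representational analyses.  At this scale the large directional findings
-- lower SSNR thresholds after noise training, clean-accuracy loss under
single-low-SSNR training, flatter (more negative) threshold-by-depth
slopes after noise training, and a standard-vs-noise-trained gap
concentrated in deep layers -- reproduce robustly across seeds; the
clean-accuracy *protection* by mixed clean+noisy training is a smaller
contrast and, on a 40-image test set, sits within binomial sampling error
for some seeds.  Absolute numbers (e.g. the exact thresholds) are
properties of the synthetic shapes and the small network and are not
comparable to results on natural images with 19-layer networks.

Other numerical details worth knowing: logistic fits use tolerance 1e-10
with bounded parameters; susceptibility curves at SSNR 1 equal the clean
condition exactly by construction; zero denominators in relevance
propagation contribute zero relevance; degenerate inputs (constant curves,
constant activation layers, zero-variance runs, empty confusion rows,
all-zero relevance maps) are flagged rather than raised as errors wherever
an experiment sweep could plausibly produce them.

# Known limitations

* The CNN engine is single-threaded base R: adequate for the shipped
  problem sizes, far from GPU-scale training; full-size 19-layer networks
  are not trainable with it (the analyses accept any model exposing the
  same layer interface).
* Adjacent early layers of a small network can have nearly identical
  representational similarity matrices, so RSA layer recovery is only
  meaningful for layers whose geometry actually differs (the tests use a
  deep layer).
* Weight CCA saturates on layers with tiny kernel spaces (see above).
* Classification-based readout accuracy improves reliably across the
  convolutional hierarchy, but the narrow fully connected stage and the
  K-dimensional softmax of the small network can compress information and
  dip slightly below the best convolutional readout; in full-scale networks
  with wide fully connected layers this effect is negligible.
* The observer simulator's stopping rule and confusability structure are
  plausible but invented; recovery tests validate the analysis code against
  the generator's ground truth, not against human behavior.
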