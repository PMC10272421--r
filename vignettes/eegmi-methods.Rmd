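---
title: "Subject-independent motor-imagery decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-independent motor-imagery decoding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A motor-imagery (MI) brain-computer interface decodes which movement a
user imagines from multi-channel EEG. Classifiers trained on one group of
subjects transfer poorly to a new subject, because spatial patterns and
rhythm amplitudes differ across heads; collecting a large calibration set
from every new user is impractical, particularly for stroke patients. This
package implements a calibration-light pipeline for the four-class MI
setting (left hand, right hand, feet, tongue; 22 channels at 250 Hz, 4-s
trials): a filter-bank common-spatial-pattern front end with LASSO
sparsification, an adversarial generator that synthesises additional
trials for the target subject, and a convolutional recurrent classifier
trained with a center-distance loss, all evaluated leave-one-subject-out
(LOSO).

## Preprocessing

Raw recordings are cleaned (`clean_nans()`: missing samples replaced by
the channel mean — per channel, because channels have different offsets
and scales), bandpassed 1–38 Hz with a 5th-order Butterworth filter, and
z-scored per channel against statistics computed on the *training* split
only. Two details are deliberate choices:

* **Standardization divisor.** The normalization is a z-score, so we
  divide by the standard deviation; `standardize(divisor = "var")` exposes
  the literal variance denominator for comparison.
* **Zero-phase filtering.** Offline MI analysis conventionally applies the
  Butterworth filter forward–backward (`signal::filtfilt`), doubling the
  effective order and removing phase distortion. A causal single pass is
  available via `zero_phase = FALSE`.

Epochs are 4-s slices from each cue onset (1000 samples at 250 Hz). The
filter bank splits 1–38 Hz into ten bands (1–4, 4–8, …, 32–35, 35–38 Hz).
`filter_bank()` supports two equivalent implementations: digital
`filtfilt` per band (default for data preparation) and a Fourier-domain
operator that multiplies the spectrum by the Butterworth magnitude-squared
response. The Fourier operator is linear and self-adjoint, which is what
allows gradients to flow through the band filters during adversarial
training; it is applied identically to real and generated trials inside
the GAN so the discriminator cannot key on filtering artifacts.

## Filter-bank OVR-CSP and the sparse spatial filter

For each band and each class $c$, the trace-normalized mean covariance
$R_c = \frac{1}{N_c}\sum_i X_i X_i^{\top} / \mathrm{tr}(X_i X_i^{\top})$
enters the one-versus-rest generalized eigenproblem
$R_c w = \lambda R_{\bar c} w$, solved by Cholesky whitening of
$R_{\bar c}$ (with a relative ridge of $10^{-8}\,\mathrm{tr}$ for rank
safety). The top $m = 4$ eigenvectors per sub-filter give
$4 \times 4 = 16$ columns per band and $160$ columns over ten bands.
Features are the standard log-normalized projected variances
$f_{ij} = \log( \mathrm{var}(w_j^\top X_i) / \sum_{j'} \mathrm{var}(w_{j'}^\top X_i))$,
with the sum over the $m$ columns of the same sub-filter; the source
text leaves the feature functional implicit and this is the universal CSP
choice (scale-invariant, and the one the trace normalization anticipates).

A single numeric-response LASSO
$\tfrac{1}{2N}\sum_i (y_i - \beta_0 - f_i^\top\beta)^2 + \lambda\|\beta\|_1$
selects columns; features are centered and unit-scaled first because L1
penalties are scale-sensitive. Treating the four class labels as one
numeric response is the literal published formulation and is the default;
a one-versus-rest variant (`multiclass = "ovr"`, union of supports) is
available because the ordinal reading is statistically odd. $\lambda$
defaults to 5-fold cross-validation on prediction error over a log grid;
a fixed value is accepted. The surviving columns, with their (band,
class, eigenvector) provenance, form the sparse spatial filter
$W_{\mathrm{csp}}$; `apply_sparse_filter()` projects a trial as
$Z = W_{\mathrm{csp}}^\top X'$ where each column multiplies the trial
filtered *in that column's own band* — the columns are only meaningful
there, and the row order follows the selection order.

## The dual-discriminator GAN

One unconditional generator is trained per (subject, class). The
generator maps a 1600-dimensional Gaussian noise vector through a fully
connected layer (256,000 units) and five transposed convolutions (batch
normalization on the first four, leaky-rectifier slope 0.2) to a
22 × 1000 trial. The published layer table fixes the endpoints, channel
counts, kernels and strides but not the reshape lattice or paddings; the
kernel/stride pairs close arithmetically only when read along (time,
electrode) axes — consistent with the time × channels trial notation used
for the raw data — giving the reshape (128 maps, 4 electrodes, 500 time
samples) and per-layer paddings (electrode: 11, 4, 2, 1, 0; time: 2, 1,
0, 1, 0). The resulting trace,
`(128,4,500) → (128,2,498) → (128,10,498) → (64,19,500) → (32,21,1000) → (1,22,1000)`,
is unit-tested. The discriminator table, by contrast, closes only in the
(electrode, time) orientation (a 1 × 23 temporal kernel followed by a
22 × 1 spatial kernel), and its fourth convolution must have stride 1 —
not the printed (1, 7) — for the documented 750-unit head to be reachable;
the analogous row of the second discriminator confirms stride 1. Each
table is therefore read in the orientation whose arithmetic is
consistent.

Two discriminators score a batch: $D_\varphi$ sees raw trials, $D_\psi$
sees the sparsely filtered trials $Z$ (rows equal to the LASSO support
size $n_{\mathrm{sel}}$; its third convolution's kernel height
$\mathrm{Var} = \lfloor n_{\mathrm{sel}}/4 \rfloor$ collapses the rows
that remain after the stride-(4,1) reduction). Losses are standard
non-saturating binary cross-entropies; the discriminator objective is the
sum over both discriminators and the generator objective weights them
equally by default (`disc_weights`), as nothing in the source fixes a
weighting. Adam uses the reference learning rate $10^{-4}$ and batch
size 5; betas (0.5, 0.999), slope 0.2 and a 1:1 update ratio are package
choices exposed in `gan_config()`.

The full-size generator holds ~4.1 × 10⁸ parameters, so training
demonstrations in the test suite use a scaled geometry (8 channels, 256
samples, 64-d noise) built by the same constructor; the scaled runs use
150 epochs at a step size of 3 × 10⁻⁴, larger than the reference rate
because the scaled model is three orders of magnitude smaller and its
loss surface correspondingly better conditioned. The number of training
epochs is nowhere stated in the source and is config-exposed
(`n_epochs`, default 100).

Generated-data quality is assessed as in the reference analysis
(`quality_report()`): class-average time traces of C3/Cz/C4, the
spectrogram of the channel-averaged signal in dB, and trial-averaged
channel covariance matrices normalized to unit diagonal, summarized by
the Pearson correlation of their upper triangles.

## The classifier and the discriminative-feature loss

`build_crnn()` assembles: a spatial convolution with kernel $C \times 45$
(stride 1) spanning all electrodes, rectifier activation, a $1 \times 75$
max-pool with stride 10, dropout 0.5, and a two-layer LSTM with hidden
state 64 and dropout 0.5 between layers. At 22 × 1000 the sequence
entering the LSTM has length $\lfloor(956 - 75)/10\rfloor + 1 = 89$. The
convolution filter count is unreadable in the source figure; 64 is the
default (matching the LSTM width) and is config-exposed. The final hidden
state is the 64-d feature vector $v$; a linear head maps it to four
logits.

Training minimizes cross-entropy plus $\lambda_c L_{\mathrm{cen}}$ with
$L_{\mathrm{cen}} = \frac{1}{b}\sum_i \|v_i - \mathrm{cen}_{y_i}\|^2$
(squared Euclidean — the convention of the center-loss literature, and
differentiable at zero). $\lambda_c = 0.1$ by default, the value the
reference sweep selects; $\lambda_c = 0$ recovers the plain classifier.
Centers are initialized before training as
$\mathrm{cen}_j = \sum_i [y_i = j] v_i / (1 + \sum_i [y_i = j])$ — the
printed formula with its "+1" denominator, implemented exactly as printed
(a shrunken mean); `shrink = FALSE` gives the plain mean, since the +1 may
well be a typo. Every 15 epochs the centers are (a) re-estimated from the
current features — they must track the drifting feature space for the
distance loss to stay meaningful, which the source leaves unstated — and
(b) pushed a step $\alpha = 0.02$ along the unit ray from the global mean
of the centers toward themselves; a center sitting exactly on the global
mean does not move (zero-direction convention). During gradient descent
the centers are treated as constants; they change only on the 15-epoch
schedule. The optimizer is Adam at $10^{-4}$, batch 32 (reference
values), betas (0.9, 0.999) (package choice).

The printed joint loss transposes the roles of the true and predicted
labels inside the cross-entropy; it is implemented as the standard
cross-entropy of predictions against true labels.

## Evaluation protocol

`loso_split()` pools all trials of all non-target subjects (both
sessions) as the training set — 4608 trials in the 9-subject reference
geometry — and keeps the target's 576 trials untouched for testing, with
a seeded shuffle. `augment()` appends `n_aug/4` generated trials per
class (flagged synthetic, carrying the target's id) to the training set
only; an audit asserts that no real target-subject trial ever enters
training and that synthetic trials never impersonate other subjects.
Accuracy is percent correct; sweeps over `lambda_center` or `n_aug`
report per-subject accuracies with the arithmetic mean and population
standard deviation, matching the mean ± std presentation of the reference
tables. Per-class confusion matrices are retained as an extra diagnostic.

Which portion of the target subject's data trains the GAN is a genuinely
open protocol point (training it on the held-out subject's own trials
imports target-specific information into the training set); the package
keeps GAN fitting explicit — the caller selects the trials passed to
`train_fbgan()` — rather than hiding a default that silently resolves the
leakage question.

## The synthetic-EEG generator

`make_dataset()` draws, per trial, a class-specific narrowband source
(band-limited Gaussian noise in the class band) with a unit-norm spatial
pattern, on top of 1/f pink noise plus 30% white sensor noise; `snr`
fixes the ratio of mean rhythm power to background power. Defaults mirror
the reference recording geometry: 9 subjects × 2 sessions × 72
trials/class, 22 channels, 250 Hz, 4 s, rhythms at 8–12 Hz and 16–24 Hz
over four sensor neighbourhoods (the C3/Cz/C4 strip and a frontal site),
snr 1, and per-subject pattern perturbation and log-gain scale 0.1 —
values chosen once as a realistic MI regime. Per-subject perturbation
rotates the patterns and rescales sensors, producing the cross-subject
generalization gap the pipeline addresses (verified as a property test).
What the generator does *not* emulate: volume-conduction forward models,
artifacts (EOG/EMG), non-stationarity within a session, and
event-related desynchronization time-locking. Passing tests on this
generator therefore demonstrate correctness of the algorithms and the
claimed structural behaviours, not clinical-grade decoding performance on
real EEG.

`planted_covariance_class()` draws zero-mean Gaussian trials with an
exact expected channel covariance, the fixture used to check that GAN
training reproduces spatial structure.

## Numerical choices and degenerate inputs

* Rest-covariance ridge $10^{-8}\,\mathrm{tr}$ before the generalized
  eigensolve; eigenvector sign fixed by making the largest-magnitude
  entry positive; equal eigenvalues keep the symmetric solver's stable
  order.
* Zero-variance CSP projections are floored at $10^{-12}$ before the log.
* LASSO constant columns are given unit scale (they can never be
  selected); glmnet is run at `thresh = 1e-12` so the support is sharp.
* Binary cross-entropies are computed in logit space with the
  softplus-based stable form.
* All training loops are fully seeded: dataset, weight initialization,
  batch order, dropout masks and noise draws derive from the single
  config seed, and identical configs reproduce identical histories.

## Problem sizes used by the test and acceptance runs

The unit and acceptance suites run the synthetic pipeline at a reduced
geometry — 8 channels at 64 Hz (256-sample trials), 10–15 trials per
class, the scaled GAN above, classifier runs of 60–150 epochs — chosen so
the whole suite exercises every stage end-to-end in minutes on one CPU.
Structural contracts that depend on the full geometry (the 1600 → 22 ×
1000 generator, the 160-column stack, 4608/576 LOSO counts) are always
checked at full size.

## Known limitations

* The epoch container and checkpoints use RDS files; no GDF/HDF5 reader
  ships, so recordings must be converted upstream.
* The literal numeric-label LASSO imposes an artificial ordering on the
  four classes; the OVR variant is provided but is not the default, to
  stay faithful to the published formulation.
* GAN training at the full 22 × 1000 geometry is computationally serious
  (~4 × 10⁸ generator parameters) and is not attempted by the test suite;
  the scaled geometry demonstrates the training dynamics instead.
* Center re-estimation between expansions is a reasoned interpolation of
  an underspecified procedure; alternatives (centers as SGD parameters,
  exponential tracking) would also be defensible.
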