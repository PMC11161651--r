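---
title: "Dual time-scale CNNs for interpretable ECG classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual time-scale CNNs for interpretable ECG classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Clinicians read an ECG on two time scales at once. Morphology — the shape
of the P wave, the QRS complex, the T wave — lives at the beat level
(hundreds of milliseconds). Rhythm — the regularity of the RR interval
series — only exists across several beats. Atrial fibrillation (AF) is
defined on both scales: the P wave disappears and is replaced by
fibrillatory (F) waves, and the ventricular response becomes irregular.

`ecgxai` implements a two-branch convolutional architecture that encodes
this separation structurally. Both branches are nine-layer 1D CNNs with
batch normalization, ReLU activations, a global-average-pooling (GAP)
head and a two-class softmax; they differ only in the receptive field
$r$ of their last convolutional layer:

* the **short-term branch** is constrained to $r = 300$ samples (0.6 s at
  500 Hz) — at most one beat at 100 bpm, so it can only exploit
  morphology;
* the **long-term branch** has $r = 5000$ samples (10 s) — the whole
  record, so it can connect information across beats.

The two softmax outputs are combined by a weighted average
$(w_s p_s + w_l p_l) / (w_s + w_l)$ with $w_s$ fixed at 1 and $w_l$
optimized on validation folds; the decision is the larger combined
probability, with exact ties resolved conservatively to non-AF.

## Designing the networks from the receptive-field equation

For kernel sizes $k_l$ and strides $s_l$, the receptive field of the
last of $L$ convolutional layers is

$$r = \sum_{l=1}^{L} \Big( (k_l - 1) \prod_{i=1}^{l-1} s_i \Big) + 1 .$$

`receptive_field()` evaluates this closed form (it is verified against a
brute-force index-tracing oracle in the test suite), and
`solve_configuration()` inverts it: given a target $r$, a depth and
per-layer kernel/stride ranges, it returns a configuration meeting the
target *exactly*. Because many configurations solve the equation, the
solver is made deterministic by explicit design rules:

* **Stride placement.** The default objective places large strides as
  early as possible (lexicographically largest stride vector). Early
  downsampling minimizes computation and parameters for a given $r$; the
  opposite preference is available as `objective = "late_downsampling"`.
* **Stride-product cap.** The cumulative stride product is the temporal
  resolution of the deepest layer (in samples). `max_stride_product = 64`
  (128 ms at 500 Hz) is the default: the rhythmic class signal is a
  difference in RR-interval dispersion of roughly 40 ms (regular) versus
  160 ms (fibrillating), so the deep layers must resolve timing at
  comparable granularity. In pilot runs, architectures that downsampled
  by 256 or more plateaued near chance on purely rhythmic class signals
  while still learning morphological ones — the clearest possible sign
  that the cap is a modelling constraint, not a tuning knob. The cap
  also leaves > 150 temporal positions entering GAP on a 10-s record.
* **Kernel assignment.** Given strides, kernels are chosen to minimize
  the maximum kernel size, ties broken by the lexicographically smallest
  vector (balanced kernels; a fully determined solution).

The feature-map schedule follows the published architecture family:
layers 1–3 carry $4f$, layers 4–6 $2f$ and layers 7–9 $f$ maps, where
$f$ is the last-layer count (a grid-search hyperparameter; desk-scale
default 8).

Signals are padded before entering a network with $r$ repetitions of the
first value on the left and of the last value on the right
(`pad_signal()`), so edge samples are covered by as many receptive
fields as central ones. "Congruent with the receptive field" is read as
$r$ values per side; convolutions themselves use no implicit padding.

Batch normalization sits between each convolution and its ReLU. The
networks are trained with Adam on categorical cross-entropy. The
original work fixes no epoch budget; `train_model()` uses at most 30
epochs with best-validation-F1 checkpointing and early stopping
(patience 8 in the package's study scripts) — on the synthetic task the
validation F1 typically saturates within ten epochs, and the returned
model is always the best checkpoint, so early stopping changes runtime,
not semantics. Hyperparameters are selected on fold F1 scores by
maximizing mean minus (population) standard deviation across folds,
which eliminates combinations with erratic fold behaviour; whether that
dispersion should be the population or sample standard deviation is not
specified in the source material — population is used.

## Preprocessing

Four deterministic stages, in order:

1. **High-pass filter**: 4th-order Butterworth, cut-off 0.3 Hz, realized
   as cascaded second-order sections. The filter is applied zero-phase
   (each biquad forward and backward) with steady-state initial
   conditions by default: at a cut-off three decades below the sampling
   rate, a causal zero-state pass leaves a baseline transient that decays
   over several seconds — a substantial bias on a 10-s record. A causal
   variant remains available (`zero_phase = FALSE`).
2. **Wavelet denoising**: 8-level periodized orthogonal sym5
   decomposition; detail coefficients are soft-thresholded with the
   universal threshold $\sigma\sqrt{2\ln n}$, $\sigma$ estimated from
   the finest detail level via the median absolute deviation; the
   approximation band is retained. The thresholding rule is a standard
   default (the source material cites an external reference without
   details); it is fully exposed in `preprocess_config()`, and
   `dwt_threshold = 0` gives an identity round trip to machine
   precision.
3. **Tukey window**, `alpha = 0.06`, against edge effects.
4. **Min-max scaling** to $[0, 1]$ (constant signals are rejected).

The pipeline is length-preserving and deliberately *not* idempotent (a
second pass re-applies the window); annotations pass through unchanged.

## The synthetic data generator

Real 10-s single-lead recordings cannot be bundled, so
`generate_record()` emulates their diagnostic structure with analytic
ground truth:

* beats are sums of Gaussian bumps (Q, R, S, T, and P for non-AF) placed
  at R-peak times;
* RR intervals are log-normal with a configurable coefficient of
  variation — 0.05 for non-AF, 0.20 for AF by default (the AF value is
  in the range reported for absolute arrhythmia; the non-AF value
  reflects ordinary sinus variability);
* AF replaces the P wave with an amplitude-modulated 4–9 Hz sinusoid
  gated away from QRS complexes (the F-wave surrogate);
* white Gaussian noise (sd 0.03 relative to the unit R peak) is added;
* heart rate is drawn uniformly from 55–100 bpm per record.

The switches `morphology_only` and `rhythm_only` equalize the other
domain across classes, which is what makes the dual-time-scale claim
testable: under `rhythm_only` both classes share the non-AF morphology
(then AF records legitimately carry P-wave annotations), under
`morphology_only` both share the regular RR distribution.

What the generator does *not* emulate: baseline wander classes,
electrode artifacts, multi-lead structure, realistic P/T morphology
variation, atrial flutter-like organized activity. Tests passing on
this generator therefore demonstrate correctness of the machinery and
recoverability of planted class signals — not clinical performance.

A note on what the two branches can learn here: the synthetic
morphological signal (presence versus absence of a P bump before every
QRS) is strong enough that even the whole-record branch, which averages
over long windows, can pick it up; the rhythmic signal, by contrast, is
invisible to the beat-scale branch apart from occasional double-beat
windows at short RR intervals. The specialization contrast is therefore
asymmetric at desk scale — sharp in the rhythm direction, soft in the
morphology direction.

## Attribution methods

Thirteen post-hoc methods are implemented behind one interface
(`explain()`), all operating on the padded signal and cropped back to
the record extent (relevance attributed to padding is discarded and
reported as `pad_mass`):

* **Gradient family** — vanilla gradient $|\partial f_c / \partial x|$,
  input-times-gradient (no absolute value), integrated gradients (32
  steps from a zero baseline — the preprocessing minimum — with absolute
  value), SmoothGrad (32 augmentations, noise sd = 10% of the input
  range, absolute value of the averaged map), guided backpropagation
  (upstream negatives zeroed at ReLUs).
* **Propagation family** — LRP-Z, LRP-$\varepsilon$
  ($\varepsilon = 0.1$), LRP-$\alpha\beta$ ($\alpha = 2, \beta = 1$;
  the stated pairing of $\varepsilon$ with the $\alpha\beta$ rule in the
  source text is contradictory, so the $\varepsilon$ enters as an
  optional denominator stabilizer, default 0.1), LRP-$w^2$, and deep
  Taylor decomposition (DTD). Batch normalization is folded into the
  adjacent convolution (evaluation statistics) before propagation;
  gradients always use the unfolded graph. LRP starts from the
  target-class logit; DTD starts from the softmax probability — a
  non-negative quantity, consistent with DTD explaining only positive
  evidence — and uses the $z^+$ rule internally with the box-constrained
  $z^B$ rule at the $[0,1]$ input layer, so DTD maps are non-negative by
  construction. Biases absorb relevance (they appear in denominators
  only); on bias-free networks LRP-Z is exactly conservative, which the
  tests assert.
* **Class-activation family** — GradCAM and GradCAM+ on the last
  convolutional layer by default. With a GAP head the class gradient is
  constant across positions of that layer, so the channel weights reduce
  to the (positive part of the) dense weights over the layer length;
  maps are ReLU-ed channel sums, linearly interpolated back to input
  coordinates through the layer's stride geometry.
* **Shapley family** — a gradient estimator (expected gradients):
  attributions average $(x - b) \odot \nabla f(b + \alpha (x - b))$ over
  background references $b$ (cycled deterministically so each reference
  appears equally often) and $\alpha \sim U(0,1)$. Exact enumeration
  (`shapley_exact()`) and permutation sampling (`shapley_sample()`) of
  arbitrary cooperative games are exported as the reference
  implementations against which the estimator is tested. The background
  is preprocessed records (500 at full scale; desk runs use fewer).

Maps explain the *predicted* class by default (`target` overrides). All
stochastic methods are seeded.

## Explanation validation by pixel-flipping

`pixel_flipping()` ranks samples by a relevance map (ties by index),
perturbs the top fraction, reclassifies, and traces the mean categorical
cross-entropy against the true labels over a fraction grid (default 2%
steps; the study scripts use 5%). Two perturbation schemes are
compared:

* **linear interpolation** (the scheme of interest): ranked samples are
  removed and filled by linear interpolation between the nearest
  surviving neighbours (boundary runs extend the nearest value). This
  destroys high-frequency information without injecting
  out-of-distribution jumps;
* **zero substitution** (the prevalent scheme): ranked samples are set
  to 0 — on $[0,1]$-scaled signals, an extreme value the models never
  saw in training.

The random-ranking baseline quantifies the noise each scheme itself
injects: a good scheme should leave the loss unchanged when the
perturbed samples are chosen at random. Curves are summarized by the
relative AUC — the trapezoidal area under loss-versus-fraction divided
by the area spanned by the maximum loss. In `compare_methods()` the
normalizer is shared across all methods and the random baseline within
one (model, scheme) pair, so the resulting table rows are mutually
comparable; per-curve normalization is available through
`relative_auc()` directly. The loss score is taken to be the training
loss (mean categorical cross-entropy), and curves average losses over
records; both conventions are stated here because the source material
leaves them open.

## Template-beat relevance aggregation

For pseudo-quantitative summaries, `segment_beats()` cuts fixed-length
windows (default 300 samples ≈ 0.6 s) centred on annotated R peaks;
beats are averaged into a per-record template, and per-template-sample
relevance mean and intra-ECG variation coefficient (population sd /
mean across the record's beats; set to 0 and flagged where the mean is
numerically zero) are computed and averaged per class. The original
procedure aligns beats by two-dimensional signal warping before
averaging; that algorithm lives in an external reference and is *not*
reimplemented — R-peak-centred fixed windows with plain averaging
preserve every aggregation statistic while giving up sub-beat
non-linear alignment. This is a documented limitation: template flanks
are slightly blurrier than warped averages would be. The conventional
1/10 scaling of the variation-coefficient band is applied only in
`plot()` output; stored values are never display-scaled.

## Numerical choices and degenerate inputs

* Denominator stabilizers: $10^{-9}$ sign-preserving for exact rules,
  the configured $\varepsilon$ for LRP-$\varepsilon$/$\alpha\beta$.
* Interpolation perturbation keeps at least one anchor sample (a fully
  masked signal is an error; with a single anchor the fill is constant).
* Min-max scaling and the variation coefficient reject or flag
  degenerate (constant, zero-mean) inputs rather than dividing by zero.
* Weight initialization is He-normal, seeded; BLAS-level determinism
  makes whole runs bit-reproducible on one platform.
* The ensemble weight grid spans 0.25–3.0 in steps of 0.0025
  (consistent with a four-decimal optimum); among F1-ties the weight
  closest to the neutral 1.0 is returned.

## Desk-scale study sizes

The package's study scripts and test suite run the complete method on
one CPU. The conditions are: 200 synthetic records per class
(training/validation/held-out split 240/60/100), three seeds per
experiment, 30-epoch budget with patience 8, last-layer feature maps 8,
batch 16, learning rate $10^{-3}$, 5% perturbation steps. The
full-scale reference operating point (thousands of real records, the
4×3×4 hyperparameter grid, 500-record Shapley backgrounds) is
documented in `reference_hyperparameters()` and `hyperparam_grid()` but
is not exercised by the tests.

## Known limitations

* The synthetic generator's simplicity means morphological class
  signals are easier than in real ECGs; absolute classification scores
  on it say nothing about clinical data.
* On the synthetic models, deep Taylor maps largely track signal
  amplitude (the QRS complex dominates), whereas input-times-gradient
  localizes the class-discriminative P-wave region; which method
  localizes diagnostic evidence best is a property of the trained model
  and data, not of the package, and should be re-validated by
  pixel-flipping on any new dataset.
* Full-scale observations need not transfer to desk scale: small
  low-noise synthetic models tolerate random-order interpolation of
  roughly half the samples before their loss drifts by 5%, not the ~70%
  seen with models trained on large heterogeneous ECG corpora, and the
  whole-record branch learns the (deliberately strong) synthetic
  morphology signal as readily as the beat-scale branch.
* DTD requires $[0,1]$ inputs (guaranteed by the preprocessing); it is
  undefined for raw signals.
* GradCAM's positional resolution is the deep layer's stride product;
  on these architectures that is 64 samples before upsampling.
* The WFDB format is not read natively; external records must be
  converted to the package's plain-text interchange format
  (`write_records()` / `read_records()`).
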