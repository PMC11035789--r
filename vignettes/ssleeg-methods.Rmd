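---
title: "Self-supervised EEG emotion recognition: models, assumptions, and design choices"
author: "ssleeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised EEG emotion recognition: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Labeled EEG emotion datasets are small: annotating a recording requires a
controlled elicitation protocol and per-trial self-assessment, while
*unlabeled* EEG is cheap. Self-supervised learning addresses this asymmetry
by manufacturing a supervised problem — a *pretext task* — from the
unlabeled signal's own structure, pretraining a feature extractor on it, and
transferring that extractor to the downstream emotion-classification task
with only a small number of real labels.

`ssleeg` implements this pipeline end to end for multichannel EEG-like time
series: differential-entropy band features, three pretext tasks (Relative
Position, Temporal Shuffling, Contrastive Predictive Coding), a small
trainable encoder and causal context model, and a trial-grouped
cross-validated evaluation harness. A synthetic-EEG generator with known
class-dependent band structure makes every stage testable without any
dataset download.

## Differential-entropy features

Recordings are segmented into non-overlapping 1-s windows (200 samples at
200 Hz; 0-based, half-open `[t, t + T)`, trailing partial windows dropped).
For each window, channel, and canonical band — delta 1–4, theta 4–8, alpha
8–13, beta 13–30, gamma 30–100 Hz — the feature is the differential entropy
of the band-limited content. For a Gaussian signal this has the closed form

$$h(X) = \tfrac{1}{2}\,\ln\!\left(2\pi e\,\sigma^2\right),$$

with $\sigma^2$ the band variance. Two estimation paths are provided and
selected by a configuration flag, because the variance can be measured
either in the time domain or spectrally:

* `method = "filter"`: zero-phase Butterworth band-pass (order 4, applied
  forward–backward via `signal::filtfilt`, so window alignment is
  preserved), then the unbiased $(n-1)$ sample variance per window.
* `method = "stft"`: mean-removed periodogram mass over the bins whose
  center frequency falls in `[low, high)`, counting both spectral sides, so
  the value is Parseval-consistent with the time-domain variance of an
  in-band signal.

Numerical conventions, pinned because they matter for exact tests: DE is
always in **nats** (discrete Shannon entropy, `shannonEntropy()`, stays in
bits — the base is a constant offset and irrelevant to any downstream
classifier, but it must be fixed); the variance estimator is the unbiased
$(n-1)$ form; a zero-variance window raises an error by default rather than
emitting $-\infty$, which would silently poison downstream training (a
`degenerate = "neginf"` escape hatch exists). The gamma band's nominal
100 Hz edge equals Nyquist at 200 Hz sampling; the band-pass clips it just
below Nyquist with a warning, and the generator synthesizes gamma content
only up to 95 Hz for the same reason.

The two DE paths agree within 0.2 nats on band-limited signals (tested). On
*empty* narrow bands they can disagree more — a 1-s window gives the delta
band only three periodogram bins, and an order-4 Butterworth has substantial
roll-off over 1–4 Hz — which is an estimator-variance fact, not a defect;
the agreement claim is therefore stated, and tested, for the band that
actually carries signal.

## The pretext tasks

All three tasks share one trainable encoder $h_\theta$ (equivalently
$g_{enc}$) that maps a window representation to a $D$-dimensional embedding.

**Relative Position (RP).** Under the assumption that a reasonable feature
representation changes slowly in time, windows close in time should be
similar. Pairs $(t, t')$ within one trial are pseudo-labeled $+1$ when
$|t - t'| \le \tau_{pos}$ and $-1$ when $|t - t'| > \tau_{neg}$; distances
in between (the *dead zone*) are never sampled. The head combines
embeddings by the element-wise absolute difference $|h - h'|$ and a linear
logistic layer, trained with
$\sum_i \log(1 + \exp(-y_i\,[w^\top g_i + w_0]))$.

**Temporal Shuffling (TS).** Two anchor windows are drawn from the positive
context ($0 < t'' - t \le \tau_{pos}$); a third window either lies strictly
between them (temporally ordered, $y = +1$) or comes from the negative
context, farther than $\tau_{neg}$ from both anchors (shuffled, $y = -1$).
The label is $+1$ exactly when $t < t' < t''$. The head concatenates the
two absolute differences, $(|h - h'|,\ |h' - h''|) \in \mathbb{R}^{2D}$,
and uses the same logistic loss.

**Contrastive Predictive Coding (CPC).** A causal autoregressive model
$g_{ar}$ summarizes the embedding history into a context
$c_t = g_{ar}(z_{\le t})$; a per-step log-bilinear score
$f_k(z, c) = \exp(z^\top W_k c)$ rates candidate future windows, and the
InfoNCE objective is the mean categorical cross-entropy of identifying the
true $z_{t+k}$ among $N$ candidates (one positive, $N-1$ negatives).
Minimizing InfoNCE maximizes a lower bound on the mutual information
between context and future; its chance level is exactly $\ln N$, reached
when all candidate scores are equal (an identity the tests check to machine
precision). All score arithmetic is in log space (log-sum-exp), since
$\exp(z^\top W_k c)$ overflows casually otherwise.

Design choices where the underlying method description is open, with
rationale:

* **RP loss form.** Only the TS loss is printed in the method's source
  description; RP uses the identical logistic form over $|h - h'|$ — the
  only reading consistent with "replace $g_{RP}$ by $g_{TS}$".
* **Class balance.** The samplers draw $N/2$ positives and $N/2$ negatives;
  the pair-sampling definition does not fix the ratio, and balance avoids a
  degenerate linear head.
* **Within-trial sampling.** Pairs and triples never cross trial
  boundaries: "adjacency" across a trial boundary is physically
  meaningless.
* **Radii.** Defaults $\tau_{pos} = 12$ windows, $\tau_{neg} = 60$ windows
  (12 s / 60 s at 1-s windows), config-exposed; these follow common
  practice for temporal pretext tasks on biosignals. Note that
  $\tau_{neg} = 60$ makes negatives unrealizable inside a 60-window trial —
  the sampler then refuses with an explicit error naming the class; runs on
  short trials should shrink the radii (the bundled pipeline defaults use
  3 / 15 windows).
* **Anchor self-pairs.** $|t - t'| = 0$ satisfies the positive constraint
  formally but yields the all-zero difference feature; the sampler excludes
  $t = t'$.
* **CPC negatives** are drawn uniformly from the whole dataset (any trial),
  excluding only the positive window itself — the standard reading of the
  contrast set. Each valid $(t, k)$ pair is used exactly once per epoch;
  anchors require a full context behind them and $K$ future steps ahead,
  i.e. $t \in [L, T - K]$ with context length $L$.
* **Per-step $W_k$.** Each prediction horizon $k = 1..K$ has its own
  bilinear matrix; the total loss is the mean over $k$, which keeps its
  scale independent of $K$.
* **Sign convention.** The InfoNCE quantity is minimized as written; the
  mutual-information bound grows as the loss falls.

## Encoder and context model

No deep-learning framework is assumed: the encoder is a small
fully-connected stack (default input → 32 tanh → $D = 16$ linear) and the
context model a single-layer tanh recurrence
$c_t = \tanh(U z_t + V c_{t-1} + b)$ run from a zero state, both with
hand-written analytic gradients (verified against finite differences in the
test suite) and a full-batch Adam optimizer. The underlying method
description names only "a CNN" without architecture, so the encoder is
deliberately a pluggable contract — anything mapping a window representation
to a fixed-length vector fits.

Two defaults deserve justification:

* **DE features as encoder input** (raw flattened windows are also
  supported): the class signal lives in band power, and the DE
  representation makes desk-scale CPU training take seconds rather than
  hours.
* **$D = 16$, a genuine bottleneck** below the 40-dimensional feature
  input. With $D \ge$ input dimension and a (near-)linear encoder, a linear
  probe on a *randomly initialized* encoder is information-equivalent to
  probing the raw features, and the pretrained-vs-random comparison would
  measure nothing. The bottleneck forces the encoder to choose what to
  keep, which is exactly what pretraining is supposed to learn.

Causality of the context model — $c_t$ unchanged by any perturbation of
$z_u$, $u > t$ — is a structural property of the recurrence and is tested
directly, at initialization and after training.

## The synthetic generator

Each trial is a sum over the five bands of band-limited Gaussian noise
(spectral masking of white noise), scaled so the trial-level band SD equals
the class profile entry, multiplied by a slow log-normal envelope, plus an
optional 1/f pink-noise background, linearly mixed across channels. Labels
are constant within a trial (one clip, one emotion). One RNG substream per
(subject, trial) makes generation order irrelevant: the same trial is
bit-identical however the dataset is traversed.

What the pieces emulate, and the parameters that matter:

* **Class-dependent band profiles** (`bandPowerProfiles`, SD units): each
  class elevates one signature band (SD 3) over a floor of 1 — class 1
  alpha, class 2 beta, class 3 theta, class 4 delta. Real emotion effect
  sizes are unknown (the source datasets deposit no accession to measure
  them from); these values are chosen once for testability: separable
  through DE features, overlapping under the noise floor.
* **Slow amplitude envelope** (`modDepth = 0.5`,
  `modTimescaleS = 10` s): Gaussian-kernel-smoothed noise, exponentiated
  and RMS-normalized so it never changes the trial-level band SD. This is
  the generator's mechanism for "signal statistics change slowly in time" —
  the assumption RP and TS rest on. Stationary band noise would have
  *uncorrelated* window variances and nothing for a temporal pretext task
  to learn; with the envelope, adjacent-window DE features are strongly
  positively correlated (tested) and the correlation decays over ~10 s.
* **Pink 1/f background** (`noiseSd = 1`): broadband nuisance power in
  every band, making single-window features noisy.
* **The structure-free control** (`whiteNoiseConfig()`): flat identical
  profiles, envelope off, *and pink noise off* — 1/f power itself drifts
  slowly and would be temporal structure, which is precisely what the null
  must not contain.

What the generator does **not** emulate: eye-blink/EMG artifacts, electrode
geometry, volume conduction, nonstationary class drift within a trial, or
realistic inter-subject variability. Passing tests on this generator
demonstrate that the algorithms do what their definitions say under their
own assumptions (Gaussian band content — making the DE closed form exact in
expectation — and slow statistics); they do not certify accuracy numbers on
real recordings.

## Evaluation protocol

Downstream evaluation is 10-fold cross-validation with **trial-grouped,
class-stratified folds**: all windows of a trial share a fold, because
window-level splitting leaks within-trial autocorrelation and inflates test
accuracy; this choice affects comparability with window-split results and
is therefore stated prominently. The linear probe is a multinomial logistic
head (`nnet::multinom`) on frozen embeddings, standardized with
training-fold statistics; `labelFraction` controls how many training-window
labels the probe may see (the low-label transfer setting uses 10%, sampled
per class so no class disappears). A `finetune` mode unfreezes the encoder
under a softmax head; a `random` method provides the uniform-prediction
chance baseline (1/3 or 1/4 for the balanced 3- and 4-class datasets).
Four-class valence/arousal labels binarize each rating at 5, ties counting
as high: class $= 2\,[V \ge 5] + [A \ge 5]$.

Accuracy and macro F1 follow the standard confusion-matrix definitions; a
class absent from both predictions and truth would make F1 0/0 and is
pinned to 0 with a warning. Method comparisons use the two-sided paired
Wilcoxon signed-rank test on per-fold scores with Bonferroni correction
across pairs; an all-zero difference vector is a degenerate test and is
refused (reported as NA in the pairwise table rather than aborting it).

Two nulls guard against self-deception:

* **Label permutation**: labels are shuffled across *windows* (fold
  geometry unchanged). Window-level permutation is deliberate: permuting at
  the trial level preserves within-trial label coherence, so fold
  accuracies stay quantized at trial granularity and their mean has
  ~9-point binomial noise at 30 trials — a tolerance-free zone no correct
  implementation could satisfy. Window permutation destroys the
  label–feature association with an effective sample size of all windows.
* **Structure-free CPC control**: the final CPC loss on held-out
  structure-free data must sit at $\ln N$. Held-out, because on a finite
  training set a model can push its *training* loss below $\ln N$ by
  memorizing realization noise even when there is genuinely nothing to
  predict; the held-out loss is the statement "nothing to predict".

## Problem sizes and reproducibility

The bundled study conditions are 30 trials (2 subjects × 15) of 60 s × 8
channels at 200 Hz — 1800 windows of 40 DE features — with CPC trained 30
full-batch epochs ($K = 4$, 7 negatives, context 16). These sizes were
chosen so the complete pipeline, including the structure-free control,
runs in about a minute on one CPU while leaving every statistical
conclusion (Wilcoxon p-values, chance baselines, null tolerances) stable
across seeds. Every random draw — generation, sampling, initialization,
negatives, fold assignment, label subsetting — flows from explicit seeds
derived from one master seed, and `runPipeline()` records per-stage seeds
and artifact hashes in a JSON manifest; rerunning a config reproduces
identical hashes for all deterministic artifacts.

```{r demo}
library(ssleeg)
run <- runPipeline(demoConfig())
run$reports
run$comparison
```

## Known limitations

* The encoder and optimizer are plain R; they are fast at the bundled
  sizes but not a route to training on real 62-channel datasets.
* Adapters for on-disk layouts of public emotion datasets are out of
  scope; recordings enter as arrays plus metadata (or via the binary
  container written by `writeDataset()`).
* Real-data accuracy is not reproduced here — the evaluation is
  property-based on synthetic data by design, and split-protocol details
  (within- vs cross-subject) strongly affect real-data numbers.
* The Wilcoxon test on 10 folds has a coarse p-value floor
  ($2^{-10} \cdot 2$ for the exact two-sided test); it can establish
  p < 0.05, not tiny p-values.
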