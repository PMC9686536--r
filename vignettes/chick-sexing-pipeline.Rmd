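---
title: "Sexing day-old chicks from their calls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexing day-old chicks from their calls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Day-old chicks isolated from their flock produce loud, regular distress
calls. Cocks' and hens' calls are not distinguishable by ear or by visual
inspection of a spectrogram, but weak sex-correlated structure exists in
some breeds, and a classifier trained on many calls can exploit it. Because
a single call is a noisy observation, the practical decision unit is the
*bird*: classify many calls per chick and take a majority vote. `chicksex`
implements this pipeline end to end — denoising, call detection, feature
extraction, classification, identity-safe evaluation and voting — together
with a synthetic call generator so that every stage can be verified without
access to field recordings.

## Signal chain

**Recording model.** Mono PCM WAV at 48 kHz / 16-bit, roughly two minutes
per bird. Integer samples are normalized by $2^{15}$, so all amplitude
thresholds in the package are on the $[-1, 1]$ scale.

**High-pass denoising.** Handling noise, footsteps and hum sit below
1000 Hz, while chick calls live above 1500 Hz. `design_highpass()` builds a
digital Butterworth high-pass (bilinear transform via the `signal` package)
with its half-power (−3 dB) point at 1500 Hz. The filter is applied as a
*single causal pass* (`apply_filter()`): a forward–backward pass would
square the magnitude response and silently move the −3 dB point. The order
(default 4) only steepens the roll-off; the −3 dB point is the design cutoff
for every order.

**Framing.** `frame_signal()` cuts the signal into 1024-sample windows
(21.3 ms at 48 kHz) advanced by 128 samples (one eighth of the window).
Trailing remainders shorter than one window are dropped, so the frame count
is exactly $\lfloor (L - 1024)/128 \rfloor + 1$ — a 0.1 s call gives 30
frames. Windows use the periodic form with divisor $M$:
$w(n) = 0.5 - 0.5\cos(2\pi n/M)$ (Hanning, default; edge value 0) or
$0.54 - 0.46\cos(2\pi n/M)$ (Hamming; edge value 0.08). The Hanning window
is the default because its faster edge decay suppresses spectral leakage
better.

**Endpoint detection.** Calls are found with the short-time zero-crossing
rate (ZCR): silence has essentially no crossings, a call near 5 kHz has
hundreds per 1024-sample frame. Two details matter:

* *Offset gating.* Sensor noise produces tiny-amplitude sign flips. Samples
  with $|x| \le$ `offset` (default 0.01 full scale) are treated as a dead
  zone: the signal must leave the band on opposite sides for a crossing to
  count. We implement this by dropping dead-zone samples and counting sign
  changes among the survivors within each frame; this is robust to a sample
  landing arbitrarily close to zero, where a literal "both neighbours above
  offset" rule undercounts.
* *ZCR on raw frames.* The window taper is a spectral-analysis device; it
  does not change sign structure and is not applied before counting.

Frames with ZCR strictly above the threshold (default 10) form maximal runs;
runs shorter than T1 = 30 frames or longer than T2 = 110 frames are
discarded (chick calls last about 0.1–0.35 s; clicks and long squeals are
rejected). Two equivalent ZCR implementations exist — a per-frame count on
the frame matrix and a cumulative sample-domain path that avoids
materializing the ~150 MB frame matrix of a two-minute recording — and a
test asserts they agree exactly.

A subtlety worth documenting: frame extents are *wider* than sample extents.
Because windows overlap 8×, a call occupying $S$ samples touches roughly
$S/128 + 7$ frames. Ground-truth frame extents from the synthetic generator
therefore use the window-overlap convention (first/last frame whose window
overlaps the call), which is what the detector can actually observe.

## Features

Each detected call becomes a fixed-shape matrix (110 frames × D), padded as
described below. All logarithms are base 10 with the 10× dB factor, and
energies are clamped at a floor of $10^{-10}$ before the log so features are
always finite.

* **Spectrogram (110 × 513).** One-sided modulus (not squared modulus) of
  the 1024-point DFT of each windowed frame, in dB. Note a consequence of
  the modulus convention: scaling the waveform by $c$ shifts the dB
  spectrogram by $10\log_{10} c$.
* **Cepstrogram (110 × 160).** Per frame, the DCT-II of the 513-bin dB
  spectrum with $N = 513$; coefficient indices $[5, 165)$ (0-based) are
  retained — exactly 160 coefficients, dropping the smooth spectral-tilt
  components. The printed transform sums $\cos(\pi n (k - 0.5)/N)$ over
  $k$; with 1-based $k$ that is the standard DCT-II kernel
  $\cos(\pi n (k + 0.5)/N)$, $k = 0,\dots,N-1$, which is what we implement.
  $N$ could arguably be the frame length (1024) instead of the spectrum
  length; we use 513 because the transform is applied to the one-sided dB
  spectrum. Both choices only rescale/reindex the coefficients.
* **MFCC + Logfbank (110 × 52).** A 26-channel triangular mel filter bank
  (mel scale $M(f) = 2595\log_{10}(1 + f/700)$) spans 0 Hz to Nyquist with
  centers equally spaced in mel and edges snapped to FFT bins so every
  filter peaks at exactly 1. Per frame: linear energies → mel energies →
  $10\log_{10}$ (**Logfbank**, 26 values) → DCT-II over the 26 channels
  (**MFCC**, all 26 coefficients kept, including the 0th — the 52-wide
  concatenation forces 26 + 26). No liftering, no delta features, no
  truncation to 13 coefficients.

**Padding.** Calls span 30–110 frames; classifier inputs are fixed at 110.
Rows beyond the call are filled with the feature of a *silent frame*: the dB
floor (−100 dB) for spectrogram and cepstrogram pad values, and the
silent-frame Logfbank/MFCC vector for the combined feature. All pad rows are
identical by construction, so the padding carries no information.
Interpolating variable-length calls to a fixed length was rejected because
it would distort the time axis that the recurrent models consume.

## Classifiers

Five families, all ending in the same head (dense 64 → ReLU → dropout 0.2 →
dense 32 → ReLU → dense 1 → sigmoid), trained with Adam on binary
cross-entropy (cock = 1, hen = 0):

* `cnn`: three [3×3 conv (64 cores) → 3×3 max-pool] stages, flatten, head.
* `gru`: two stacked GRU layers (64 units); the second layer's *last-step*
  output feeds the head. (Using the full sequence is the other defensible
  reading; last-step is the common default for sequence classification.)
* `crnn`: the conv stack, then a "time flatten" that reshapes the conv
  output to (time, channels × reduced frequency) preserving temporal order,
  then the two GRU layers.
* `twostream`: the conv branch and the GRU branch side by side on the same
  input, concatenated before the head.
* `resnet50`: 7×7/2 stem, four stages of (3, 4, 6, 3) bottleneck blocks
  with batch normalization and post-add ReLU, input replicated to three
  channels, global average pooling. The third conv of stage-4 bottlenecks
  uses 512 3×3 cores (the standard bottleneck width for that stage).

Because no deep-learning framework is available in R, the package carries
its own small reverse-mode layer library (im2col convolutions, max pooling,
batch normalization, GRU with backpropagation through time, dropout, Adam).
Gradients of every architecture are verified against central finite
differences in the test suite. One honest caveat found during that
verification: at initialization all biases are exactly zero, so ReLU-dead
regions can place residual preactivations *exactly on* the ReLU kink, where
a finite difference straddles the non-differentiability; the analytic
gradient uses the standard subgradient (zero at the kink). The checks
therefore probe configurations away from that measure-zero set.

Every builder accepts all three feature widths (513/160/52) unchanged, and a
`width_multiplier` in $(0, 1]$ scales the conv/GRU/residual widths so the
same architectures run at desk scale; 1 reproduces the full-size networks.
Unstated hyperparameters were fixed once: Adam at its usual defaults
(learning rate $10^{-3}$), batch size 32, max 2000 epochs (the recurrent
models converge slowest), pool stride equal to the 3×3 pool size.

**Training protocol.** Early stopping monitors *validation accuracy* with
patience 100 at full scale: if it has not increased for `patience` epochs,
training stops and the parameters of the best epoch are restored. Training
is exactly reproducible under a fixed seed.

## Chick-level evaluation and voting

Calls of one bird are highly self-similar, so scattering a bird's calls
across training and test sets inflates test accuracy — the central
methodological trap this design avoids. `split_by_chick()` holds out whole
birds: test chicks are sampled per sex (default fraction 0.2, the full-scale
study proportion), training and validation calls are drawn only from the
remaining birds at a 5:1 ratio, and call counts are balanced between sexes
within every partition. The constructor enforces an empty intersection
between test chick ids and the rest.

A bird's sex is decided by majority vote over its first 41 detected calls
(earliest-first; the selection order is not specified at full scale, and
earliest-first is deterministic and matches the "30 s of effective audio"
idea). 41 is odd, so ties are impossible; even vote counts are rejected
rather than tie-broken. Voting amplifies per-call accuracy sharply: with
per-call accuracy $p$, chick-level accuracy is the binomial tail
$P(\mathrm{Bin}(41, p) \ge 21)$ — at $p = 0.7$ that is already ≈ 0.996, and
the test suite checks a Monte-Carlo simulation against this closed form.

## The synthetic generator

Real study recordings are not shareable, so `generate_call()` /
`generate_recording()` / `generate_study()` produce fixtures with known
ground truth that emulate what the pipeline assumes about real data:

* harmonic calls with a ~5 kHz fundamental and a weaker ~16 kHz formant
  component, smooth raised-cosine onset/offset, peak amplitude 0.8;
* per-chick frequency jitter (uniform ±150 Hz, fixed per bird) so calls of
  one bird track each other while birds differ — the property that makes
  identity-safe splitting necessary;
* a controllable per-sex fundamental offset (default 400 Hz for cocks);
  offset 0 makes the sexes acoustically identical, giving a chance-level
  control. Synthetic "breeds" are profiles with decreasing offsets,
  emulating the qualitative ordering of breed separability without claiming
  to model real breeds;
* additive low-pass background noise below 1000 Hz, the band the high-pass
  filter removes.

Call durations are drawn uniformly from [0.1, 0.26] s by default. The upper
end deliberately sits below 0.35 s: the duration gate is specified in
*frames* (30–110), and once window overlap is counted a 0.35 s call spans
~131 frames and would be rejected by its own detector. The [0.1, 0.26] s
default keeps every planted call inside the gate so clean recordings are
recovered with recall 1.0; the range is a parameter and can be widened.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real sex differences are weak, breed-dependent and of
unknown acoustic form (the planted frequency offset is a test device, not a
biological claim); real recordings contain overlapping vocalization types,
echo and amplitude variation; and real per-call accuracy is far below the
near-separable synthetic benchmark. The synthetic end-to-end benchmark
validates the *machinery* (detection, features, training, splitting,
voting), not field performance.

## Desk-scale problem sizes

The shipped tests and examples run the full pipeline at reduced scale,
chosen once as sizes a reviewer can run on a laptop core: studies of up to
20 chicks per sex with 43–45 calls per bird (~19 s of audio each), CNN width
multiplier 1/8 (8 conv cores), ResNet width multiplier 1/16, early-stopping
patience 6–15 with epoch caps of 15–40. The end-to-end benchmark asserts
per-call accuracy ≥ 0.85 and chick-level accuracy ≥ 0.95 at a 400 Hz offset,
and that the zero-offset control collapses toward chance. With identical
sexes the classifier keys on individual birds' frequencies, so with 8
held-out birds the control's accuracy has high variance around 0.5; the
test therefore asserts a wide chance band plus a large contrast against the
separable run, rather than a tight value that 8 birds cannot statistically
support.

## Known limitations

* The IIR filter is applied causally once; there is no zero-phase option.
* Non-48 kHz input is accepted (windows are specified in samples), but
  parameters are not rescaled automatically; the 21.3 ms window assumption
  holds only at 48 kHz.
* The ZCR detector presumes clean, high-SNR recordings (its design
  premise); no energy- or entropy-based detection is provided.
* The R layer library is optimized for desk-scale experiments, not for
  full-scale training; `width_multiplier = 1` with tens of thousands of
  calls is better served by a GPU framework, and the package's value there
  is the reference semantics of the pipeline.
* Pretrained ResNet initialization is supported only via weight files
  produced by `save_model_weights()`; no pretrained weights ship with the
  package.
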