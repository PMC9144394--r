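---
title: "Denoising larval feeding sounds: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising larval feeding sounds: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wood-boring beetle larvae (e.g. *Semanotus bifasciatus* in *Platycladus*
logs) are most damaging, and most treatable, before any external symptom
shows. A waveguide screw coupled to a piezoelectric probe picks up the
substrate vibration of larval mouthparts rasping wood: a sparse train of
short broadband "biting" pulses, a few milliseconds long, with dominant
energy near 5 kHz. In the field this signal sits under traffic rumble,
horns, bird song, wind, dripping water and human speech, often at
strongly negative signal-to-noise ratios. Detecting infestation then
hinges on denoising.

`larvadenoise` implements the full experimental chain: SNR-controlled
mixture construction, two neural denoising families plus a wavelet
baseline, a three-metric evaluation suite, and a small downstream
classifier that quantifies how much a denoiser helps detection.

## Signal model and dataset construction

All audio is mono, 16 kHz, float in [-1, 1] (`audio_clip`). Recordings
are cut into 5-minute segments and 2-second slices; a trailing remainder
shorter than a slice is discarded, which is what makes the bookkeeping
exact: 84 training segments × 150 slices = 12,600 training slices, 36
test segments → 5,400 slices.

A noisy mixture is built by scaling only the noise:
$$S_t = C_t + a\,N_t,\qquad
  a = \sqrt{\frac{\sum_t C_t^2}{10^{\mathrm{SNR}/10}\,\sum_t N_t^2}},$$
so that the measured SNR
$10\log_{10}\!\left[\sum_t C_t^2 / \sum_t (S_t - C_t)^2\right]$
equals the target exactly (the package round-trips to within
1e-6 dB). The training grid is $\{-20,\dots,5\}$ dB in 5 dB steps, the
test grid $\{-24,\dots,6\}$ dB in 6 dB steps; assignment is *balanced*
(each level receives exactly $n/6$ mixtures) because the study-design
counts (1,050 and 450 per level) are only possible under balanced
assignment, not under independent uniform draws. When a mixture would
clip, the builder rescales pure, noise and mixture jointly — an SNR is a
ratio, so the measured SNR is untouched; `mix_at_snr` itself never
rescales anything.

## Synthetic surrogate signals

No field recordings are distributed, so a generator module emulates the
three signal classes. It makes every downstream module testable; it does
not claim species-level acoustic fidelity.

* **Feeding** (`gen_feeding`): Poisson-arriving, exponentially damped
  band-limited bursts (default 10 pulses/s, 6 ms, carrier drawn from
  5000 ± 1000 Hz, peak amplitude 0.5 with 30 % jitter) over a 0.002-RMS
  noise floor. Defaults put pure-clip RMS near 0.05, leaving headroom to
  mix down to -24 dB without clipping.
* **Noise** (`gen_noise`): one recipe per field noise class — FM chirp
  trains (bird song), low-passed rumble plus engine harmonics
  (vehicles), vibrato tones (whistles), 1/f noise with slow gusting
  (wind), syllabically modulated band-passed noise (speech), sparse
  decaying clicks (dripping), plus white and pink references. Every clip
  is rescaled to an exact target RMS (default 0.05).
* **Ambient** (`gen_ambient`): very low-level coloured noise
  (RMS 0.005), the non-infested-log control class.

One global seed drives everything: clip $i$ uses
`derive_seed(seed, i)`, kept below $2^{31}$. Train and test sources draw
from disjoint derived-seed ranges, mirroring the disjoint recordings of
the original design. What the surrogates deliberately lack: reverberant
coupling through wood, non-stationary field noise statistics, and
amplitude statistics of real larvae — results on synthetic data
therefore validate the *machinery* (shapes, bookkeeping, losses,
metrics, qualitative ranking), not absolute field performance.

## Time-domain networks (TDD-Nets)

Waveform in, waveform out: an input convolution (1 → C channels), eight
convolution blocks, an output convolution, and a final 1×1 convolution
back to one channel. Every convolution except the final 1×1 is followed
by batch normalization and a leaky ReLU (slope 0.01). The four variants
differ only in the blocks: standard convolutions (`C`); dilated
convolutions with rate $2^k$ in block $k$ (`D`), growing the receptive
field to 1,025 samples for kernel 3; an identity shortcut per block
(`DS`); a convolutional (dilation-1) shortcut per block (`DC`). In a
block, the shortcut is added to the batch-normalized convolution output
and the sum passes through the activation; the shortcut convolution
carries its own batch norm. The loss is waveform MSE against the pure
slice.

Unstated architectural details we fixed: channel width 64 and kernel 3
(the smallest standard choice that keeps the $2^8$ dilation meaningful
on 2-s inputs); zero padding for same-length outputs; one standard
convolution before the blocks, one after, then the 1×1 head.

## Frequency-domain networks (FDD-Nets)

Mask estimators over magnitude spectrograms (Hann 256/128,
non-centered — this framing is forced by the 129 × 249 shape of a 2-s
clip; centered framing would give 251 frames). Frames are the recurrence
axis and the 129 bins the features: three recurrent layers (RNN, GRU or
LSTM; unidirectional or bidirectional — variants R/G/L/BR/BG/BL),
dropout (0.2) before a fully connected ReLU layer mapping back to 129
mask values per frame. The denoised magnitude is
$F_{den} = F_{noisy} \odot M$ and the loss is
$\sum (F_{noisy}\hat M - F_{pure})^2 / N$ with $N$ = bins × frames.

The spectrogram entering the loss is the linear *magnitude* (the
masking equation with a real non-negative mask only makes sense on
magnitudes), and reconstruction reuses the noisy phase — the standard
choice where phase is not modelled. Network inputs are standardized per
frequency bin with training-set statistics; mask and loss operate on raw
magnitudes. Hidden size 256 and dropout 0.2 are defaults where no value
was stated.

Two consequences of noisy-phase reconstruction are worth spelling out.
First, the right *oracle* (upper-bound) mask is not the magnitude ratio
$|F_{pure}|/|F_{noisy}|$: in noise-dominated cells that mask keeps the
pure magnitude with the wrong phase and can double the residual, to the
point of losing to the all-ones mask on sparse signals. The package's
`oracle_mask()` is therefore the phase-sensitive mask
$\max(0, \mathrm{Re}(F_{pure}\overline{F_{noisy}})/|F_{noisy}|^2)$,
which per cell minimises the masked reconstruction error and provably
dominates all-ones. Second, the ISTFT normalizer (the overlap-added
squared synthesis window) is floored at 10 % of its peak: the few
outermost samples of a clip are covered only by the near-zero tail of
one window, and dividing a *modified* spectrogram by ~1e-7 there would
blow up the clip edges; flooring attenuates those samples instead while
leaving the interior reconstruction exact.

## Initialisation of the output heads

Both families initialise their final projection (the 1×1 convolution,
the mask head) at 1 % of Glorot scale. The untrained network is then a
near-null denoiser — which at negative SNR is already a strong baseline,
since replacing a -24 dB mixture by silence raises the measured SNR to
0 dB. Short training runs therefore start from sensible behaviour and
move monotonically toward signal recovery instead of spending their
first epochs unlearning a random initial output. This is the same logic
as zero-initialising the last layer of residual blocks.

## Training protocol

Adam, batch size 16, 50 epochs at full scale. TDD: initial learning
rate 0.001, halved every 20 epochs (step policy). FDD: initial rate
0.0001 with plateau policy — multiplied by 0.7 after any epoch whose
mean training loss did not decrease. "Did not decrease" is evaluated on
per-epoch mean training loss; no validation split is used, matching the
protocol the schedules come from.

## Wavelet baseline

Classical shrinkage: db1 (Haar) multilevel decomposition, soft
thresholding of all detail bands, minimax threshold
$\hat\sigma\,(0.3936 + 0.1829\log_2 n)$ for $n > 32$ (else 0), with
$\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ from the finest detail
band. Unstated parameters: decomposition depth 5 (the coarsest band
then sits near 250–500 Hz at 16 kHz, far below the 5 kHz signal band)
and the median noise estimator. Odd-length signals are extended by one
mirrored sample per level; reconstruction with zero thresholds is exact
to 1e-8.

## Metrics

* **ΔSNR** — SNR after denoising minus before. As printed, the source
  formula has the two terms swapped, which would make every reported
  improvement negative; the package implements after − before.
* **ΔSegSNR** — the same increment on frame-averaged SNR (256-sample
  windows, 128 shift). Frames with zero pure energy are excluded
  (configurable) rather than propagating −∞; per-frame SNRs are not
  clamped.
* **LSD** — frame-averaged root-mean-square difference of log power
  spectra (STFT 256/128, power floored at 1e-10), i.e. per frame
  $\sqrt{\mathrm{mean}_b [10\log_{10}(P_{pure}/P_{den})]^2}$, averaged
  over frames. The compact printed formula omits the root and the
  normalisations; only the RMS reading produces values on the ~1 dB
  scale reported.
* **Relative improvement** — $100\,(x - r)/r$ (or $(r - x)/r$ for
  LSD-type "fell by" statements), rounded to two decimals *half away
  from zero*: this is the rounding that reproduces every printed
  percentage (banker's rounding fails on 15.625 → 15.63).

On sparse synthetic clips the absolute LSD runs far above the ~0.85 dB
reported on field recordings: most synthetic frames are near-silent, so
log-power ratios are dominated by the noise floors of the two signals.
LSD comparisons between methods remain meaningful; absolute values are
not comparable across signal populations.

## Downstream classifier (FSRNet)

A 3-class spectrogram classifier — feeding / non-infested ambient /
environmental noise — measures detection benefit: magnitude STFT with
Hann 480/160 (241 × 198 for 2 s), two 3×3 stride-2 convolutions (32 and
64 filters, ReLU), global average pooling, softmax over 3 classes.
Inputs are log1p-compressed and standardized per spectrogram. It trains
only on the three *clean* classes; denoised mixtures are only ever
scored, not trained on. `evaluate_denoising_benefit` reports the
fraction of mixed feeding clips still recognised as feeding, per SNR
bucket and per condition (pure / noisy / each denoiser).

## Problem sizes, numerical choices, determinism

The package's benchmark profile (`experiment_config()`) is an honest
desk scale chosen so a full run completes in minutes on one CPU: 198
training and 60 test mixtures (33 and 10 per SNR level) of 0.25-s
slices, 5 epochs, TDD channels 16, FDD hidden size 32. Full-scale
defaults (2-s slices, channels 64, hidden 256, 50 epochs) remain on the
model constructors. At the desk scale the package reproduces the
qualitative ordering of the original comparison — both trained networks
clearly exceed the wavelet baseline's mean ΔSNR, with the time-domain
network ahead of the frequency-domain one — but not the absolute dB
values, which depend on undeposited recordings.

Other numerical choices: STFT/ISTFT use a periodic Hann window with
synthesis-window overlap-add normalisation (perfect reconstruction on
the interior at hop = window/2; the outermost half-window is
approximate); power spectra are floored at 1e-10 before logs; batch
norm uses eps 1e-5 and momentum 0.1 running statistics; Adam uses the
standard (0.9, 0.999, 1e-8). Heavy conv/batch-norm loops run in
compiled code; recurrent layers and everything else are plain R matrix
algebra. All stochastic steps (generation, pairing, shuffling, dropout,
initialisation) derive from explicit integer seeds; evaluation passes
are deterministic.

## Known limitations

* Surrogate signals, not recordings: absolute metric values (especially
  LSD) are not comparable to field numbers.
* Noisy-phase reconstruction bounds FDD performance at very low SNR.
* The Haar basis makes the wavelet baseline's boundary handling exact
  but its frequency selectivity crude; that is the configuration being
  reproduced, not a recommendation.
* Smoke-scale training (hundreds of Adam steps) demonstrates learning
  and ordering, not convergence; nothing here should be read as a tuned
  field-ready model.

## A minimal end-to-end run

```{r, eval = FALSE}
library(larvadenoise)
res <- run_benchmark(experiment_config(seed = 1))
res$summary
improvement_table(res$summary, reference = "wavelet")
```
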