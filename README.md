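# larvadenoise

Acoustic denoising for early monitoring of wood-boring pest larvae.

Wood-boring beetle larvae (such as *Semanotus bifasciatus* in
*Platycladus* logs) feed invisibly inside trunks, but their biting
registers on a piezoelectric probe as a sparse train of millisecond
broadband pulses with dominant energy near 5 kHz. In the field this
signal is buried under traffic, horns, bird song, wind and speech, often
at strongly negative SNR. `larvadenoise` implements the denoising chain
that makes acoustic detection workable:

* **SNR-controlled mixing** — noisy feeding sounds built as
  `S = C + a N` with `a` chosen so that
  `10·log10[ΣC² / Σ(S−C)²]` hits a target SNR exactly; balanced
  assignment over a training grid (−20…5 dB, step 5) and a wider test
  grid (−24…6 dB, step 6).
* **Time-domain denoising networks (TDD-Nets)** — waveform-to-waveform
  convolutional denoisers with eight convolution blocks; variants use
  standard convolutions (`C`), dilated convolutions with rate `2^k` in
  block `k` (`D`), identity shortcuts (`DS`) or convolutional shortcuts
  (`DC`); batch norm + leaky ReLU after every convolution except the
  final 1×1; waveform-MSE loss.
* **Frequency-domain denoising networks (FDD-Nets)** — recurrent mask
  estimators (RNN/GRU/LSTM, uni/bidirectional) over magnitude
  spectrograms (Hann 256/128), `F_den = F_noisy ⊙ M`, masked-MSE loss,
  reconstruction with the noisy phase.
* **Wavelet baseline** — db1 (Haar) decomposition, minimax threshold
  `σ̂(0.3936 + 0.1829 log2 n)`, soft thresholding.
* **Metrics** — ΔSNR, ΔSegSNR (frame-wise, 256/128) and log-spectral
  distance, plus the relative-improvement statistic used in comparison
  tables.
* **FSRNet** — a compact 3-class spectrogram classifier
  (feeding / non-infested ambient / environmental noise) quantifying how
  much a denoiser helps downstream detection.
* **Synthetic surrogate signals** — seeded generators for feeding
  pulses, eight environmental-noise classes and quiet wood ambience, so
  the whole pipeline runs and is tested without field recordings.

The network layers (dilated 1-D/strided 2-D convolution, batch norm,
RNN/GRU/LSTM with backpropagation through time, Adam) are implemented in
the package itself, with the hot loops in compiled code; no external
deep-learning framework is required.

## A worked example

```r
library(larvadenoise)

# a pure feeding clip and a bird-song noise clip, 2 s at 16 kHz
pure  <- gen_feeding(feeding_spec(seed = 7), duration = 2, rate = 16000)
noise <- gen_noise(noise_spec("bird_chirp", seed = 8), 2, 16000)

# mix at exactly -12 dB and verify
rec <- mix_at_snr(pure, noise, target = -12)
measure_snr(rec$pure, rec$mixed)
#> [1] -12

# wavelet baseline on this clip
den <- wavelet_denoise(rec$mixed)
delta_snr(rec$pure, rec$mixed, den)
#> [1] 0.1806506
```

A full (desk-scale) benchmark — synthesize sources, build balanced
train/test mixtures, train TDD-Net-DC and FDD-Net-BL for 5 epochs,
evaluate against the wavelet baseline:

```r
res <- run_benchmark(experiment_config(seed = 1))
res$summary
#>    method delta_snr delta_segsnr      lsd
#> 1  tdd_dc 14.374114    18.542431 15.17495
#> 2  fdd_bl  7.996902    19.587709 25.37287
#> 3 wavelet  3.749527     4.657486 19.73635
```

Mean ΔSNR: the trained time-domain network gains ~14 dB and the
frequency-domain network ~8 dB over the test grid, both well above the
wavelet baseline's ~3.7 dB — the qualitative ordering the method
comparison is about. Absolute values at this scale are not field
numbers; see the vignette (`vignettes/denoising-methods.Rmd`) for what
the synthetic benchmark does and does not show.

## Command-line interface

A thin CLI over the same functions lives at
`inst/scripts/larvadenoise-cli.R` (after installation:
`system.file("scripts", "larvadenoise-cli.R", package = "larvadenoise")`),
with subcommands `synth`, `mix`, `denoise` and `evaluate` for
shell-based dataset generation, mixing, denoising of WAV files and
report generation.
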