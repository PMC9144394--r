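# Small fixtures shared across test files; everything is generated in
# code so test inputs stay deterministic and text-free.

fix_feeding <- function(seconds = 0.5, rate = 16000, seed = 101L) {
  gen_feeding(feeding_spec(seed = seed), seconds, rate)
}

fix_noise <- function(kind = "bird_chirp", seconds = 0.5, rate = 16000,
                      seed = 202L, level = 0.05) {
  gen_noise(noise_spec(kind, level = level, seed = seed), seconds, rate)
}

# a small balanced mixture set over a grid
fix_mixtures <- function(n = 12, seconds = 0.5, rate = 16000,
                         grid = snr_grid("test"), seed = 303L) {
  pures <- gen_segments("feeding", n, seconds, rate, seed = seed)
  noises <- gen_segments("noise", n, seconds, rate, seed = seed + 1L)
  build_mixture_dataset(pures, noises, grid, seed = seed + 2L)
}

# write a 2-channel 16-bit PCM WAV by hand (for reject tests)
write_stereo_wav <- function(path, n = 100, rate = 8000) {
  x <- as.integer(round(1000 * sin(2 * pi * 440 * (1:(2 * n)) / rate)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")          # stereo
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 4L), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  path
}

# periodogram peak frequency of a clip (independent oracle for spectral
# content: direct FFT of the whole clip, no package framing involved)
peak_freq <- function(clip) {
  n <- length(clip$samples)
  p <- Mod(stats::fft(clip$samples))^2
  half <- seq_len(n %/% 2)
  (which.max(p[half]) - 1) * clip$rate / n
}

# spectral flatness (geometric over arithmetic mean of the periodogram)
spectral_flatness <- function(clip) {
  n <- length(clip$samples)
  p <- Mod(stats::fft(clip$samples))^2
  p <- p[2:(n %/% 2)] + 1e-300
  exp(mean(log(p))) / mean(p)
}
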