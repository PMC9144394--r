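test_that("STFT shapes follow the non-centered framing formula", {
  clip <- fix_feeding(seconds = 2)
  S <- stft(clip, 256, 128)
  expect_equal(dim(S$values), c(129, 249))
  S2 <- stft(clip, 480, 160)
  expect_equal(dim(S2$values), c(241, 198))

  # property sweep: bins = window/2 + 1, frames = floor((L - w)/h) + 1
  set.seed(12)
  for (i in 1:8) {
    w <- sample(c(64, 128, 256, 512), 1)
    h <- sample(c(w %/% 4, w %/% 2, w), 1)
    L <- w + sample(0:5000, 1)
    x <- audio_clip(stats::rnorm(L), 16000)
    S <- stft(x, w, h)
    expect_equal(dim(S$values), c(w / 2 + 1, (L - w) %/% h + 1))
  }
  expect_error(stft(audio_clip(numeric(100), 16000), 256, 128), "shorter")
})

test_that("STFT is linear and zero in equals zero out", {
  x <- fix_feeding()
  a <- 2.5
  ax <- audio_clip(a * x$samples, x$rate)
  expect_equal(stft(ax)$values, a * stft(x)$values)
  z <- stft(audio_clip(numeric(1000), 16000), 256, 128)
  expect_true(all(z$values == 0))
})

test_that("ISTFT inverts STFT on the interior and preserves energy", {
  set.seed(5)
  x <- audio_clip(stats::rnorm(8000), 16000)
  back <- istft(stft(x, 256, 128), length_out = 8000)
  interior <- 129:(8000 - 129)
  expect_lt(max(abs(back$samples[interior] - x$samples[interior])), 1e-6)
  e_in <- sum(x$samples[interior]^2)
  e_out <- sum(back$samples[interior]^2)
  expect_lt(abs(e_out - e_in) / e_in, 0.001)

  zs <- stft(audio_clip(numeric(1000), 16000))
  expect_true(all(istft(zs)$samples == 0))
})

test_that("power spectra square magnitudes with an epsilon floor", {
  m <- spectrogram(matrix(2, 129, 3), 256, 128, 16000, kind = "magnitude")
  p <- power_spec(m)
  expect_true(all(p$values == 4))
  z <- spectrogram(matrix(0, 129, 3), 256, 128, 16000, kind = "magnitude")
  expect_true(all(power_spec(z)$values == 1e-10))
})

test_that("framewise power tracks windowed time-domain energy (Parseval)", {
  set.seed(6)
  x <- audio_clip(stats::rnorm(2048), 16000)
  S <- stft(x, 256, 128)
  P <- power_spec(S)$values
  # one-sided sum doubled (minus DC/Nyquist once) = window * frame energy
  w <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 256)
  for (j in seq_len(ncol(P))) {
    seg <- x$samples[((j - 1) * 128 + 1):((j - 1) * 128 + 256)] * w
    lhs <- 2 * sum(P[, j]) - P[1, j] - P[129, j]
    expect_lt(abs(lhs - 256 * sum(seg^2)) / (256 * sum(seg^2)), 0.01)
  }
})
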