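test_that("WAV write/read round-trips a clip up to 16-bit quantization", {
  clip <- audio_clip(stats::runif(32000, -0.9, 0.9), 16000)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  back <- read_wav(f)
  expect_equal(n_samples(back), 32000)
  expect_equal(back$rate, 16000)
  expect_lt(max(abs(back$samples - clip$samples)), 2^-15)
})

test_that("16-bit PCM scaling convention puts full scale at 32767/32768", {
  clip <- audio_clip(c(1, -1, 0), 8000)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  back <- read_wav(f)
  expect_equal(back$samples, c(32767 / 32768, -1, 0))
})

test_that("multi-channel and missing files are rejected", {
  f <- withr::local_tempfile(fileext = ".wav")
  write_stereo_wav(f)
  expect_error(read_wav(f), "multi-channel")
  expect_error(read_wav(file.path(tempdir(), "no_such_file.wav")), "not found")
})

test_that("resampling honours the length ratio and identity case", {
  clip <- audio_clip(stats::rnorm(441000), 44100)
  out <- resample_clip(clip, 16000)
  expect_equal(n_samples(out), 160000)
  expect_equal(out$rate, 16000)
  same <- resample_clip(clip, 44100)
  expect_identical(same$samples, clip$samples)
  expect_error(resample_clip(clip, -1), "positive")
})

test_that("resampling preserves the dominant tone frequency", {
  t <- (0:440999) / 44100
  tone <- audio_clip(sin(2 * pi * 1000 * t), 44100)
  out <- resample_clip(tone, 16000)
  # oracle: periodogram of the resampled analytic tone; one-bin slack
  bin <- out$rate / n_samples(out)
  expect_lt(abs(peak_freq(out) - 1000), bin + 1e-9)
})

test_that("partition cuts exact pieces and discards the remainder", {
  seg <- audio_clip(stats::rnorm(300 * 16000), 16000)
  pieces <- partition(seg, 2)
  expect_length(pieces, 150)
  expect_true(all(vapply(pieces, n_samples, integer(1)) == 32000))

  short <- audio_clip(stats::rnorm(5 * 8000), 8000)
  expect_length(partition(short, 2), 2)

  # concatenating the pieces reproduces the prefix of the original
  glued <- unlist(lapply(pieces, `[[`, "samples"))
  expect_identical(glued, seg$samples[seq_len(150 * 32000)])
})
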