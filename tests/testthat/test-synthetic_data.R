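test_that("generators respect the duration/rate contract and seeds", {
  f1 <- gen_feeding(feeding_spec(seed = 5L), 2, 16000)
  expect_equal(n_samples(f1), 32000)
  expect_equal(f1$rate, 16000)
  f2 <- gen_feeding(feeding_spec(seed = 5L), 2, 16000)
  expect_identical(f1$samples, f2$samples)

  for (kind in c("bird_chirp", "vehicle", "whistle", "wind", "speech_like",
                 "dripping", "white", "pink")) {
    n1 <- gen_noise(noise_spec(kind, seed = 9L), 0.5, 16000)
    n2 <- gen_noise(noise_spec(kind, seed = 9L), 0.5, 16000)
    expect_identical(n1$samples, n2$samples)
    expect_equal(n_samples(n1), 8000)
  }

  a1 <- gen_ambient(0.5, 16000, seed = 4L)
  a2 <- gen_ambient(0.5, 16000, seed = 4L)
  expect_identical(a1$samples, a2$samples)
})

test_that("feeding pulses concentrate energy near the configured band", {
  spec <- feeding_spec(center_freq = 5000, bandwidth = 2000, seed = 21L)
  # average periodogram across several clips: the peak must sit within
  # center +/- bandwidth/2
  peaks <- vapply(1:5, function(i) {
    peak_freq(gen_feeding(feeding_spec(center_freq = 5000, bandwidth = 2000,
                                       seed = 21L + i), 2, 16000))
  }, numeric(1))
  expect_true(all(abs(peaks - 5000) <= 1000))
  expect_error(gen_feeding(feeding_spec(center_freq = 9000, seed = 1L),
                           1, 16000), "Nyquist")
})

test_that("noise kinds follow their construction contracts", {
  w <- gen_noise(noise_spec("white", level = 0.1, seed = 2L), 2, 16000)
  expect_lt(abs(clip_rms(w) - 0.1) / 0.1, 0.01)

  wh <- gen_noise(noise_spec("whistle", seed = 3L), 1, 16000)
  p <- Mod(stats::fft(wh$samples))^2
  half <- p[2:8000]
  # single dominant spectral peak: the top bin towers over the median
  expect_gt(max(half) / stats::median(half), 1e3)

  n1 <- gen_noise(noise_spec("wind", level = 0.05, seed = 10L), 2, 16000)
  n2 <- gen_noise(noise_spec("wind", level = 0.05, seed = 11L), 2, 16000)
  expect_false(identical(n1$samples, n2$samples))
  expect_lt(abs(clip_rms(n1) - clip_rms(n2)) / 0.05, 0.05)

  expect_error(noise_spec("engine"), "arg")
})

test_that("ambient sound is quiet, seeded, and spectrally flatter than feeding", {
  amb <- gen_ambient(1, 16000, seed = 8L)
  expect_lt(clip_rms(amb), 0.1 * feeding_spec()$amplitude)
  feed <- gen_feeding(feeding_spec(seed = 8L), 1, 16000)
  expect_gt(spectral_flatness(amb), spectral_flatness(feed))
})

test_that("derived seeds stay valid R integer seeds", {
  s <- vapply(1:1000, function(i) derive_seed(2147480000, i), numeric(1))
  expect_true(all(s == as.integer(s)))
  expect_true(all(s < 2^31 & s >= 0))
  expect_equal(length(unique(s)), 1000)
})

test_that("synth_dataset writes slices and a manifest", {
  dir <- withr::local_tempdir()
  man <- synth_dataset(dir, "feeding", n = 2, seconds = 4, rate = 16000,
                       seed = 3L, slice_seconds = 2)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_wav(man$path[1])
  expect_equal(n_samples(back), 32000)
})
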