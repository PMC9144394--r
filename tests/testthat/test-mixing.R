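test_that("measure_snr matches the energy-ratio definition", {
  p <- audio_clip(c(1, 1, 1, 1), 8000)
  s <- audio_clip(p$samples + c(1, -1, 1, -1), 8000)
  expect_equal(measure_snr(p, s), 0)

  s10 <- audio_clip(p$samples + c(1, -1, 1, -1) / sqrt(10), 8000)
  expect_equal(measure_snr(p, s10), 10)

  expect_error(measure_snr(p, p), "zero")
  expect_identical(measure_snr(p, p, infinite = "inf"), Inf)
  z <- audio_clip(numeric(4), 8000)
  expect_error(measure_snr(z, s), "zero energy")
})

test_that("mix_at_snr hits the target SNR exactly and leaves pure untouched", {
  pure <- fix_feeding(seed = 31L)
  noise <- fix_noise(seed = 32L)
  rec <- mix_at_snr(pure, noise, -12)
  expect_lt(abs(measure_snr(rec$pure, rec$mixed) - (-12)), 1e-6)
  expect_identical(rec$pure$samples, pure$samples)
  # linearity: mixed - pure = scale * noise exactly
  expect_equal(rec$mixed$samples - pure$samples,
               rec$noise_scale * noise$samples)
  # equal-energy inputs at 0 dB need no scaling
  a <- audio_clip(c(1, 2, 3), 8000)
  b <- audio_clip(c(3, 2, 1), 8000)
  expect_equal(mix_at_snr(a, b, 0)$noise_scale, 1)
  expect_error(mix_at_snr(a, b, Inf), "finite")
})

test_that("round-trip holds across the SNR range for random synthetic pairs", {
  set.seed(77)
  for (i in 1:20) {
    pure <- gen_feeding(feeding_spec(seed = 1000L + i), 0.25, 16000)
    noise <- gen_noise(noise_spec("pink", seed = 2000L + i), 0.25, 16000)
    target <- stats::runif(1, -24, 6)
    rec <- mix_at_snr(pure, noise, target)
    expect_lt(abs(measure_snr(rec$pure, rec$mixed) - target), 1e-6)
  }
})

test_that("dataset builder balances SNR levels and keeps provenance", {
  recs <- fix_mixtures(n = 12)
  expect_length(recs, 12)
  man <- mixture_manifest(recs)
  expect_equal(as.integer(table(man$snr_db)), rep(2L, 6))
  expect_setequal(man$snr_db, rep(snr_grid("test"), 2))
  # records carry audio and measured SNR equals the assignment
  for (r in recs[1:3]) {
    expect_lt(abs(measure_snr(r$pure, r$mixed) - r$target_snr), 1e-6)
  }
})

test_that("dataset builder truncates non-divisible counts with a warning", {
  pures <- gen_segments("feeding", 13, 0.25, 16000, seed = 51L)
  noises <- gen_segments("noise", 13, 0.25, 16000, seed = 52L)
  expect_warning(
    recs <- build_mixture_dataset(pures, noises, snr_grid("training"), 1L),
    "truncating"
  )
  expect_length(recs, 12)
})

test_that("grids match the study design", {
  expect_equal(snr_grid("training"), c(-20, -15, -10, -5, 0, 5))
  expect_equal(snr_grid("test"), c(-24, -18, -12, -6, 0, 6))
})
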