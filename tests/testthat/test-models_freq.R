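test_that("variant names map to cell/direction and masks have spectrogram shape", {
  cfg <- fdd_variant("BL", hidden_size = 8)
  expect_equal(cfg$cell, "LSTM")
  expect_true(cfg$bidirectional)
  cfg2 <- fdd_variant("G", hidden_size = 8)
  expect_equal(cfg2$cell, "GRU")
  expect_false(cfg2$bidirectional)

  m <- build_fdd(cfg, seed = 1L)
  clip <- fix_feeding(seconds = 2, seed = 606L)
  S <- stft(clip, 256, 128)
  Xstd <- array(t(Mod(S$values)), dim = c(ncol(S$values), 1, 129))
  mask <- fdd_forward(m, Xstd)$out
  expect_equal(dim(mask)[c(1, 3)], c(249, 129))
  expect_true(all(mask >= 0))

  # bidirectional layers double the width feeding the final projection
  uni <- build_fdd(fdd_variant("L", hidden_size = 8), seed = 1L)
  expect_equal(nrow(m$params$fc$W), 2 * nrow(uni$params$fc$W))
})

test_that("apply_mask is the element-wise product with shape checking", {
  S <- spec_magnitude(stft(fix_feeding(seed = 5L), 256, 128))
  ones <- matrix(1, nrow(S$values), ncol(S$values))
  expect_equal(apply_mask(S, ones)$values, S$values)
  expect_true(all(apply_mask(S, ones * 0)$values == 0))
  half <- ones; half[10, 3] <- 0.5
  out <- apply_mask(S, half)
  expect_equal(out$values[10, 3], S$values[10, 3] * 0.5)
  expect_equal(out$values[-10, ], S$values[-10, ])
  expect_error(apply_mask(S, ones[, -1]), "shape")
  expect_error(apply_mask(S, -ones), "non-negative")
})

test_that("fdd_loss matches the masked-spectrogram MSE", {
  Fn <- matrix(c(1, 2, 4, 8), 2)
  Fp <- matrix(c(0.5, 1, 2, 4), 2)
  exact <- Fp / Fn
  expect_equal(fdd_loss(Fn, exact, Fp), 0)
  expect_equal(fdd_loss(matrix(1, 2, 2), matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  set.seed(7)
  M <- matrix(abs(stats::rnorm(4)), 2)
  expect_gte(fdd_loss(Fn, M, Fp), 0)
})

test_that("denoise_freq reconstructs through mask, noisy phase and ISTFT", {
  m <- build_fdd(fdd_variant("BL", hidden_size = 8), seed = 2L)
  clip <- audio_clip(stats::rnorm(8000), 16000)
  ones <- matrix(1, 129, (8000 - 256) %/% 128 + 1)
  out <- denoise_freq(m, clip, forced_mask = ones)
  expect_equal(n_samples(out), 8000)
  interior <- 129:(8000 - 129)
  expect_lt(max(abs(out$samples[interior] - clip$samples[interior])), 1e-6)
  # network path: correct length, deterministic
  out1 <- denoise_freq(m, clip)
  out2 <- denoise_freq(m, clip)
  expect_identical(out1$samples, out2$samples)
  expect_equal(n_samples(out1), 8000)
  expect_error(denoise_freq(m, audio_clip(stats::rnorm(8000), 8000)), "rate")
})

test_that("the oracle mask beats the all-ones mask on synthetic mixtures", {
  m <- build_fdd(fdd_variant("BL", hidden_size = 4), seed = 3L)
  recs <- fix_mixtures(n = 6, seconds = 0.5, seed = 707L)
  for (r in recs) {
    Sp <- stft(r$pure, 256, 128)
    Sn <- stft(r$mixed, 256, 128)
    omask <- oracle_mask(Sp, Sn)
    d_or <- denoise_freq(m, r$mixed, forced_mask = omask)
    d_id <- denoise_freq(m, r$mixed,
                         forced_mask = matrix(1, nrow(omask), ncol(omask)))
    expect_gt(delta_snr(r$pure, r$mixed, d_or),
              delta_snr(r$pure, r$mixed, d_id))
  }
})

test_that("smoke training reduces the masking loss", {
  recs <- fix_mixtures(n = 24, seconds = 0.25, seed = 808L)
  m <- build_fdd(fdd_variant("BL", hidden_size = 16), seed = 4L)
  m <- train_fdd(m, recs, epochs = 3, batch_size = 8, seed = 5L)
  expect_length(m$loss_history, 3)
  expect_lt(m$loss_history[3], m$loss_history[1])
})
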